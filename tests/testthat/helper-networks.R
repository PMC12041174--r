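# Test fixtures built in code: random tree networks and an independent
# series-parallel reduction oracle for them.

# random tree with n_seg segments, outlets (ref pressure 0) at every leaf
random_tree_network <- function(n_seg, seed) {
  set.seed(seed)
  seg <- data.frame(id = character(), name = character(), proximal = character(),
                    distal = character(), radius = numeric(), length = numeric(),
                    area_reduction = numeric(), stenosis_length = numeric(),
                    stringsAsFactors = FALSE)
  nodes <- "n0"
  for (i in seq_len(n_seg)) {
    parent <- sample(nodes, 1)
    child <- paste0("n", i)
    seg <- rbind(seg, data.frame(
      id = paste0("s", i), name = paste0("s", i), proximal = parent,
      distal = child, radius = runif(1, 1.2, 3.5), length = runif(1, 15, 60),
      area_reduction = 0, stenosis_length = 0, stringsAsFactors = FALSE))
    nodes <- c(nodes, child)
  }
  leaves <- setdiff(seg$distal, seg$proximal)
  out <- data.frame(node = leaves, resistance = runif(length(leaves), 0.2, 3),
                    compliance = 0, reference_pressure = 0,
                    stringsAsFactors = FALSE)
  arterial_network(seg, list(node = "n0", pressure = runif(1, 60, 140)), out)
}

# series-parallel reduction oracle (trees only, outlet refs must be 0):
# collapses the tree into equivalent resistances and back-substitutes.
# Entirely independent of the package's nodal solver.
sp_oracle_flows <- function(network) {
  seg <- network$segments
  out <- network$outlets
  res <- vapply(seq_len(nrow(seg)), function(i)
    segment_resistance(as.list(seg[i, ]), network$viscosity), numeric(1))
  stopifnot(all(out$reference_pressure == 0))
  req <- function(node) {
    rs <- numeric()
    i <- match(node, out$node)
    if (!is.na(i)) rs <- c(rs, out$resistance[i])
    for (k in which(seg$proximal == node)) rs <- c(rs, res[k] + req(seg$distal[k]))
    1 / sum(1 / rs)
  }
  flows <- setNames(numeric(nrow(seg)), seg$id)
  walk <- function(node, p) {
    for (k in which(seg$proximal == node)) {
      q <- p / (res[k] + req(seg$distal[k]))
      flows[seg$id[k]] <<- q
      walk(seg$distal[k], p - q * res[k])
    }
  }
  walk(network$inlet$node, network$inlet$pressure)
  flows
}

# total outlet drain of a solution (for conservation checks)
total_outlet_flow <- function(solution, network) {
  sum((solution$node_pressures[network$outlets$node] -
         network$outlets$reference_pressure) / network$outlets$resistance,
      na.rm = TRUE)
}
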