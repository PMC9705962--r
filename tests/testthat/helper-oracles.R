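# Independent brute-force oracles used by the structure-search and
# symbolic-regression tests.

# Exhaustive search over all interaction networks with at most one parent
# per taxon: enumerate every per-child parent choice (including "none"),
# reject cyclic combinations, and return the best total score.
exhaustive_best_score <- function(data, max_parents = 1) {
  stopifnot(max_parents == 1)
  taxa <- colnames(data$t1)
  choices <- lapply(taxa, function(tx) {
    c(list(character(0)), as.list(c(
      paste0("diet:", colnames(data$diet)),
      paste0("t0:", colnames(data$t0)),
      paste0("t1:", setdiff(taxa, tx))
    )))
  })
  grid <- do.call(expand.grid, c(lapply(choices, seq_along),
    list(KEEP.OUT.ATTRS = FALSE)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    parents <- stats::setNames(lapply(seq_along(taxa), function(i) {
      choices[[i]][[grid[r, i]]]
    }), taxa)
    net <- tryCatch(
      interaction_network(colnames(data$diet), taxa, parents,
        max_parents = 1),
      error = function(e) NULL  # cyclic combination
    )
    if (is.null(net)) next
    s <- network_score(net, data)
    if (s > best) best <- s
  }
  best
}

# All depth-1 candidate expressions for the classifier: each bare feature
# and the constants 0 and 1. Returns the minimum mean-squared error.
depth1_best_mse <- function(features, labels) {
  cand <- c(as.list(colnames(features)), list(0, 1))
  min(vapply(cand, function(cc) {
    v <- if (is.character(cc)) features[, cc] else rep(cc, nrow(features))
    mean((v - labels)^2)
  }, numeric(1)))
}

# Small helper: a paired_data object built directly from log2-scale
# matrices with named columns.
make_paired <- function(diet, t0, t1) {
  paired_data(diet, t0, t1, log = FALSE)
}
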