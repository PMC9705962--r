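# Predicted Relative Metabolic Turnover (PRMT): a metabolic-network
# topology score of a community's relative capacity, versus the cohort
# average, to synthesize (+) or catabolize (-) each metabolite, computed
# from enzyme-function-profile deviations pushed through a signed,
# degree-normalized enzyme-metabolite connection matrix.

#' Read / write a signed enzyme-metabolite reaction network
#'
#' TSV columns: `ec`, `metabolite`, `sign` (+1 = the enzyme function
#' produces the metabolite, -1 = consumes it).
#'
#' @param path File path.
#' @return A `reaction_network` data frame.
#' @export
load_reaction_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ec", "metabolite", "sign")
  if (!all(need %in% names(df))) {
    stop("reaction network table must have columns: ",
      paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (!all(df$sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  if (anyDuplicated(df[, c("ec", "metabolite")])) {
    stop("duplicate (ec, metabolite) link(s)")
  }
  class(df) <- c("reaction_network", "data.frame")
  df
}

#' @rdname load_reaction_network
#' @param network A `reaction_network`.
#' @export
write_reaction_network <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Build the signed, degree-normalized connection matrix
#'
#' `W[m, e] = sign(e, m) / degree(e)`, where `degree(e)` is the number of
#' metabolites linked to enzyme function `e`; zero where no link exists.
#' The degree normalization spreads an enzyme's contribution evenly over
#' the metabolites it touches.
#'
#' @param network A `reaction_network` data frame.
#' @return Numeric matrix, metabolites in rows, enzyme functions in
#'   columns.
#' @export
build_connection_matrix <- function(network) {
  if (nrow(network) == 0) stop("empty reaction network")
  if (!all(network$sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  if (anyDuplicated(network[, c("ec", "metabolite")])) {
    stop("duplicate (ec, metabolite) link(s)")
  }
  ecs <- sort(unique(network$ec))
  mets <- sort(unique(network$metabolite))
  deg <- table(factor(network$ec, levels = ecs))
  w <- matrix(0, length(mets), length(ecs), dimnames = list(mets, ecs))
  w[cbind(match(network$metabolite, mets), match(network$ec, ecs))] <-
    network$sign / as.numeric(deg[network$ec])
  w
}

#' Score community metabolomes by Predicted Relative Metabolic Turnover
#'
#' Each sample's EFP is normalized to sum 1, stabilized as `log2(x + 1)`,
#' and centered on the cohort mean per enzyme function; the centered
#' deviations are pushed through the connection matrix:
#' `score[m, n] = sum_e W[m, e] * (x[e, n] - mean_n' x[e, n'])`. A positive
#' score means above-cohort-average predicted capacity to produce the
#' metabolite; scores sum to zero over the cohort for every metabolite.
#' Enzyme functions absent from the network contribute nothing.
#'
#' @param efps EFP matrix (samples x EC); at least 2 samples, since scores
#'   are relative to the cohort.
#' @param w Connection matrix from [build_connection_matrix()].
#' @return Matrix (samples x metabolites) of PRMT scores.
#' @export
compute_prmt <- function(efps, w) {
  efps <- as.matrix(efps)
  if (nrow(efps) < 2) {
    stop("PRMT scores are cohort-relative; need at least 2 samples")
  }
  s <- rowSums(efps)
  if (any(s == 0)) stop("sample(s) with an all-zero EFP")
  x <- log2(efps / s + 1)
  shared <- intersect(colnames(x), colnames(w))
  dev <- x[, shared, drop = FALSE]
  dev <- sweep(dev, 2, colMeans(dev))
  scores <- dev %*% t(w[, shared, drop = FALSE])
  rownames(scores) <- rownames(efps)
  scores
}

#' Fisher score for two-class feature separability
#'
#' `F = (mu_plus - mu_minus)^2 / (s2_plus + s2_minus)` per feature, with
#' unbiased (n-1) class variances. A zero denominator with a nonzero
#' numerator gives `Inf` (perfectly separated constant classes); 0/0 gives
#' 0 (a globally constant feature carries no information).
#'
#' @param features Matrix (samples x features).
#' @param labels Binary 0/1 vector, one per sample; both classes must have
#'   at least 2 samples.
#' @return Named numeric vector of scores, one per feature.
#' @export
fisher_score <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (sum(labels == 0) < 2 || sum(labels == 1) < 2) {
    stop("each class needs at least 2 samples for a class variance")
  }
  a <- features[labels == 1, , drop = FALSE]
  b <- features[labels == 0, , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, stats::var) + apply(b, 2, stats::var)
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

#' Select the top-scoring fraction of features
#'
#' Takes the `ceiling(fraction * n)` highest-scoring features; ties at the
#' cutoff are broken by lexical feature-name order, so the selection is
#' deterministic.
#'
#' @param scores Named numeric vector (e.g. from [fisher_score()]).
#' @param fraction Fraction in (0, 1\] (default 0.05, the top 5%).
#' @return Character vector of selected feature names.
#' @export
select_top_fraction <- function(scores, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(k)]
}
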