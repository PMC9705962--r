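# The in silico microbiome-transplant experiment: chain the fitted stages
# (community response to diet -> enzyme function profile -> metabolome ->
# obesity function) for a grid of starting communities and diets, and
# score each condition's obesogenesis relative to the run average.

#' Obesogenesis scores from obesity-function values
#'
#' `score_i = log(O_i / mean(O))` (log base 2 by default): a condition
#' scoring above 0 is predicted more obesogenic than the average condition
#' in the run, below 0 leaner.
#'
#' @param values Numeric vector of obesity-function values, one per
#'   condition.
#' @param base Logarithm base (default 2).
#' @return Numeric vector of scores; `NA` where a value (or the mean) is
#'   not positive.
#' @export
obesogenesis_scores <- function(values, base = 2) {
  avg <- mean(values)
  if (!is.finite(avg) || avg <= 0) {
    warning("mean obesity value is not positive; all scores undefined")
    return(rep(NA_real_, length(values)))
  }
  out <- rep(NA_real_, length(values))
  pos <- values > 0
  out[pos] <- log(values[pos] / avg, base)
  if (any(!pos)) {
    warning("non-positive obesity value(s); their scores are undefined")
  }
  out
}

#' Run the in silico microbiome-transplant experiment
#'
#' For every combination of a labeled starting community (e.g. `"Lean"`,
#' `"Obese"`) and a labeled diet (e.g. `"LF"`, `"HF"`): (1) predict the
#' community after the diet period with the fitted MAP regression, (2)
#' predict its enzyme function profile, (3) score the metabolome by PRMT
#' with the run's own conditions as the cohort, (4) evaluate the evolved
#' obesity function on the metabolome, and (5) convert the function values
#' to obesogenesis scores relative to the run average.
#'
#' @param communities Matrix of starting communities (rows labeled, sum-100
#'   scale) or a named list of abundance vectors.
#' @param diets Matrix of diet vectors (rows labeled, log2-normalized) or a
#'   named list.
#' @param map_model Fitted `map_regression`.
#' @param genomes A `genome_function_matrix`.
#' @param connection Connection matrix from [build_connection_matrix()].
#' @param phenotype A `phenotype_model` whose features are metabolites.
#' @param offsets Optional optimized offset matrix (default `NULL`).
#' @param feature_center,feature_scale Optional per-metabolite statistics
#'   (from the classifier's training cohort) used to standardize the
#'   metabolome before evaluating the obesity function; see
#'   [standardize_features()].
#' @param base Log base of the obesogenesis score (default 2).
#' @param clamp_epsilon If set, obesity-function values are floored at this
#'   positive value instead of yielding undefined scores.
#' @return An `obesogenesis_result` data frame with columns `community`,
#'   `diet`, `obesity_met`, `obesogenesis`, and attributes
#'   `predicted_communities`, `efp`, `metabolome`.
#' @export
run_transplant <- function(communities, diets, map_model, genomes,
                           connection, phenotype, offsets = NULL,
                           feature_center = NULL, feature_scale = NULL,
                           base = 2, clamp_epsilon = NULL) {
  as_mat <- function(x) {
    if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  }
  communities <- as_mat(communities)
  diets <- as_mat(diets)
  if (is.null(rownames(communities)) || is.null(rownames(diets))) {
    stop("communities and diets must be labeled (rownames or list names)")
  }
  grid <- expand.grid(community = rownames(communities),
    diet = rownames(diets), stringsAsFactors = FALSE)
  if (nrow(grid) < 2) stop("need at least 2 conditions for cohort scoring")

  pred <- t(vapply(seq_len(nrow(grid)), function(i) {
    predict_community(map_model, diets[grid$diet[i], ],
      communities[grid$community[i], ])[1, ]
  }, numeric(length(map_model$taxa))))
  rownames(pred) <- paste(grid$community, grid$diet, sep = "|")

  efp <- predict_efp(pred, genomes, offsets)
  metabolome <- compute_prmt(efp, connection)
  feats <- metabolome
  if (!is.null(feature_center)) {
    feats <- standardize_features(
      metabolome[, names(feature_center), drop = FALSE],
      center = feature_center, scale_ = feature_scale)
  }
  obesity <- eval_expression(phenotype$expr, feats)
  if (!is.null(clamp_epsilon)) {
    stopifnot(clamp_epsilon > 0)
    obesity <- pmax(obesity, clamp_epsilon)
  }
  scores <- obesogenesis_scores(obesity, base)

  out <- data.frame(grid, obesity_met = obesity, obesogenesis = scores)
  attr(out, "predicted_communities") <- pred
  attr(out, "efp") <- efp
  attr(out, "metabolome") <- metabolome
  class(out) <- c("obesogenesis_result", "data.frame")
  out
}
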