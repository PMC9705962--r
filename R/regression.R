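# The MAP (Microbiome Assemblage Prediction) regression layer: per-taxon
# linear models of log2 relative abundance at the final timepoint on diet
# features, initial-timepoint taxa, and (for the network-constrained
# variant) other final-timepoint taxa.

#' @keywords internal
new_map_regression <- function(variant, coef, parents, diet_features, taxa,
                               pseudocount = 0.01) {
  structure(
    list(variant = variant, coef = coef, parents = parents,
      diet_features = diet_features, taxa = taxa, pseudocount = pseudocount),
    class = "map_regression"
  )
}

#' @export
print.map_regression <- function(x, ...) {
  np <- sum(lengths(x$parents))
  cat("MAP regression (", x$variant, " variant): ", length(x$taxa),
    " taxa, ", np, " predictor terms\n", sep = "")
  invisible(x)
}

# Matrix of all node values (prefixed columns) for a paired_data object.
node_values <- function(data) {
  cbind(
    `colnames<-`(data$diet, paste0("diet:", colnames(data$diet))),
    `colnames<-`(data$t0, paste0("t0:", colnames(data$t0))),
    `colnames<-`(data$t1, paste0("t1:", colnames(data$t1)))
  )
}

fit_children <- function(data, parents, variant) {
  vals <- node_values(data)
  taxa <- colnames(data$t1)
  coef <- stats::setNames(lapply(taxa, function(tx) {
    pset <- parents[[tx]]
    y <- data$t1[, tx]
    x <- cbind(1, vals[, pset, drop = FALSE])
    if (nrow(x) < ncol(x)) {
      warning("taxon '", tx, "': fewer observations than parameters; ",
        "minimum-norm fit")
    }
    b <- ls_solve(x, y)
    c(intercept = b[1], stats::setNames(b[-1], pset))
  }), taxa)
  new_map_regression(variant, coef, parents, colnames(data$diet), taxa,
    data$pseudocount)
}

#' Fit the network-constrained diet-response regression
#'
#' Ordinary least squares, per taxon, of its log2 abundance at the final
#' timepoint on the values of its parents in the interaction network.
#' Observed values are used for final-timepoint parents during fitting;
#' prediction later re-evaluates them in topological order. Rank-deficient
#' designs are solved by the minimum-norm solution. A taxon with no
#' parents reduces to an intercept equal to its mean.
#'
#' @param network An `interaction_network`.
#' @param data A `paired_data` object over the same variables.
#' @return A `map_regression` object (variant `"network"`).
#' @export
fit_map_regression <- function(network, data) {
  stopifnot(inherits(network, "interaction_network"),
    inherits(data, "paired_data"))
  if (!identical(sort(network$taxa), sort(colnames(data$t1)))) {
    stop("network taxa do not match the data's taxon columns")
  }
  m <- fit_children(data, network$parents, "network")
  m$network <- network
  m
}

#' Fit the dense (non-network) diet-response regression
#'
#' The control model: every diet feature and every initial-timepoint taxon
#' predicts every taxon, with no network constraint and no final-timepoint
#' taxa among the predictors.
#'
#' @param data A `paired_data` object.
#' @return A `map_regression` object (variant `"dense"`).
#' @export
fit_nonnetwork_regression <- function(data) {
  stopifnot(inherits(data, "paired_data"))
  all_parents <- c(paste0("diet:", colnames(data$diet)),
    paste0("t0:", colnames(data$t0)))
  parents <- stats::setNames(
    rep(list(all_parents), ncol(data$t1)), colnames(data$t1))
  fit_children(data, parents, "dense")
}

#' Predict a community from a fitted MAP regression
#'
#' Evaluates every taxon's regression. For the network variant,
#' final-timepoint taxa are evaluated in topological order of the
#' final-timepoint subgraph, so each such parent contributes its freshly
#' predicted value. The log2 predictions are back-transformed and the
#' community renormalized to sum 100.
#'
#' @param model A fitted `map_regression`.
#' @param diet A diet vector (named, log2-normalized) as returned by
#'   [build_diet_vector()], or a matrix of them (samples x features).
#' @param community_t0 Initial community: named abundance vector
#'   (sum-100 scale) or matrix (samples x taxa).
#' @return Matrix (samples x taxa) of predicted abundances summing to 100
#'   per row, with attribute `"log2"` holding the raw log2 predictions.
#' @export
predict_community <- function(model, diet, community_t0) {
  stopifnot(inherits(model, "map_regression"))
  if (is.null(dim(diet))) diet <- matrix(diet, 1, dimnames = list("s1", names(diet)))
  if (is.null(dim(community_t0))) {
    community_t0 <- matrix(community_t0, 1,
      dimnames = list(rownames(diet)[1], names(community_t0)))
  }
  n <- nrow(diet)
  pc <- model$pseudocount
  t0_log2 <- log2_community(community_t0, pc)
  x1 <- matrix(NA_real_, n, length(model$taxa),
    dimnames = list(rownames(diet), model$taxa))
  order_t1 <- if (model$variant == "network") {
    topological_order(model$network)
  } else {
    model$taxa
  }
  for (tx in order_t1) {
    b <- model$coef[[tx]]
    pset <- model$parents[[tx]]
    z <- rep(b[["intercept"]], n)
    for (p in pset) {
      v <- switch(sub(":.*", "", p),
        diet = diet[, sub("^diet:", "", p)],
        t0 = t0_log2[, sub("^t0:", "", p)],
        t1 = x1[, sub("^t1:", "", p)])
      z <- z + b[[p]] * v
    }
    x1[, tx] <- z
  }
  out <- normalize_community(pmax(2^x1 - pc, 1e-12))
  attr(out, "log2") <- x1
  out
}

#' Mean per-sample Pearson correlation between communities
#'
#' The package's accuracy convention: for each sample, the Pearson
#' correlation between predicted and observed log2 relative abundances
#' across its taxa; the mean and SD are taken over samples. A sample in
#' which either vector has zero variance gets PCC 0 with a warning.
#'
#' @param predicted,observed Community matrices (samples x taxa, sum-100
#'   scale) with matching shapes.
#' @param pseudocount Log2 pseudocount (default 0.01).
#' @return List with `mean`, `sd` and `per_sample` PCC values.
#' @export
evaluate_mean_pcc <- function(predicted, observed, pseudocount = 0.01) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) {
    stop("predicted and observed must have the same shape")
  }
  mean_pcc(log2_community(predicted, pseudocount),
    log2_community(observed, pseudocount))
}

#' Cross-validate a MAP model by a k-fold partition
#'
#' Splits the samples into `n_folds` non-overlapping test folds (together a
#' partition, so each sample is tested exactly once). For each fold the
#' network is learned (network variant) and the regressions fitted on the
#' training samples, and the mean per-sample PCC is evaluated on both
#' sides.
#'
#' @param data A `paired_data` object.
#' @param variant `"network"` (learn a DAG, fit the constrained model) or
#'   `"dense"` (the all-predictors control).
#' @param n_folds Number of folds (default 5, i.e. 80/20 splits).
#' @param max_parents,restarts Passed to [learn_interaction_network()].
#' @param seed Integer seed controlling fold assignment and the structure
#'   search.
#' @return A `cv_report`: data frame of per-fold train/test mean PCC with
#'   attributes `mean_train`, `mean_test`, `sd_train`, `sd_test` (SDs over
#'   the pooled per-sample PCCs) and `folds` (the test index partition).
#' @export
cross_validate <- function(data, variant = c("network", "dense"),
                           n_folds = 5, max_parents = 5, restarts = 10,
                           seed = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "paired_data"))
  n <- data$n
  if (n < 2 * n_folds) stop("each fold needs at least 2 samples")
  folds <- with_seed(sub_seed(seed, "folds"), {
    split(sample(n), rep(seq_len(n_folds), length.out = n))
  })
  take <- function(idx) {
    structure(list(diet = data$diet[idx, , drop = FALSE],
      t0 = data$t0[idx, , drop = FALSE], t1 = data$t1[idx, , drop = FALSE],
      n = length(idx), pseudocount = data$pseudocount),
      class = "paired_data")
  }
  pcc_on <- function(model, d) {
    pred <- predict_community(model, d$diet, 2^d$t0 - d$pseudocount)
    p <- row_pcc(attr(pred, "log2"), d$t1)
    as.numeric(p)
  }
  train_pcc <- list()
  test_pcc <- list()
  rows <- lapply(seq_len(n_folds), function(f) {
    test_idx <- folds[[f]]
    train <- take(setdiff(seq_len(n), test_idx))
    test <- take(test_idx)
    model <- if (variant == "network") {
      net <- learn_interaction_network(train, max_parents = max_parents,
        restarts = restarts, seed = sub_seed(seed, paste0("fold", f)))
      fit_map_regression(net, train)
    } else {
      suppressWarnings(fit_nonnetwork_regression(train))
    }
    tr <- pcc_on(model, train)
    te <- pcc_on(model, test)
    train_pcc[[f]] <<- tr
    test_pcc[[f]] <<- te
    data.frame(fold = f, train_pcc = mean(tr), test_pcc = mean(te))
  })
  report <- do.call(rbind, rows)
  class(report) <- c("cv_report", "data.frame")
  attr(report, "mean_train") <- mean(unlist(train_pcc))
  attr(report, "mean_test") <- mean(unlist(test_pcc))
  attr(report, "sd_train") <- stats::sd(unlist(train_pcc))
  attr(report, "sd_test") <- stats::sd(unlist(test_pcc))
  attr(report, "folds") <- folds
  report
}

#' Hypergeometric enrichment of nutrient categories in a network
#'
#' For each nutrient category, the upper-tail hypergeometric probability of
#' observing at least the realized number of category members among the
#' diet features that participate in the interaction network, drawing from
#' the full diet feature population.
#'
#' @param network An `interaction_network`.
#' @param categories Named character vector mapping each diet feature to
#'   its category (default: the built-in 48-feature vocabulary).
#' @return Data frame with columns `category`, `in_network`, `in_population`,
#'   `p_value`.
#' @export
nutrient_enrichment <- function(network,
                                categories = stats::setNames(
                                  reference_diet("HF")$category,
                                  reference_diet("HF")$nutrient)) {
  pop <- names(categories)
  nodes <- intersect(network_diet_nodes(network), pop)
  n_draw <- length(nodes)
  cats <- unique(unname(categories))
  rows <- lapply(cats, function(cc) {
    members <- pop[categories[pop] == cc]
    k <- sum(nodes %in% members)
    p <- stats::phyper(k - 1, length(members), length(pop) - length(members),
      n_draw, lower.tail = FALSE)
    data.frame(category = cc, in_network = k, in_population = length(members),
      p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
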