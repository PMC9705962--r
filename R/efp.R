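# Enzyme function profiles (EFPs): predicting a community's metagenomic
# gene content for metabolic enzyme functions (EC numbers) from its
# taxonomic structure and genome-derived average gene counts, optionally
# refined by per-(taxon, EC) offsets bounded by the observed genome SD.

#' Construct a genome function matrix
#'
#' Taxon-by-enzyme-function summary of sequenced genomes: the mean number
#' of genes per genome for each enzyme function in each taxon (`ave`) and
#' its standard deviation across genomes (`sd`).
#'
#' @param ave,sd Non-negative numeric matrices (taxa x EC) with matching
#'   dimnames.
#' @return A `genome_function_matrix`.
#' @export
genome_function_matrix <- function(ave, sd) {
  ave <- as.matrix(ave)
  sd <- as.matrix(sd)
  if (!all(dim(ave) == dim(sd))) stop("ave and sd must have the same shape")
  if (any(ave < 0) || any(sd < 0)) stop("ave and sd must be non-negative")
  if (!identical(dimnames(ave), dimnames(sd))) {
    stop("ave and sd must share dimnames")
  }
  structure(list(ave = ave, sd = sd), class = "genome_function_matrix")
}

#' Read a genome function matrix from TSV
#'
#' Expects a main table (rows taxa, columns EC identifiers) and a paired
#' `_SD` table of the same shape.
#'
#' @param path Path to the mean-gene-count TSV.
#' @param sd_path Path to the SD TSV (default: `path` with `_SD` inserted
#'   before the extension).
#' @return A `genome_function_matrix`.
#' @export
load_genome_matrix <- function(path, sd_path = sub("(\\.[^.]*)$", "_SD\\1", path)) {
  read_m <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, row.names = 1)
    as.matrix(df)
  }
  genome_function_matrix(read_m(path), read_m(sd_path))
}

#' Write a genome function matrix as paired TSVs
#' @param genomes A `genome_function_matrix`.
#' @param path Output path for the mean table; the SD table gets `_SD`.
#' @return Invisibly, the two paths.
#' @export
write_genome_matrix <- function(genomes, path) {
  sd_path <- sub("(\\.[^.]*)$", "_SD\\1", path)
  w <- function(m, p) {
    utils::write.table(data.frame(taxon = rownames(m), m, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(genomes$ave, path)
  w(genomes$sd, sd_path)
  invisible(c(path, sd_path))
}

check_offsets <- function(offsets, genomes) {
  if (!all(dim(offsets) == dim(genomes$ave))) {
    stop("offset matrix shape does not match the genome matrix")
  }
  if (any(abs(offsets) > genomes$sd + 1e-9)) {
    stop("offsets must lie within +/- the genome SD, element-wise")
  }
  invisible(TRUE)
}

#' Predict enzyme function profiles from community structure
#'
#' The community-weighted genome sum: for enzyme function i,
#' `EC_i = sum_j (AveEC_ij + e_ji) * taxon_j`, with `taxon_j` the relative
#' abundance on the sum-100 scale. Without offsets this is the plain
#' genome-average prediction; offsets (bounded element-wise by the genome
#' SD) give the refined variant. Negative sums are floored at 0.
#'
#' @param community Named abundance vector or matrix (samples x taxa,
#'   sum-100 scale) over the genome matrix's taxa.
#' @param genomes A `genome_function_matrix`.
#' @param offsets Optional taxon x EC offset matrix (`NULL` = no offsets).
#' @return Matrix (samples x EC) of non-negative predicted abundances.
#' @export
predict_efp <- function(community, genomes, offsets = NULL) {
  if (is.null(dim(community))) {
    community <- matrix(community, 1, dimnames = list("s1", names(community)))
  }
  community <- as.matrix(community)
  if (ncol(community) != nrow(genomes$ave) ||
      !identical(colnames(community), rownames(genomes$ave))) {
    stop("community taxa do not match the genome matrix's taxa")
  }
  m <- genomes$ave
  if (!is.null(offsets)) {
    check_offsets(offsets, genomes)
    m <- m + offsets
  }
  pmax(community %*% m, 0)
}

#' Mean per-sample PCC between predicted and observed EFPs
#'
#' Per sample, the Pearson correlation across enzyme functions, computed
#' on `log2(x + 1)` values by default, then averaged over samples.
#'
#' @param predicted,observed EFP matrices (samples x EC) of equal shape.
#' @param log Correlate log2(x + 1) values (default `TRUE`) or raw counts.
#' @return List with `mean`, `sd` and `per_sample` PCCs.
#' @export
evaluate_efp_pcc <- function(predicted, observed, log = TRUE) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) {
    stop("predicted and observed must have the same shape")
  }
  if (log) {
    predicted <- log2(predicted + 1)
    observed <- log2(observed + 1)
  }
  mean_pcc(predicted, observed)
}

# Internal objective used by the optimizer: mean per-sample PCC on
# log2(x+1) (or raw) values; with fewer than 3 enzyme functions the PCC is
# degenerate, so negative RMSE serves as the objective instead.
efp_objective <- function(pred, obs, log = TRUE) {
  if (ncol(obs) < 3) return(-sqrt(mean((pred - obs)^2)))
  if (log) {
    pred <- log2(pred + 1)
    obs <- log2(obs + 1)
  }
  mean(row_pcc(pred, obs))
}

#' Optimize genome offsets by Boltzmann-weighted stochastic hill climbing
#'
#' Starting from zero offsets, each iteration samples one (taxon, EC) cell
#' with probability proportional to `exp(SD / T)` (so high-variance cells
#' are proposed more often), draws a replacement offset uniformly within
#' `[-SD, +SD]`, and accepts the move only if the objective - the mean
#' per-sample PCC between predicted and observed EFPs - strictly
#' increases. Cells with SD 0 are pinned at offset 0 and never proposed.
#'
#' @param communities Community matrix (samples x taxa, sum-100 scale).
#' @param observed Observed EFP matrix (samples x EC).
#' @param genomes A `genome_function_matrix`.
#' @param iterations Number of proposal steps (default 2000).
#' @param seed Integer seed.
#' @param temperature Boltzmann temperature T (default: mean positive SD).
#' @param log Objective on log2(x+1) values (default `TRUE`).
#' @return List: `offsets` (taxon x EC), `objective` (final value),
#'   `baseline` (zero-offset value), `trace` (objective after each
#'   iteration; non-decreasing), `accepted` (move count).
#' @export
optimize_offsets <- function(communities, observed, genomes,
                             iterations = 2000, seed = 1,
                             temperature = NULL, log = TRUE) {
  communities <- as.matrix(communities)
  observed <- as.matrix(observed)
  stopifnot(iterations >= 0)
  if (nrow(communities) != nrow(observed)) {
    stop("communities and observed EFPs must be paired")
  }
  sdm <- genomes$sd
  e <- matrix(0, nrow(sdm), ncol(sdm), dimnames = dimnames(sdm))
  raw <- communities %*% genomes$ave
  obj <- efp_objective(pmax(raw, 0), observed, log)
  baseline <- obj
  free <- which(sdm > 0)
  if (length(free) == 0) {
    warning("all genome SDs are zero; nothing to optimize")
    return(list(offsets = e, objective = obj, baseline = baseline,
      trace = numeric(0), accepted = 0L))
  }
  if (is.null(temperature)) temperature <- mean(sdm[free])
  prob <- exp(sdm[free] / temperature)
  trace <- numeric(iterations)
  accepted <- 0L
  with_seed(sub_seed(seed, "hill_climb"), {
    cells <- if (iterations > 0) {
      sample(length(free), iterations, replace = TRUE, prob = prob)
    } else {
      integer(0)
    }
    draws <- stats::runif(iterations, -1, 1)
    for (it in seq_len(iterations)) {
      cell <- free[cells[it]]
      j <- (cell - 1) %% nrow(sdm) + 1      # taxon (row)
      i <- (cell - 1) %/% nrow(sdm) + 1     # enzyme function (column)
      e_new <- draws[it] * sdm[cell]
      delta <- communities[, j] * (e_new - e[cell])
      raw_new <- raw
      raw_new[, i] <- raw[, i] + delta
      obj_new <- efp_objective(pmax(raw_new, 0), observed, log)
      if (obj_new > obj) {
        obj <- obj_new
        raw <- raw_new
        e[cell] <- e_new
        accepted <- accepted + 1L
      }
      trace[it] <- obj
    }
  })
  list(offsets = e, objective = obj, baseline = baseline, trace = trace,
    accepted = accepted)
}

#' Run-to-run variation audit of the offset optimizer
#'
#' Runs the stochastic hill climber `n_runs` times with distinct sub-seeds
#' and reports the percent coefficient of variation of the final
#' objectives - a convergence diagnostic (small CV means repeated runs
#' reach very similar solutions).
#'
#' @inheritParams optimize_offsets
#' @param n_runs Number of repeats (at least 2).
#' @return List: `cv_percent` (100 * sd / mean of final objectives),
#'   `objectives` (per-run finals).
#' @export
run_variation_audit <- function(communities, observed, genomes,
                                iterations = 2000, n_runs = 5, seed = 1,
                                temperature = NULL, log = TRUE) {
  if (n_runs < 2) stop("n_runs must be at least 2")
  finals <- vapply(seq_len(n_runs), function(r) {
    optimize_offsets(communities, observed, genomes, iterations = iterations,
      seed = sub_seed(seed, paste0("audit", r)), temperature = temperature,
      log = log)$objective
  }, numeric(1))
  list(cv_percent = 100 * stats::sd(finals) / mean(finals),
    objectives = finals)
}
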