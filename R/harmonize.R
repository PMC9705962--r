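#' Normalize a community abundance matrix to sum 100 per sample
#'
#' Relative abundances are expressed on a 0--100 scale: each sample (row) is
#' rescaled so its taxa sum to exactly 100. Idempotent on already-normalized
#' input.
#'
#' @param x Numeric matrix, samples in rows, taxa in columns; non-negative.
#' @return Matrix of the same shape with rows summing to 100.
#' @export
normalize_community <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundances are not allowed")
  s <- rowSums(x)
  if (any(s == 0)) {
    stop("degenerate input: sample(s) with all-zero abundances: ",
      paste(rownames(x)[s == 0], collapse = ", "))
  }
  x * (100 / s)
}

#' Read a samples-by-taxa community table from TSV
#'
#' The first column holds sample identifiers; the remaining columns are
#' named after taxa. Columns are reordered onto the supplied vocabulary and
#' every row is normalized to sum 100.
#'
#' @param path Path to a tab-separated file.
#' @param vocabulary A taxon vocabulary data frame (default
#'   [taxon_vocabulary()]).
#' @param fold_other If `TRUE`, columns whose name is not in the vocabulary
#'   are summed into the `"Other"` class instead of raising an error.
#' @return Numeric matrix (samples x taxa), rows normalized to 100, columns
#'   in vocabulary order, rownames = sample ids.
#' @export
load_community_table <- function(path, vocabulary = taxon_vocabulary(),
                                 fold_other = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("community table needs a sample column and taxa columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  unknown <- setdiff(colnames(m), vocabulary$name)
  if (length(unknown) > 0 && !fold_other) {
    stop("unknown taxon column(s): ", paste(unknown, collapse = ", "),
      " (set fold_other = TRUE to sum them into 'Other')")
  }
  out <- matrix(0, nrow(m), nrow(vocabulary),
    dimnames = list(ids, vocabulary$name))
  known <- intersect(colnames(m), vocabulary$name)
  out[, known] <- m[, known]
  if (length(unknown) > 0) {
    if (!"Other" %in% vocabulary$name) {
      stop("cannot fold unknown taxa: vocabulary has no 'Other' class")
    }
    out[, "Other"] <- out[, "Other"] + rowSums(m[, unknown, drop = FALSE])
  }
  normalize_community(out)
}

#' Write a community table as TSV
#'
#' @param x Community matrix (samples x taxa) with rownames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_community_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write diet composition tables
#'
#' Diet TSVs have columns `nutrient`, `category`, `value_g_per_kg`.
#'
#' @param path File path.
#' @return `load_diet_table`: a `diet_composition` data frame.
#' @export
load_diet_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("nutrient", "category", "value_g_per_kg")
  if (!all(need %in% names(df))) {
    stop("diet table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  class(df) <- c("diet_composition", "data.frame")
  df
}

#' @rdname load_diet_table
#' @param x A `diet_composition`.
#' @export
write_diet_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

.check_same_nutrients <- function(a, b) {
  if (!identical(a$nutrient, b$nutrient)) {
    stop("diet compositions do not share the same nutrient list")
  }
}

#' Blend two diet compositions
#'
#' Convex per-nutrient combination of a low- and a high-reference diet,
#' modeling feed given as a mixture of pellets:
#' `fraction_high * high + (1 - fraction_high) * low`.
#'
#' @param low,high `diet_composition` objects over the same nutrient list.
#' @param fraction_high Mixing fraction in \[0, 1\].
#' @return A `diet_composition`.
#' @export
blend_diets <- function(low, high, fraction_high) {
  .check_same_nutrients(low, high)
  if (fraction_high < 0 || fraction_high > 1) {
    stop("fraction_high must be in [0, 1]")
  }
  out <- low
  out$value_g_per_kg <- fraction_high * high$value_g_per_kg +
    (1 - fraction_high) * low$value_g_per_kg
  out
}

#' Normalize a diet composition onto the 20--80 band and log2-transform
#'
#' Per nutrient, a linear map sends the smaller of the two reference values
#' to 20 and the larger to 80; the composition's value is mapped through it
#' and then log2-transformed. The anchors leave headroom so diets somewhat
#' outside the reference span remain representable: mapped (pre-log) values
#' anywhere in the closed band \[0, 100\] are accepted, beyond it rejected.
#' Nutrients whose two reference values coincide map to the band midpoint
#' (pre-log 50).
#'
#' @param composition The diet to normalize.
#' @param reference_low,reference_high The two anchor diets (defaults: the
#'   built-in LF and HF references).
#' @return Named numeric vector of log2-normalized diet features
#'   (a "diet vector").
#' @examples
#' build_diet_vector(reference_diet("HF"))[["Kcal/g"]]  # log2(80)
#' @export
build_diet_vector <- function(composition,
                              reference_low = reference_diet("LF"),
                              reference_high = reference_diet("HF")) {
  .check_same_nutrients(composition, reference_low)
  .check_same_nutrients(composition, reference_high)
  lo <- pmin(reference_low$value_g_per_kg, reference_high$value_g_per_kg)
  hi <- pmax(reference_low$value_g_per_kg, reference_high$value_g_per_kg)
  x <- composition$value_g_per_kg
  pre <- ifelse(hi > lo, 20 + (x - lo) / (hi - lo) * 60, 50)
  bad <- pre < 0 | pre > 100
  if (any(bad)) {
    stop("nutrient value(s) outside the representable band: ",
      paste(composition$nutrient[bad], collapse = ", "))
  }
  stats::setNames(log2(pre), composition$nutrient)
}

#' Log2-transform relative abundances
#'
#' @param abundances Non-negative numeric vector or matrix of relative
#'   abundances (sum-100 scale).
#' @param pseudocount Positive additive offset applied before the log so
#'   zeros stay finite (default 0.01, i.e. 1% of one abundance unit).
#' @return `log2(abundances + pseudocount)`, same shape as the input.
#' @export
log2_community <- function(abundances, pseudocount = 0.01) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  log2(abundances + pseudocount)
}

#' Assemble paired diet-response observations into model-ready matrices
#'
#' The interaction-network and regression code operates on three aligned
#' matrices: the diet vectors, the log2 community at the initial timepoint,
#' and the log2 community after the diet period.
#'
#' @param diet Matrix (samples x diet features) of log2-normalized diet
#'   values, or a single diet vector recycled across samples.
#' @param t0,t1 Community matrices (samples x taxa, sum-100 scale), or
#'   matrices already on the log2 scale if `log = FALSE`.
#' @param pseudocount Passed to [log2_community()].
#' @param log Apply the log2 transform to `t0`/`t1`? Set `FALSE` when the
#'   inputs are already log2 abundances.
#' @return A `paired_data` object: list with elements `diet`, `t0`, `t1`
#'   (all log2-scale matrices with shared rownames) and `n`.
#' @export
paired_data <- function(diet, t0, t1, pseudocount = 0.01, log = TRUE) {
  diet <- as.matrix(diet)
  t0 <- as.matrix(t0)
  t1 <- as.matrix(t1)
  if (nrow(t0) != nrow(t1) || nrow(diet) != nrow(t0)) {
    stop("diet, t0 and t1 must have the same number of samples")
  }
  if (!identical(colnames(t0), colnames(t1))) {
    stop("t0 and t1 must share the same taxon columns")
  }
  if (log) {
    t0 <- log2_community(t0, pseudocount)
    t1 <- log2_community(t1, pseudocount)
  }
  structure(
    list(diet = diet, t0 = t0, t1 = t1, n = nrow(t0),
      pseudocount = pseudocount),
    class = "paired_data"
  )
}
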