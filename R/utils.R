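# Internal numerical helpers shared across modules.

# Pearson correlation between the rows of two matrices of equal shape.
# Rows with zero variance on either side get PCC 0; callers decide whether
# to warn about them.
row_pcc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  out <- ifelse(den > 0, num / den, 0)
  attr(out, "degenerate") <- den == 0
  out
}

# Per-sample mean/SD summary of row-wise PCCs (the package-wide convention:
# correlate within each sample across its features, then aggregate).
mean_pcc <- function(pred, obs, warn = TRUE) {
  p <- row_pcc(pred, obs)
  if (warn && any(attr(p, "degenerate"))) {
    warning("zero-variance sample(s); their PCC is defined as 0")
  }
  list(mean = mean(p), sd = stats::sd(p), per_sample = as.numeric(p))
}

# Derive a reproducible integer sub-seed from a base seed and a stream name,
# so adding one generator call does not perturb the draws of another.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Minimum-norm least squares: ordinary QR solution when X has full column
# rank, Moore-Penrose pseudoinverse otherwise.
ls_solve <- function(x, y) {
  qx <- qr(x)
  if (qx$rank == ncol(x)) {
    as.numeric(qr.coef(qx, y))
  } else {
    as.numeric(MASS::ginv(x) %*% y)
  }
}
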