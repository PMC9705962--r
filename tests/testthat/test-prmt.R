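# PRMT metabolome scoring, Fisher-score feature ranking, and top-fraction
# selection.

rn <- function(...) {
  df <- data.frame(...)
  class(df) <- c("reaction_network", "data.frame")
  df
}

test_that("the connection matrix is signed and degree-normalized", {
  # one enzyme producing one metabolite
  w1 <- build_connection_matrix(rn(ec = "E1", metabolite = "M1", sign = 1))
  expect_equal(w1["M1", "E1"], 1)

  # one substrate + one product: entries -1/2 and +1/2
  w2 <- build_connection_matrix(rn(ec = c("E1", "E1"),
    metabolite = c("M1", "M2"), sign = c(-1, 1)))
  expect_equal(w2["M1", "E1"], -0.5)
  expect_equal(w2["M2", "E1"], 0.5)

  # a metabolite not linked to an enzyme has weight 0 there
  w3 <- build_connection_matrix(rn(ec = c("E1", "E2"),
    metabolite = c("M1", "M2"), sign = c(1, 1)))
  expect_equal(w3["M2", "E1"], 0)
  expect_equal(w3["M1", "E2"], 0)

  expect_error(build_connection_matrix(rn(ec = character(0),
    metabolite = character(0), sign = numeric(0))), "empty")
  expect_error(build_connection_matrix(rn(ec = c("E1", "E1"),
    metabolite = c("M1", "M1"), sign = c(1, -1))), "duplicate")
})

test_that("PRMT scores are cohort-centered deviations", {
  w <- build_connection_matrix(rn(ec = "E1", metabolite = "M1", sign = 1))

  # two identical samples sit exactly at the cohort mean: all scores 0
  efp <- rbind(s1 = c(E1 = 5, E2 = 3), s2 = c(E1 = 5, E2 = 3))
  expect_equal(unname(compute_prmt(efp, w)), matrix(0, 2, 1))

  # two samples, one producing enzyme: antisymmetric scores summing to 0
  efp2 <- rbind(s1 = c(E1 = 9, E2 = 1), s2 = c(E1 = 1, E2 = 9))
  sc <- compute_prmt(efp2, w)
  expect_equal(sc["s1", "M1"], -sc["s2", "M1"])
  expect_gt(sc["s1", "M1"], 0)  # more E1 => more capacity to make M1

  # enzymes absent from the network contribute no term: the scores equal
  # the hand formula with only the linked enzyme's deviations
  efp3 <- cbind(efp2, E9 = c(100, 7))
  x <- log2(efp3[, "E1"] / rowSums(efp3) + 1)
  expect_equal(compute_prmt(efp3, w),
    matrix(x - mean(x), 2, 1, dimnames = list(c("s1", "s2"), "M1")))

  # cohort centering: per-metabolite scores sum to 0 across samples
  set.seed(4)
  net <- simulate_reaction_network(4, n_ec = 12, n_metabolites = 20)
  wbig <- build_connection_matrix(net)
  efp4 <- matrix(rexp(8 * 12), 8, 12,
    dimnames = list(paste0("s", 1:8), sprintf("EC%04d", 1:12)))
  scores <- compute_prmt(efp4, wbig)
  expect_lt(max(abs(colSums(scores))), 1e-9)

  expect_error(compute_prmt(efp2[1, , drop = FALSE], w), "2 samples")
})

test_that("Fisher scores match the hand calculation and conventions", {
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(unname(fisher_score(x, labels)["f"]), (5 - 2)^2 / (1 + 1))

  # identical class distributions score 0
  x2 <- cbind(f = c(1, 2, 3, 1, 2, 3))
  expect_equal(unname(fisher_score(x2, labels)), 0)

  # globally constant feature: 0/0 convention
  x3 <- cbind(f = rep(2, 6))
  expect_equal(unname(fisher_score(x3, labels)), 0)

  # perfectly separated constant classes: +Inf ordering rank
  x4 <- cbind(f = c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(fisher_score(x4, labels)), Inf)

  # shift invariance
  expect_equal(fisher_score(x + 100, labels), fisher_score(x, labels))

  expect_error(fisher_score(x[1:3, , drop = FALSE], c(0, 0, 1)), "class")
})

test_that("top-fraction selection uses the ceiling and lexical ties", {
  s <- c(a = 1, b = 1, c = 0)
  expect_equal(select_top_fraction(s, 0.05), "a")  # ceil(0.15) = 1, tie -> a
  expect_setequal(select_top_fraction(s, 1), c("a", "b", "c"))
  expect_equal(length(select_top_fraction(stats::setNames(rnorm(10),
    paste0("m", 1:10)), 0.05)), 1)  # ceil(0.5) = 1
  big <- stats::setNames(seq_len(2560), sprintf("M%04d", seq_len(2560)))
  expect_equal(length(select_top_fraction(big, 0.05)), 128)
  expect_error(select_top_fraction(s, 0), "fraction")
})
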