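# Enzyme-function-profile prediction and the stochastic hill-climbing
# offset optimizer.

toy_genomes <- function(ave, sd = ave * 0) {
  genome_function_matrix(ave, sd)
}

test_that("EFP prediction is the community-weighted genome sum", {
  g <- toy_genomes(matrix(c(2, 0), 2, 1,
    dimnames = list(c("A", "B"), "EC0001")))
  expect_equal(unname(predict_efp(c(A = 50, B = 50), g)[1, 1]), 100)

  # zero offsets reduce to the plain prediction
  g2 <- genome_function_matrix(
    matrix(c(2, 0), 2, 1, dimnames = list(c("A", "B"), "EC0001")),
    matrix(c(1, 1), 2, 1, dimnames = list(c("A", "B"), "EC0001")))
  e0 <- matrix(0, 2, 1, dimnames = dimnames(g2$ave))
  expect_equal(predict_efp(c(A = 50, B = 50), g2, e0),
    predict_efp(c(A = 50, B = 50), g2))

  # single taxon with an offset: (1 + 0.5) * 100 = 150
  g3 <- genome_function_matrix(
    matrix(1, 1, 1, dimnames = list("A", "EC0001")),
    matrix(1, 1, 1, dimnames = list("A", "EC0001")))
  e3 <- matrix(0.5, 1, 1, dimnames = dimnames(g3$ave))
  expect_equal(unname(predict_efp(c(A = 100), g3, e3)[1, 1]), 150)

  # dimension mismatch and offset-bound violations are rejected
  expect_error(predict_efp(c(A = 50), g), "taxa")
  eBad <- matrix(2, 1, 1, dimnames = dimnames(g3$ave))
  expect_error(predict_efp(c(A = 100), g3, eBad), "SD")
})

test_that("EFP correlation follows the per-sample convention", {
  obs <- rbind(s1 = c(10, 20, 30, 5), s2 = c(4, 2, 8, 1))
  expect_equal(evaluate_efp_pcc(obs, obs)$mean, 1)

  # hand-computed per-sample PCCs on raw values
  prd <- rbind(s1 = c(12, 18, 33, 6), s2 = c(5, 1, 9, 2))
  r <- evaluate_efp_pcc(prd, obs, log = FALSE)
  hand <- c(cor(prd[1, ], obs[1, ]), cor(prd[2, ], obs[2, ]))
  expect_equal(r$per_sample, hand)
  expect_equal(r$mean, mean(hand))

  # Pearson is invariant under positive scaling of the predictions
  expect_equal(evaluate_efp_pcc(prd * 7, obs, log = FALSE)$mean, r$mean)
})

test_that("offset optimization starts at zero and only improves", {
  s <- simulate_metagenome_study(11, n_taxa = 5, n_ec = 20, n_samples = 15,
    noise = 0)
  # zero iterations: offsets stay zero, objective equals the baseline
  o0 <- optimize_offsets(s$communities, s$efp, s$genomes, iterations = 0,
    seed = 1)
  expect_true(all(o0$offsets == 0))
  expect_equal(o0$objective, o0$baseline)

  o <- optimize_offsets(s$communities, s$efp, s$genomes, iterations = 1000,
    seed = 1)
  expect_gte(o$objective, o$baseline)
  expect_false(is.unsorted(o$trace))
  expect_true(all(abs(o$offsets) <= s$genomes$sd + 1e-9))

  # all-zero SD: nothing to optimize
  g0 <- toy_genomes(s$genomes$ave)
  expect_warning(oz <- optimize_offsets(s$communities, s$efp, g0,
    iterations = 10, seed = 1), "zero")
  expect_true(all(oz$offsets == 0))
})

test_that("a one-cell problem converges to the known offset", {
  # single taxon at abundance 100, AveEC = 1, SD = 1, observed EFP = 150:
  # the objective (RMSE for this degenerate width) is maximized at e = 0.5
  g <- genome_function_matrix(
    matrix(1, 1, 1, dimnames = list("A", "EC0001")),
    matrix(1, 1, 1, dimnames = list("A", "EC0001")))
  comm <- matrix(100, 1, 1, dimnames = list("s1", "A"))
  obs <- matrix(150, 1, 1, dimnames = list("s1", "EC0001"))
  o <- optimize_offsets(comm, obs, g, iterations = 500, seed = 6)
  expect_lt(abs(o$offsets[1, 1] - 0.5), 0.05)
})

test_that("optimization recovers planted offsets on clean data", {
  s <- simulate_metagenome_study(17, n_taxa = 5, n_ec = 20, n_samples = 20,
    noise = 0)
  o <- optimize_offsets(s$communities, s$efp, s$genomes, iterations = 2000,
    seed = 2)
  expect_gt(o$objective, o$baseline)
  expect_gt(cor(as.numeric(o$offsets), as.numeric(s$offsets)), 0.5)
})

test_that("the variation audit reports a small coefficient of variation", {
  s <- simulate_metagenome_study(23, n_taxa = 5, n_ec = 20, n_samples = 15,
    noise = 0)
  aud <- run_variation_audit(s$communities, s$efp, s$genomes,
    iterations = 800, n_runs = 5, seed = 3)
  expect_length(aud$objectives, 5)
  expect_lt(aud$cv_percent, 5)
  expect_error(run_variation_audit(s$communities, s$efp, s$genomes,
    n_runs = 1), "n_runs")
})
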