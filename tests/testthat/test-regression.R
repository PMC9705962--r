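# MAP regression fitting, prediction, evaluation, cross-validation, and
# nutrient-category enrichment.

test_that("least squares recovers a hand-solvable single-parent model", {
  # taxon A depends on dietX with slope 2, intercept 0: {(1,2),(2,4),(3,6)}
  diet <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "dietX"))
  t0 <- matrix(rnorm(3), 3, 1, dimnames = list(NULL, "A"))
  t1 <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "A"))
  pd <- make_paired(diet, t0, t1)
  net <- interaction_network("dietX", "A", list(A = "diet:dietX"))
  m <- fit_map_regression(net, pd)
  expect_equal(unname(m$coef$A), c(0, 2), tolerance = 1e-10)

  # a taxon with no parents reduces to its mean
  net0 <- interaction_network("dietX", "A")
  m0 <- fit_map_regression(net0, pd)
  expect_equal(unname(m0$coef$A), mean(c(2, 4, 6)))
})

test_that("noise-free data with the true network gives exact weights", {
  s <- simulate_diet_study(3, noise_sd = 0)
  pd <- study_paired_data(s, from_truth = TRUE)
  m <- fit_map_regression(s$truth$network, pd)
  for (tx in m$taxa) {
    expect_equal(m$coef[[tx]],
      s$truth$weights$coef[[tx]][names(m$coef[[tx]])],
      tolerance = 1e-6)
  }
})

test_that("the dense regression pads uninformative predictors with ~0", {
  # informative dietX plus constant extra predictors; minimum-norm fit
  diet <- cbind(dietX = c(1, 2, 3, 4), dietC = 1)
  t0 <- matrix(2, 4, 2, dimnames = list(NULL, c("A", "B")))
  t1 <- cbind(A = c(2, 4, 6, 8), B = c(1, 1, 1, 1))
  pd <- make_paired(diet, t0, t1)
  m <- suppressWarnings(fit_nonnetwork_regression(pd))  # n < p: minimum-norm
  expect_equal(m$variant, "dense")
  expect_equal(length(m$parents$A), 4)  # every diet + t0 predictor
  expect_equal(m$coef$A[["diet:dietX"]], 2, tolerance = 1e-8)
  # fitted values reproduce the consistent system exactly
  pred <- predict_community(m, pd$diet, 2^pd$t0 - 0.01)
  expect_equal(unname(attr(pred, "log2")[, "A"]), c(2, 4, 6, 8),
    tolerance = 1e-8)

  # intercept-only data predicts the mean
  t1b <- cbind(A = c(3, 5, 3, 5), B = 1)
  pdb <- make_paired(cbind(dietC = rep(1, 4)),
    matrix(2, 4, 2, dimnames = list(NULL, c("A", "B"))), t1b)
  mb <- fit_nonnetwork_regression(pdb)
  predb <- predict_community(mb, pdb$diet, 2^pdb$t0 - 0.01)
  expect_equal(unname(attr(predb, "log2")[, "A"]), rep(4, 4),
    tolerance = 1e-8)
})

test_that("prediction evaluates time-t parents in topological order", {
  # chain: A <- dietX (w=1, c=0); B <- A (w=1, c=0)
  net <- interaction_network("dietX", c("A", "B"),
    list(A = "diet:dietX", B = "t1:A"))
  m <- obesonet:::new_map_regression("network",
    list(A = c(intercept = 0, `diet:dietX` = 1),
      B = c(intercept = 0, `t1:A` = 1)),
    net$parents, "dietX", c("A", "B"))
  m$network <- net
  v <- 3.7
  pred <- predict_community(m, c(dietX = v), c(A = 40, B = 60))
  expect_equal(unname(attr(pred, "log2")[1, ]), c(v, v))
  expect_equal(sum(pred), 100)
})

test_that("mean per-sample PCC follows the hand-computed convention", {
  # sample 1: identical vectors (PCC 1); sample 2: cor((1,2,3),(1,3,2)) = 0.5
  pc <- 0.01
  obs_log2 <- rbind(c(1, 2, 3), c(1, 3, 2))
  prd_log2 <- rbind(c(1, 2, 3), c(1, 2, 3))
  obs <- 2^obs_log2 - pc
  prd <- 2^prd_log2 - pc
  r <- evaluate_mean_pcc(prd, obs, pseudocount = pc)
  expect_equal(r$per_sample, c(1, 0.5))
  expect_equal(r$mean, 0.75)
  expect_equal(r$sd, stats::sd(c(1, 0.5)))

  # identical communities: mean 1, sd 0
  r1 <- evaluate_mean_pcc(obs, obs, pseudocount = pc)
  expect_equal(r1$mean, 1)
  expect_equal(r1$sd, 0)

  # anti-correlated sample
  r2 <- evaluate_mean_pcc(2^rbind(c(3, 2, 1)) - pc, 2^rbind(c(1, 2, 3)) - pc,
    pseudocount = pc)
  expect_equal(r2$mean, -1)

  # zero-variance sample -> PCC 0 with a warning
  expect_warning(
    r3 <- evaluate_mean_pcc(2^rbind(c(2, 2, 2)) - pc, 2^rbind(c(1, 2, 3)) - pc,
      pseudocount = pc),
    "zero-variance")
  expect_equal(r3$mean, 0)
})

test_that("cross-validation partitions samples into disjoint folds", {
  study <- simulate_diet_study(13, n_mice = 10)
  pd <- study_paired_data(study)
  cv <- suppressWarnings(cross_validate(pd, "dense", n_folds = 5, seed = 4))
  folds <- attr(cv, "folds")
  expect_equal(lengths(folds), rep(2L, 5), ignore_attr = TRUE)
  expect_equal(sort(unname(unlist(folds))), 1:10)
  cv2 <- suppressWarnings(cross_validate(pd, "dense", n_folds = 5, seed = 4))
  expect_identical(attr(cv, "folds"), attr(cv2, "folds"))
  expect_error(cross_validate(pd, "dense", n_folds = 6, seed = 1), "fold")
})

test_that("a noise-free study cross-validates almost perfectly", {
  study <- simulate_diet_study(8, noise_sd = 0)
  pd <- study_paired_data(study, from_truth = TRUE)
  cv <- cross_validate(pd, "network", restarts = 2, seed = 5)
  expect_gt(attr(cv, "mean_test"), 0.99)
})

test_that("nutrient enrichment reproduces the hand hypergeometric", {
  feats <- paste0("f", 1:10)
  cats <- stats::setNames(rep(c("vitamin", "mineral"), each = 5), feats)
  taxa <- c("A", "B", "C", "D")
  # 4 diet nodes in the network, all vitamins
  net <- interaction_network(feats, taxa,
    list(A = c("diet:f1", "diet:f2"), B = c("diet:f3", "diet:f4")))
  enr <- nutrient_enrichment(net, categories = cats)
  expect_equal(enr$p_value[enr$category == "vitamin"],
    choose(5, 4) * choose(5, 0) / choose(10, 4))
  # k = 0 has upper-tail probability 1
  expect_equal(enr$p_value[enr$category == "mineral"], 1)
  # an empty network gives p = 1 everywhere
  enr0 <- nutrient_enrichment(interaction_network(feats, taxa),
    categories = cats)
  expect_equal(enr0$p_value, c(1, 1))
  # a saturated draw gives p = 1 everywhere
  netF <- interaction_network(feats, taxa, list(
    A = paste0("diet:", feats[1:5]), B = paste0("diet:", feats[6:10])))
  enrF <- nutrient_enrichment(netF, categories = cats)
  expect_equal(enrF$p_value, c(1, 1))
})
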