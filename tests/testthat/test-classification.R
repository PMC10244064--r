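# small feature matrices for classifier tests
make_separable <- function(n_per = 17, margin = 0.5, p_noise = 8,
                           seed = 101) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(2 * n_per * p_noise), 2 * n_per,
                            dimnames = list(NULL, paste0("f", 1:p_noise))))
  x$sep <- c(runif(n_per, margin / 2, 1), runif(n_per, -1, -margin / 2))
  list(features = x, labels = rep(c("left", "right"), each = n_per))
}

make_noise <- function(n_per = 17, p = 9, seed = 102) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(2 * n_per * p), 2 * n_per,
                            dimnames = list(NULL, paste0("f", 1:p))))
  list(features = x, labels = rep(c("left", "right"), each = n_per))
}

test_that("a perfectly separating feature yields near-perfect accuracy", {
  d <- make_separable()
  run <- run_repeated_cv(d$features, d$labels, n_iter = 50, seed = 1)
  expect_gt(run$mean_accuracy, 0.95)
})

test_that("pure-noise features stay at chance", {
  d <- make_noise()
  run <- run_repeated_cv(d$features, d$labels, n_iter = 300, seed = 2)
  expect_lt(abs(run$mean_accuracy - 0.5),
            3 * run$sd_accuracy / sqrt(run$n_iter) + 0.02)
})

test_that("per-iteration metrics satisfy the contingency identities", {
  d <- make_separable(n_per = 12, margin = 0.1)
  run <- run_repeated_cv(d$features, d$labels, n_iter = 40, seed = 3)
  tot <- run$contingency
  expect_equal(sum(tot), 24 * 40)  # every patient predicted every iteration
  expect_equal(run$mean_accuracy, mean(run$accuracy))
  expect_equal(unname((tot["TP"] + tot["TN"]) / sum(tot)),
               mean(run$accuracy), tolerance = 1e-12)
  # spot-check with a one-iteration run
  r1 <- run_repeated_cv(d$features, d$labels, n_iter = 1, seed = 4)
  ct <- r1$contingency
  expect_equal(r1$sensitivity, unname(ct["TP"] / (ct["TP"] + ct["FN"])))
  expect_equal(r1$specificity, unname(ct["TN"] / (ct["TN"] + ct["FP"])))
  expect_equal(r1$ppv, unname(ct["TP"] / (ct["TP"] + ct["FP"])))
  expect_equal(r1$npv, unname(ct["TN"] / (ct["TN"] + ct["FN"])))
})

test_that("identical seed and matrix reproduce the run bit for bit", {
  d <- make_noise(n_per = 12)
  r1 <- run_repeated_cv(d$features, d$labels, n_iter = 25, seed = 7)
  r2 <- run_repeated_cv(d$features, d$labels, n_iter = 25, seed = 7)
  expect_identical(r1, r2)
  r3 <- run_shuffle_null(d$features, d$labels, n_iter = 25, seed = 7)
  r4 <- run_shuffle_null(d$features, d$labels, n_iter = 25, seed = 7)
  expect_identical(r3, r4)
})

test_that("swapping the positive class swaps sensitivity and PPV pairs", {
  d <- make_separable(n_per = 13, margin = 0.05)
  rl <- run_repeated_cv(d$features, d$labels, n_iter = 20, seed = 5,
                        positive = "left")
  rr <- run_repeated_cv(d$features, d$labels, n_iter = 20, seed = 5,
                        positive = "right")
  expect_equal(rl$sensitivity, rr$specificity)
  expect_equal(rl$specificity, rr$sensitivity)
  expect_equal(rl$ppv, rr$npv)
  expect_equal(rl$npv, rr$ppv)
  expect_equal(rl$accuracy, rr$accuracy)
})

test_that("the shuffle null collapses even a separable matrix to chance", {
  d <- make_separable()
  run <- run_shuffle_null(d$features, d$labels, n_iter = 300, seed = 6)
  expect_lt(abs(run$mean_accuracy - 0.5),
            3 * run$sd_accuracy / sqrt(run$n_iter) + 0.02)
})

test_that("an unbalanced cohort's shuffle null sits above one half", {
  set.seed(60)
  x <- as.data.frame(matrix(rnorm(60 * 5), 60,
                            dimnames = list(NULL, paste0("f", 1:5))))
  labels <- rep(c("left", "right"), c(40, 20))
  run <- run_shuffle_null(x, labels, n_iter = 200, seed = 8)
  expect_gt(run$mean_accuracy, 0.5)
})

test_that("run comparison: identity, separable vs null, and ordering", {
  d <- make_separable(n_per = 17, margin = 0.4)
  r_sep <- run_repeated_cv(d$features, d$labels, n_iter = 100, seed = 9)
  r_nul <- run_shuffle_null(d$features, d$labels, n_iter = 100, seed = 10)
  same <- compare_runs(a = r_sep, b = r_sep)
  expect_equal(same$contrasts$diff, 0)
  expect_equal(same$contrasts$p, 1)
  two <- compare_runs(model = r_sep, null = r_nul)
  expect_lt(two$contrasts$p_adj, 0.001)
  # three runs: noise-only, +separating feature, shuffle
  dn <- make_noise(n_per = 17)
  r_noise <- run_repeated_cv(dn$features, dn$labels, n_iter = 100,
                             seed = 11)
  three <- compare_runs(sep = r_sep, noise = r_noise, null = r_nul)
  expect_lt(three$anova_p, 1e-6)
  ord <- sort(three$means, decreasing = TRUE)
  expect_equal(names(ord)[1], "sep")
  expect_true(all(three$contrasts$p_adj >= three$contrasts$p - 1e-12))
  expect_error(compare_runs(a = r_sep,
                            b = run_shuffle_null(d$features, d$labels,
                                                 n_iter = 37, seed = 1)),
               "same number of iterations")
})

test_that("Fisher's exact p matches hypergeometric enumeration", {
  expect_equal(contingency_significance(c(10, 0, 0, 10)),
               oracle_fisher_p(c(10, 0, 0, 10)), tolerance = 1e-9)
  expect_lt(contingency_significance(c(10, 0, 0, 10)), 2e-5)
  expect_equal(contingency_significance(c(5, 5, 5, 5)), 1)
  p <- contingency_significance(c(23, 11, 12, 22))
  expect_equal(p, oracle_fisher_p(c(23, 11, 12, 22)), tolerance = 1e-9)
  expect_lt(p, 0.05)
  # zero-margin table: no association measurable
  expect_equal(contingency_significance(c(0, 0, 7, 9)), 1)
})

test_that("predictor importance singles out the informative feature", {
  d <- make_separable(n_per = 17, margin = 0.5)
  run <- run_repeated_cv(d$features, d$labels, n_iter = 40, seed = 12)
  imp <- predictor_importance(run)
  expect_equal(unname(imp["sep"]), 1)
  expect_true(all(imp[names(imp) != "sep"] < 0.3))
  # a constant feature is never selected
  d$features$const <- 1
  run2 <- run_repeated_cv(d$features, d$labels, n_iter = 40, seed = 13)
  expect_equal(unname(predictor_importance(run2)["const"]), 0)
})

test_that("duplicated separating features share importance", {
  d <- make_separable(n_per = 17, margin = 0.5, p_noise = 4)
  single <- run_repeated_cv(d$features, d$labels, n_iter = 60, seed = 14)
  imp_single <- colMeans(single$importance_raw)
  d2 <- d
  d2$features$sep2 <- d2$features$sep
  dup <- run_repeated_cv(d2$features, d2$labels, n_iter = 60, seed = 15)
  imp_dup <- colMeans(dup$importance_raw)
  ratio <- (imp_dup[["sep"]] + imp_dup[["sep2"]]) / imp_single[["sep"]]
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("degenerate matrices are rejected", {
  d <- make_noise(n_per = 12)
  expect_error(run_repeated_cv(d$features, rep("left", 24)), "single-class")
  expect_error(run_repeated_cv(d$features[c(1:3, 13:15), ],
                               d$labels[c(1:3, 13:15)]),
               "at least 10")
  dd <- d$features
  dd$f1[1] <- Inf
  expect_error(run_repeated_cv(dd, d$labels), "finite")
})

test_that("the low-IED-asymmetry subset promotes spindle density", {
  # IED LI is strongly lateralizing for half the cohort and ~0 for the rest;
  # sp_density is moderately informative throughout
  set.seed(70)
  n_per <- 20
  lab <- rep(c("left", "right"), each = n_per)
  sgn <- ifelse(lab == "left", 1, -1)
  strong <- rep(c(TRUE, FALSE), n_per)
  x <- data.frame(
    sp_density = sgn * 0.25 + rnorm(2 * n_per, 0, 0.25),
    sw_amplitude = rnorm(2 * n_per, 0, 0.3),
    ied_rate = ifelse(strong, sgn * 0.8 + rnorm(2 * n_per, 0, 0.05),
                      rnorm(2 * n_per, 0, 0.02)))
  full <- run_repeated_cv(x, lab, n_iter = 60, seed = 16)
  expect_gt(predictor_importance(full)[["ied_rate"]], 0.2)
  sub <- low_asymmetry_subset(x, lab, n_iter = 60, seed = 17)
  expect_false(sub$empty)
  expect_equal(sub$n_subset, n_per)
  expect_gt(sub$importance[["sp_density"]], sub$importance[["ied_rate"]])
  dt <- sub$importance_test
  row <- dt[dt$group1 == "sp_density", ]
  expect_lt(row$p_adj, 0.001)
})

test_that("low-asymmetry subset handles degenerate IED distributions", {
  set.seed(71)
  n_per <- 12
  lab <- rep(c("left", "right"), each = n_per)
  x <- data.frame(sp_density = ifelse(lab == "left", 0.4, -0.4) +
                    rnorm(2 * n_per, 0, 0.1),
                  ied_rate = rep(0.3, 2 * n_per))
  # all |LI| equal: strict inequality leaves an empty subset
  res <- low_asymmetry_subset(x, lab, n_iter = 10, seed = 18)
  expect_true(res$empty)
  # uninformative but varying IED: subset ~ half the cohort, sp_density
  # importance keeps the lead
  x2 <- x
  set.seed(72)
  x2$ied_rate <- rnorm(2 * n_per, 0, 0.05)
  res2 <- low_asymmetry_subset(x2, lab, n_iter = 30, seed = 19)
  expect_false(res2$empty)
  expect_equal(res2$n_subset, n_per)
  expect_gt(res2$importance[["sp_density"]],
            res2$importance[["ied_rate"]])
})
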