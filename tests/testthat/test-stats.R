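# Rank-statistic engines against independent oracles: base cor.test /
# wilcox.test, brute-force pair counting, and pROC for DeLong intervals.

test_that("spearman_cor matches rank-then-Pearson and base cor.test", {
  set.seed(11)
  # perfect antitone relation
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)

  for (i in 1:25) {
    n <- sample(12:60, 1)
    x <- sample(1:20, n, replace = TRUE)         # ties likely
    y <- x + rnorm(n, 0, 5)
    got <- spearman_cor(x, y)
    expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("small-sample spearman p is the exact permutation value", {
  set.seed(3)
  for (i in 1:5) {
    x <- sample(1:100, 6)  # distinct values: comparable with exact cor.test
    y <- sample(1:100, 6)
    got <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("spearman_cor applies pairwise deletion and flags degeneracy", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, 1, 4, NA, 5, 6)
  got <- spearman_cor(x, y)
  expect_equal(got$n, 4L)
  keep <- !is.na(x) & !is.na(y)
  expect_equal(got$rho, cor(x[keep], y[keep], method = "spearman"))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "3 complete pairs")
})

test_that("mann_whitney U equals the brute-force pairwise count", {
  set.seed(5)
  for (i in 1:40) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x1 <- sample(1:8, n1, replace = TRUE)
    x2 <- sample(1:8, n2, replace = TRUE)
    got <- mann_whitney(c(x1, x2), rep(c(TRUE, FALSE), c(n1, n2)))
    brute <- sum(outer(x1, x2, ">")) + 0.5 * sum(outer(x1, x2, "=="))
    expect_equal(got$U, brute)
  }
})

test_that("mann_whitney normal-approximation p matches wilcox.test", {
  set.seed(6)
  for (i in 1:20) {
    n1 <- sample(9:30, 1); n2 <- sample(9:30, 1)
    x1 <- sample(1:10, n1, replace = TRUE)
    x2 <- sample(1:10, n2, replace = TRUE) + rbinom(n2, 1, 0.5)
    got <- mann_whitney(c(x1, x2), rep(c(TRUE, FALSE), c(n1, n2)))
    ref <- suppressWarnings(
      wilcox.test(x1, x2, exact = FALSE, correct = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("mann_whitney exact path: symmetry and complete separation", {
  # identical groups: U at its null mean, p = 1
  got <- mann_whitney(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(got$U, 4.5)
  expect_equal(got$p, 1)

  # complete separation with n1 = n2 = 3: 2 of the 20 arrangements are as
  # extreme, so the exact two-sided p is 0.1
  got <- mann_whitney(c(10, 11, 12, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(got$U, 9)
  expect_equal(got$p, 0.1)

  expect_error(mann_whitney(1:4, rep(TRUE, 4)), "empty")
})

test_that("mRS dichotomies and distribution summary follow the scale", {
  expect_true(dichotomize_mrs(2, 2))
  expect_false(dichotomize_mrs(3, 2))
  expect_error(dichotomize_mrs(2, 5), "k must be")
  expect_error(dichotomize_mrs(7, 2), "0-6")

  s <- mrs_distribution_summary(mrs_from_counts(c(226, 256, 209, 232, 124,
                                                  39, 192)))
  expect_equal(s$n, 1278L)
  expect_equal(s$fi_count, 691L)
  expect_equal(round(s$fi_percent), 54)

  expect_equal(mrs_distribution_summary(rep(6, 5))$fi_count, 0L)
  s <- mrs_distribution_summary(c(0, 0, 6))
  expect_equal(s$fi_count, 2L)
  expect_equal(s$fi_percent, 200 / 3)
  expect_error(mrs_distribution_summary(c(1, 9)), "0-6")
})

test_that("roc_auc equals brute-force concordance and the U identity", {
  set.seed(8)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(T, F), 5))$auc, 0.5)

  for (i in 1:30) {
    n <- sample(10:30, 1)
    score <- sample(0:90, n, replace = TRUE)
    good <- runif(n) < 0.5
    if (length(unique(good)) < 2) next
    r <- roc_auc(score, good)
    xs <- score[good]; ys <- score[!good]
    conc <- (sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))) /
      (r$n_pos * r$n_neg)
    expect_equal(r$auc, conc, tolerance = 1e-12)
    U <- mann_whitney(score, good)$U
    expect_equal(r$auc * r$n_pos * r$n_neg, U, tolerance = 1e-12)
    # curve shape invariants
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  set.seed(9)
  for (f in list(function(x) 3 * x + 1, exp, function(x) x^3)) {
    score <- rnorm(50)
    good <- runif(50) < 0.4
    expect_equal(roc_auc(f(score), good)$auc, roc_auc(score, good)$auc,
                 tolerance = 1e-12)
  }
})

test_that("DeLong interval matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:5) {
    score <- sample(0:90, 80, replace = TRUE)
    good <- runif(80) < plogis((score - 45) / 15)
    r <- roc_auc(score, good)
    pr <- pROC::roc(good, score, quiet = TRUE, direction = "<")
    ci <- pROC::ci.auc(pr, method = "delong")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$ci_low, max(0, ci[1]), tolerance = 1e-9)
    expect_equal(r$ci_high, min(1, ci[3]), tolerance = 1e-9)
  }
})

test_that("logistic fit recovers, reports c-statistic, flags separation", {
  set.seed(12)
  # intercept-only, balanced outcome
  d0 <- data.frame(y = rep(c(TRUE, FALSE), 50))
  f0 <- fit_logistic(d0, "y", character(0))
  expect_equal(f0$coefficients$estimate[1], 0, tolerance = 1e-6)
  expect_equal(f0$c_statistic, 0.5)

  # known coefficients
  n <- 2000
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = rnorm(n))
  eta <- -0.5 + 1 * d$x1 - 0.8 * d$x2 + 0.3 * d$x3
  d$y <- runif(n) < plogis(eta)
  fit <- fit_logistic(d, "y", c("x1", "x2", "x3"))
  truth <- c(-0.5, 1, -0.8, 0.3)
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    3 * fit$coefficients$se))
  expect_equal(fit$n_used, n)

  # listwise deletion only over model columns
  d$x1[1:100] <- NA
  expect_equal(fit_logistic(d, "y", c("x1", "x2", "x3"))$n_used, n - 100)

  # perfectly predictive feature
  ds <- data.frame(y = rep(c(TRUE, FALSE), each = 20),
                   z = rep(c(1, 0), each = 20), w = rnorm(40))
  expect_warning(fit_logistic(ds, "y", c("z", "w")), "separation")

  expect_error(fit_logistic(data.frame(y = rep(TRUE, 20), x = rnorm(20)),
                            "y", "x"), "constant outcome")
  expect_error(fit_logistic(data.frame(y = rep(c(TRUE, FALSE), 10),
                                       x = rep(1, 20)), "y", "x"),
               "constant predictor")
})

test_that("subgroup table signs, self-split, and pairwise deletion", {
  set.seed(13)
  n <- 300
  d <- data.frame(daoh = sample(0:90, n, replace = TRUE))
  d$mrs90 <- pmax(0, pmin(6, round(6 - d$daoh / 15 + rnorm(n))))
  d$self <- d$daoh > median(d$daoh)
  d$noise_flag <- runif(n) < 0.5
  d$cont <- rnorm(n, 50, 10)

  tab <- subgroup_table(d, c(self = "flag", noise_flag = "flag",
                             cont = "continuous"))
  self_row <- tab[tab$factor == "self", ]
  expect_gt(self_row$daoh_difference, 0)
  expect_lt(self_row$daoh_p, 1e-10)

  # relabelling present/absent flips every difference sign exactly
  d2 <- d; d2$noise_flag <- !d2$noise_flag
  t1 <- subgroup_table(d, c(noise_flag = "flag"))
  t2 <- subgroup_table(d2, c(noise_flag = "flag"))
  expect_equal(t1$daoh_difference, -t2$daoh_difference)
  expect_equal(t1$mrs_difference, -t2$mrs_difference)
  expect_equal(t1$daoh_p, t2$daoh_p)

  # sign convention: difference = present median - absent median
  expect_equal(self_row$daoh_difference,
               self_row$daoh_present - self_row$daoh_absent)

  # missingness in one factor leaves other rows untouched
  d3 <- d; d3$noise_flag[1:50] <- NA
  t3 <- subgroup_table(d3, c(self = "flag", noise_flag = "flag"))
  expect_equal(t3[t3$factor == "self", ], tab[tab$factor == "self", ])
  expect_equal(t3$n_present[t3$factor == "noise_flag"] +
                 t3$n_absent[t3$factor == "noise_flag"], n - 50)

  # single-level factor: difference unavailable, row still emitted
  d$onelevel <- TRUE
  t4 <- subgroup_table(d, c(onelevel = "flag"))
  expect_true(is.na(t4$daoh_difference))
  expect_equal(t4$n_absent, 0L)
})

test_that("null factors give small differences and calibrated p-values", {
  set.seed(14)
  ps <- replicate(40, {
    n <- 200
    d <- data.frame(daoh = sample(0:90, n, replace = TRUE),
                    mrs90 = sample(0:6, n, replace = TRUE),
                    flag = runif(n) < 0.5)
    subgroup_table(d, c(flag = "flag"))$daoh_p
  })
  # roughly uniform: around 5% significant, not clustered at 0
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.25)
})
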