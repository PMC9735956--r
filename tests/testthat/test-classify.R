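# ECD labelling, SVM Monte Carlo cross-validation, correlation report.

two_cluster_data <- function(n_per = 10, gap = 50, sd = 1, seed = 2) {
  set.seed(seed)
  data.frame(
    class = factor(rep(c("damaged", "intact"), each = n_per),
                   levels = c("damaged", "intact")),
    S_Elev_ps = c(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd)),
    S_Phys_ps = c(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd)))
}

test_that("ECD labelling is strict at the 3000 cells/mm^2 threshold", {
  expect_equal(as.character(label_from_ecd(3500)), "intact")
  expect_equal(as.character(label_from_ecd(3000)), "damaged")
  expect_equal(as.character(label_from_ecd(1)), "damaged")
  expect_error(label_from_ecd(-5), "positive")
})

test_that("perfectly separated clusters classify with AUC 1 and zero spread", {
  dat <- two_cluster_data()
  m <- thz_svm(class ~ S_Elev_ps + S_Phys_ps, dat, n_iter = 40, seed = 1)
  expect_equal(m$auc_mean, 1)
  expect_equal(m$auc_sd, 0)
  expect_error(thz_svm(class ~ 0, dat, n_iter = 2, seed = 1), "predictor")
})

test_that("results are bit-reproducible under the master seed", {
  dat <- two_cluster_data(gap = 2)
  a <- thz_svm(class ~ S_Elev_ps, dat, n_iter = 30, seed = 7)
  b <- thz_svm(class ~ S_Elev_ps, dat, n_iter = 30, seed = 7)
  cc <- thz_svm(class ~ S_Elev_ps, dat, n_iter = 30, seed = 8)
  expect_identical(a$aucs, b$aucs)
  expect_identical(a$roc, b$roc)
  expect_false(identical(a$aucs, cc$aucs))
})

test_that("per-iteration AUCs are invariant to a positive rescaling of features", {
  dat <- two_cluster_data(gap = 2)
  a <- thz_svm(class ~ S_Elev_ps + S_Phys_ps, dat, n_iter = 25, seed = 3)
  dat2 <- dat
  dat2$S_Elev_ps <- 37 * dat2$S_Elev_ps
  dat2$S_Phys_ps <- 37 * dat2$S_Phys_ps
  b <- thz_svm(class ~ S_Elev_ps + S_Phys_ps, dat2, n_iter = 25, seed = 3)
  expect_identical(a$aucs, b$aucs)
})

test_that("with scores held fixed, flipping labels maps AUC to 1 - AUC", {
  # Mann-Whitney oracle on the retained per-iteration decision scores:
  # the recorded AUC must equal the pairwise-comparison statistic, and
  # flipping the test labels under the same scores must give 1 - AUC
  dat <- two_cluster_data(gap = 1.5)
  m <- thz_svm(class ~ S_Elev_ps + S_Phys_ps, dat, n_iter = 20, seed = 5,
               keep_scores = TRUE)
  mw_auc <- function(score, label) {
    pos <- score[label == "intact"]; neg <- score[label == "damaged"]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (i in c(1, 7, 20)) {
    s <- m$scores[m$scores$iteration == i, ]
    expect_equal(m$aucs[i], mw_auc(s$score, s$label), tolerance = 1e-12)
    flipped <- factor(ifelse(s$label == "intact", "damaged", "intact"),
                      levels = c("damaged", "intact"))
    expect_equal(mw_auc(s$score, flipped), 1 - m$aucs[i], tolerance = 1e-12)
  }
})

test_that("mean ROC is a monotone curve through (0,0) and (1,1)", {
  dat <- two_cluster_data(gap = 1)
  m <- thz_svm(class ~ S_Elev_ps, dat, n_iter = 30, seed = 11)
  expect_equal(m$roc$tpr_mean[1], 0)
  expect_equal(m$roc$tpr_mean[length(m$roc$tpr_mean)], 1)
  expect_true(all(diff(m$roc$tpr_mean) >= -1e-12))
  expect_true(all(m$aucs >= 0 & m$aucs <= 1))
  expect_length(m$aucs, 30)
})

test_that("AUC at 2-SD class separation matches the Gaussian closed form", {
  # two unit-variance Gaussian classes whose means differ by d have
  # AUC = pnorm(d / sqrt(2)); drawn at the study's n = 19 and averaged
  # over 300 splits the estimate must land within 0.05 of it
  set.seed(19)
  d <- 2
  x0 <- scale(rnorm(9))           # class draws standardized so the
  x1 <- scale(rnorm(10)) + d      # realized separation is exactly d SDs
  dat <- data.frame(
    class = factor(c(rep("damaged", 9), rep("intact", 10)),
                   levels = c("damaged", "intact")),
    S_Elev_ps = c(x0, x1))
  m <- thz_svm(class ~ S_Elev_ps, dat, n_iter = 300, seed = 4)
  expect_lt(abs(m$auc_mean - pnorm(d / sqrt(2))), 0.05)
})

test_that("correlation report matches the normal-equations oracle", {
  ft <- data.frame(S_Elev_ps = c(-0.4, -0.1, -0.25, -0.33, -0.15),
                   S_Phys_ps = c(-0.38, -0.05, -0.2, -0.35, -0.12))
  cr <- correlation_report(ft)
  beta <- oracle_ols(ft$S_Elev_ps, ft$S_Phys_ps)
  expect_equal(cr$slope, beta[2], tolerance = 1e-10)
  expect_equal(cr$intercept, beta[1], tolerance = 1e-10)
  pred <- beta[1] + beta[2] * ft$S_Elev_ps
  r2 <- 1 - sum((ft$S_Phys_ps - pred)^2) /
    sum((ft$S_Phys_ps - mean(ft$S_Phys_ps))^2)
  expect_equal(cr$r_squared, r2, tolerance = 1e-10)
})

test_that("correlation report on identical and independent features behaves as expected", {
  ident <- data.frame(S_Elev_ps = c(-0.3, -0.2, -0.1, -0.25),
                      S_Phys_ps = c(-0.3, -0.2, -0.1, -0.25))
  cr <- correlation_report(ident)
  expect_equal(cr$slope, 1)
  expect_equal(cr$intercept, 0)
  expect_equal(cr$r_squared, 1)
  set.seed(6)
  indep <- data.frame(S_Elev_ps = rnorm(500), S_Phys_ps = rnorm(500))
  expect_lt(correlation_report(indep)$r_squared, 0.05)
  expect_error(correlation_report(data.frame(S_Elev_ps = c(1, 1, 1),
                                             S_Phys_ps = c(1, 2, 3))),
               "variance")
})
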