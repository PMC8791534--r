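test_that("structured likelihood equals the dense multivariate-normal oracle", {
  for (seed in 1:3) {
    d <- toy_lmm_data(seed, n_centers = 3, n_subjects = 6, n_scans = 2)
    fit <- fit_lmm(y ~ x, d)
    expect_equal(fit$loglik, dense_lmm_loglik(fit), tolerance = 1e-8)
  }
  # a larger unbalanced instance, still within dense reach
  d <- toy_lmm_data(9, n_centers = 5, n_subjects = 60, n_scans = 3)
  d <- d[-sample(nrow(d), 20), ]
  fit <- fit_lmm(y ~ x, d)
  expect_equal(fit$loglik, dense_lmm_loglik(fit), tolerance = 1e-8)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- toy_lmm_data(4, n_centers = 4, n_subjects = 80, n_scans = 3)
  fit <- fit_lmm(y ~ x, d)
  m <- lme4::lmer(y ~ x + (1 | center_id) + (1 | center_id:subject_id),
                  data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients),
               unname(lme4::fixef(m)[names(fit$coefficients)]),
               tolerance = 1e-4)
})

test_that("degenerate variance case reduces to ordinary least squares", {
  set.seed(7)
  n <- 300
  # singleton groups: V is proportional to the identity for any variance
  # ratio, so the GLS fixed effects must coincide with ordinary least squares
  d <- data.frame(subject_id = seq_len(n), center_id = seq_len(n),
                  x = stats::runif(n, 0, 10))
  d$y <- 1 + 0.5 * d$x + stats::rnorm(n)
  fit <- fit_lmm(y ~ x, d)
  ols <- stats::coef(stats::lm(y ~ x, d))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("balanced one-way layout matches the closed-form ML moment solution", {
  set.seed(11)
  k <- 40; m <- 4
  g <- rep(seq_len(k), each = m)
  y <- 10 + stats::rnorm(k, 0, 2)[g] + stats::rnorm(k * m)
  d <- data.frame(subject_id = g, center_id = 1, y = y)
  fit <- fit_lmm(y ~ 1, d, random = "subject")
  ybar_g <- tapply(y, g, mean)
  MSW <- sum((y - ybar_g[g])^2) / (k * (m - 1))
  psi <- m * sum((ybar_g - mean(y))^2) / k      # ML divides by k, not k-1
  expect_equal(unname(fit$varcomps["resid"]), MSW, tolerance = 1e-5)
  expect_equal(unname(fit$varcomps["subject"]), (psi - MSW) / m,
               tolerance = 1e-4)
})

test_that("information criteria follow from the likelihood and k_params", {
  d <- toy_lmm_data(2)
  fit <- fit_lmm(y ~ x, d)
  expect_equal(fit$k_params, 2 + 3)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$k_params)
  expect_equal(fit$BIC, -2 * fit$loglik + fit$k_params * log(fit$n_obs))
  expect_true(all(fit$varcomps >= 0))
})

test_that("adding a random effect never decreases the maximized likelihood", {
  for (seed in 1:4) {
    d <- toy_lmm_data(seed, n_centers = 4, n_subjects = 30, n_scans = 3)
    f_subj <- fit_lmm(y ~ x, d, random = "subject")
    f_both <- fit_lmm(y ~ x, d)
    expect_gte(f_both$loglik, f_subj$loglik - 1e-6)
  }
})

test_that("cluster-robust covariance matches a hand-assembled sandwich", {
  d <- toy_lmm_data(5, n_centers = 3, n_subjects = 9, n_scans = 2)
  fit <- fit_lmm(y ~ x, d)
  it <- fit$internals
  vc <- fit$varcomps
  n <- length(it$y)
  Zs <- outer(it$subj_i, sort(unique(it$subj_i)), "==") + 0
  Zc <- outer(it$cent_i, sort(unique(it$cent_i)), "==") + 0
  V <- vc["center"] * tcrossprod(Zc) + vc["subject"] * tcrossprod(Zs) +
    vc["resid"] * diag(n)
  e <- it$y - drop(it$X %*% fit$coefficients)
  Vi <- solve(V)
  G <- length(unique(it$cent_i))
  meat <- matrix(0, ncol(it$X), ncol(it$X))
  for (c_ in unique(it$cent_i)) {
    i <- it$cent_i == c_
    g <- t(it$X[i, , drop = FALSE]) %*% Vi[i, i] %*% e[i]
    meat <- meat + tcrossprod(g)
  }
  bread <- solve(t(it$X) %*% Vi %*% it$X)
  oracle <- bread %*% meat %*% bread * G / (G - 1)
  expect_equal(unname(cluster_robust_cov(fit)), unname(oracle),
               tolerance = 1e-6)
  sd_rob <- sqrt(diag(cluster_robust_cov(fit)))
  expect_true(all(eigen(cluster_robust_cov(fit))$values > -1e-10))
  expect_true(all(is.finite(sd_rob)))
})

test_that("singleton clusters reduce the sandwich to per-observation scores", {
  d <- toy_lmm_data(6, n_centers = 3, n_subjects = 12, n_scans = 2)
  fit <- fit_lmm(y ~ x, d)
  it <- fit$internals
  n <- length(it$y)
  Vcl <- cluster_robust_cov(fit, cluster = seq_len(n))
  scores <- it$X * (it$We / it$sigma2)
  bread <- solve(it$M / it$sigma2)
  oracle <- bread %*% crossprod(scores) %*% bread * n / (n - 1)
  expect_equal(unname(Vcl), unname(oracle), tolerance = 1e-8)
})

test_that("duplicating every cluster scales the sandwich by the expected factor", {
  d <- toy_lmm_data(8, n_centers = 4, n_subjects = 20, n_scans = 2)
  fit <- fit_lmm(y ~ x, d)
  d2 <- d
  d2$center_id <- d2$center_id + 100
  d2$subject_id <- d2$subject_id + 1000
  fit2 <- fit_lmm(y ~ x, rbind(d, d2))
  G <- fit$n_centers
  # doubled data halves the covariance, modulo the G/(G-1) factors
  adj <- (G / (G - 1)) / ((2 * G) / (2 * G - 1))
  expect_equal(unname(2 * cluster_robust_cov(fit2) * adj),
               unname(cluster_robust_cov(fit)), tolerance = 1e-4)
  expect_error(cluster_robust_cov(fit, cluster = rep(1, fit$n_obs)),
               ">= 2 clusters")
})

test_that("population prediction is the fixed-effects row product", {
  d <- toy_lmm_data(3)
  fit <- fit_lmm(y ~ 1, d)
  expect_equal(unname(predict(fit, data.frame(x = c(1, 99)))),
               rep(unname(fit$coefficients[1]), 2))
  fit2 <- fit_lmm(y ~ x, d)
  expect_equal(unname(predict(fit2, d[3, ])),
               unname(drop(c(1, d$x[3]) %*% fit2$coefficients)))
})

test_that("fixed effects are recovered without bias across simulated cohorts", {
  tr <- modified_truth(gap = FALSE)
  truth_f <- tr$beta["frontal", ]
  est <- t(sapply(1:50, function(s) {
    d <- generate_cohort(tr, seed = 1000 + s)
    coef(gm_trajectory(d, "frontal", powers = c(0, 1)))
  }))
  truth_all <- c(truth_f[1], truth_f[1] * 1.10, truth_f[2], truth_f[2] * 1.10,
                 truth_f[3], truth_f[3] * 1.10)
  names(truth_all) <- c("sexF", "sexM", "sexF:g1", "sexM:g1",
                        "sexF:g2", "sexM:g2")
  for (nm in colnames(est)) {
    mc_se <- stats::sd(est[, nm]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, nm]) - truth_all[nm]), 2.5 * mc_se)
  }
})

test_that("mean prediction is consistent on a large simulated cohort", {
  # center variance off: with 6 centers the intercept absorbs the mean
  # center effect, a finite-G offset that no subject count removes
  tr <- calibrate_truth(sigma_center_frac = 0)
  tr$gamma[, ] <- 0
  d <- generate_cohort(tr, n_obj1 = 1600, n_obj2 = 400, seed = 77)
  traj <- gm_trajectory(d, "frontal", powers = c(0, 1))
  ages <- seq(1, 20, by = 0.5)
  for (s in c("F", "M")) {
    mult <- if (s == "M") 1.10 else 1
    tv <- vapply(ages, function(a)
      truth_volume(tr, "frontal", s, FALSE, a), numeric(1))
    expect_lt(mean(abs(predict(traj, s, ages) - tv) / tv), 0.01)
  }
})

test_that("singular designs and degenerate groupings are rejected", {
  d <- toy_lmm_data(1)
  d$x2 <- 2 * d$x
  expect_error(fit_lmm(y ~ x + x2, d), "singular")
  d1 <- d[d$subject_id == 1, ]
  expect_error(fit_lmm(y ~ x, d1), "2 subjects")
})
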