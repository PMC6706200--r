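test_that("predictor transforms are log, sqrt and identity as appropriate", {
  env <- data.frame(week_start = as.Date("2015-08-25"), sst = 16.3,
                    par = 4, sea_level = 12, wind_speed = 1,
                    wind_direction = 270)
  tr <- transform_predictors(env)
  expect_equal(tr$log_wind_speed, 0)
  expect_equal(tr$sqrt_par, 2)
  expect_equal(tr$sst, 16.3)
  expect_equal(tr$wind_direction, 270)
  env$wind_speed <- 0
  expect_error(transform_predictors(env), "positive")
})

test_that("VIF screening follows 1/(1 - R^2) and drops collinear terms", {
  # exactly orthogonal pair: both VIF = 1, both retained
  set.seed(40)
  x <- c(scale(rnorm(40)))
  z <- c(scale(residuals(lm(rnorm(40) ~ x))))
  v <- vif_screen(data.frame(x = x, z = z))
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-10)
  expect_equal(v$retained, c("x", "z"))

  # sample correlation exactly 0.9: VIF = 1/(1 - 0.81) = 5.263..., one falls
  y <- 0.9 * x + sqrt(1 - 0.81) * z
  v2 <- vif_screen(data.frame(x = x, y = y))
  expect_equal(unname(v2$initial_vif), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)
  expect_length(v2$dropped, 1)

  # duplicated covariate: infinite VIF, dropped first
  v3 <- vif_screen(data.frame(a = x, b = x, c = z))
  expect_true(is.infinite(max(v3$initial_vif)))
  expect_true(all(v3$vif <= 3))

  # protected covariates survive; their collinear partner falls
  v4 <- vif_screen(data.frame(x = x, y = y, z = z), protect = "x")
  expect_true("x" %in% v4$retained)
  expect_equal(v4$dropped, "y")
})

test_that("VIF values agree with the car implementation", {
  skip_if_not_installed("car")
  set.seed(41)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  X$d <- X$a + 0.5 * X$b + rnorm(50, 0, 0.5)
  mine <- vif_screen(X, threshold = Inf)$initial_vif
  y <- rnorm(50)
  theirs <- car::vif(lm(y ~ a + b + c + d, data = X))
  expect_equal(unname(mine), unname(theirs[names(mine)]), tolerance = 1e-8)
})

test_that("Welch ANOVA reduces to classical F and matches the formula", {
  # identical distributions -> F = 0, p = 1
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  w <- welch_anova(v, g)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)

  # equal sample variances and equal n: the Welch F reduces to the
  # classical one-way F — exactly for two groups, where the Welch
  # denominator correction vanishes, and approximately for more
  set.seed(42)
  dev <- c(scale(rnorm(10)))
  v2 <- c(dev, dev + 1)
  g2 <- rep(c("a", "b"), each = 10)
  cl2 <- summary(aov(v2 ~ factor(g2)))[[1]]$`F value`[1]
  expect_equal(welch_anova(v2, g2)$statistic, cl2, tolerance = 1e-10)
  v3 <- c(dev, dev + 1, dev + 2)
  g3 <- rep(c("a", "b", "c"), each = 10)
  cl3 <- summary(aov(v3 ~ factor(g3)))[[1]]$`F value`[1]
  expect_equal(welch_anova(v3, g3)$statistic, cl3, tolerance = 0.05)

  # direct evaluation of the Welch formula on a fixed fixture
  set.seed(43)
  vals <- c(rnorm(10, 0, 1), rnorm(10, 0.5, 2), rnorm(10, 1, 3))
  grp <- rep(c("a", "b", "c"), each = 10)
  ni <- tapply(vals, grp, length); mi <- tapply(vals, grp, mean)
  vi <- tapply(vals, grp, var)
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  k <- 3
  num <- sum(wi * (mi - mw)^2) / (k - 1)
  tmp <- sum((1 - wi / sum(wi))^2 / (ni - 1))
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * tmp
  f_direct <- num / den
  df2_direct <- (k^2 - 1) / (3 * tmp)
  w3 <- welch_anova(vals, grp)
  expect_equal(w3$statistic, f_direct, tolerance = 1e-10)
  expect_equal(w3$df2, df2_direct, tolerance = 1e-10)

  expect_error(welch_anova(rep(1, 6), rep(c("a", "b"), 3)), "variance")
})

test_that("Games-Howell gives null results on identical groups and agrees with Welch t at k = 2", {
  v <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  gh <- games_howell(v, g)
  expect_equal(gh$q, 0)
  expect_equal(gh$p_value, 1)

  set.seed(44)
  agree <- 0
  for (i in 1:40) {
    x <- rnorm(12, 0, 1); y <- rnorm(9, sample(c(0, 1.2), 1), 2)
    vals <- c(x, y); grp <- rep(c("a", "b"), c(12, 9))
    p_gh <- games_howell(vals, grp)$p_value
    p_t <- t.test(x, y)$p.value
    expect_equal(p_gh, p_t, tolerance = 1e-6)
    agree <- agree + ((p_gh < 0.05) == (p_t < 0.05))
  }
  expect_equal(agree, 40)
})

test_that("Games-Howell separates three stratified groups in order", {
  set.seed(45)
  vals <- c(rnorm(30, 5, 1.5), rnorm(30, 2.5, 1), rnorm(30, 0.5, 0.5))
  grp <- rep(c("summer", "autumn", "winter"), each = 30)
  gh <- games_howell(vals, grp)
  expect_equal(nrow(gh), 3)
  expect_true(all(gh$p_value < 0.05))
  expect_true(all(gh$df > 0))
})

test_that("Spearman permutation test matches exhaustive enumeration", {
  expect_equal(spearman_test(1:8, (1:8)^2, exact = TRUE)$rho, 1)
  expect_equal(spearman_test(1:8, rev(1:8), exact = TRUE)$rho, -1)
  expect_error(spearman_test(1:5, rep(1, 5)), "constant")

  set.seed(46)
  x <- rnorm(7); y <- 0.6 * x + rnorm(7)
  res <- spearman_test(x, y, exact = TRUE)
  # independent enumeration oracle
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- oracle_perms(7)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  p_oracle <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$n_perm, factorial(7))

  # Monte Carlo agrees with the exact value within sampling error
  set.seed(47)
  mc <- spearman_test(x, y, n_perm = 4000)
  expect_lt(abs(mc$p_value - p_oracle), 0.03)
})

test_that("site comparisons behave at both extremes", {
  v <- rep(c(1, 2, 3, 4), 2)
  s <- rep(c("I", "II"), each = 4)
  tt <- site_comparison(v, s, "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # disjoint ranges: rank-sum p equals the exact minimal two-sided value
  lo <- 1:5; hi <- 11:15
  wt <- site_comparison(c(lo, hi), rep(c("I", "II"), each = 5), "wilcoxon")
  expect_equal(wt$p_value, 2 / choose(10, 5), tolerance = 1e-10)

  # a clear shift is detected at moderate n
  set.seed(48)
  shift <- site_comparison(c(rnorm(60), rnorm(60, 1.5)),
                           rep(c("I", "II"), each = 60), "t")
  expect_lt(shift$p_value, 1e-6)
  expect_error(site_comparison(1:5, rep("I", 5), "t"), "2 levels")
})

test_that("NB mixed model recovers its own generative parameters", {
  set.seed(49)
  n_subj <- 30; n_week <- 15
  sst <- seq(16, 4, length.out = n_week)
  d <- expand.grid(subject = sprintf("s%02d", 1:n_subj), week = 1:n_week,
                   stringsAsFactors = FALSE)
  d$sst <- sst[d$week]
  b <- rnorm(n_subj, 0, 0.8)
  mu <- exp(-1.5 + b[match(d$subject, sprintf("s%02d", 1:n_subj))] +
              0.25 * d$sst)
  d$count <- rnbinom(nrow(d), mu = mu, size = 2)
  fit <- fit_nb_glmm(count ~ sst, d, subject = "subject")
  expect_true(fit$converged)
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "sst"] - 0.25), 0.08)
  expect_true(all(est$se > 0))
  expect_true(all(est$p >= 0 & est$p <= 1))
  expect_gt(fit$theta, 0)
  expect_equal(fit$n, n_subj * n_week)
  expect_equal(fit$n_subjects, n_subj)

  # intercept-only fit reproduces the sample mean on the response scale
  d0 <- data.frame(count = rpois(200, 6),
                   subject = rep(sprintf("s%d", 1:20), each = 10))
  f0 <- fit_nb_glmm(count ~ 1, d0, subject = "subject")
  expect_equal(exp(f0$coefficients$estimate[1]), mean(d0$count),
               tolerance = 0.05)
})

test_that("ZINB reduces to NB without structural zeros and recovers pi", {
  set.seed(50)
  n_subj <- 30; n_week <- 15
  sst <- seq(16, 4, length.out = n_week)
  d <- expand.grid(subject = sprintf("s%02d", 1:n_subj), week = 1:n_week,
                   stringsAsFactors = FALSE)
  d$sst <- sst[d$week]
  b <- rnorm(n_subj, 0, 0.5)
  mu <- exp(-0.5 + b[match(d$subject, sprintf("s%02d", 1:n_subj))] +
              0.2 * d$sst)
  d$count <- rnbinom(nrow(d), mu = mu, size = 2)
  nb <- fit_nb_glmm(count ~ sst, d, subject = "subject")
  zi <- fit_zinb_glmm(count ~ sst, d, subject = "subject")
  expect_true(zi$converged)
  expect_lt(abs(zi$coefficients$estimate[2] - nb$coefficients$estimate[2]),
            0.03)
  expect_lt(zi$zi_prob, 0.1)  # no structural zeros were simulated

  # 30% structural zeros are recovered
  d$count2 <- d$count * rbinom(nrow(d), 1, 0.7)
  zi2 <- fit_zinb_glmm(count2 ~ sst, d, subject = "subject")
  expect_true(zi2$converged)
  expect_lt(abs(zi2$zi_prob - 0.3), 0.1)

  # an all-zero response is flagged, not an error
  d$zero <- 0L
  z0 <- fit_zinb_glmm(zero ~ sst, d, subject = "subject")
  expect_false(z0$converged)
})
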