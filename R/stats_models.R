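#' Transform environmental predictors
#'
#' Applies the standard normalising transforms used for the connectivity
#' models: wind speed is log-transformed and PAR square-root transformed;
#' SST, sea level and wind direction enter untransformed.
#'
#' @param env Environmental data frame (see [read_environment()]).
#' @return A `data.frame` with `week_start` (if present), `sst`,
#'   `log_wind_speed`, `sqrt_par`, `sea_level`, `wind_direction`.
#' @export
transform_predictors <- function(env) {
  if (any(env$wind_speed <= 0)) stop("wind_speed must be positive to log")
  if (any(env$par < 0)) stop("par must be non-negative")
  out <- data.frame(sst = env$sst,
                    log_wind_speed = log(env$wind_speed),
                    sqrt_par = sqrt(env$par),
                    sea_level = env$sea_level,
                    wind_direction = env$wind_direction)
  if (!is.null(env$week_start)) out <- cbind(week_start = env$week_start, out)
  out
}

#' Screen covariates for collinearity by variance inflation factor
#'
#' VIF of covariate j is `1 / (1 - R^2_j)` from regressing it on the other
#' covariates. Covariates are dropped greedily, largest VIF first, until
#' all remaining VIFs are at or below the threshold; perfectly collinear
#' covariates have infinite VIF and fall first.
#'
#' @param covariates Numeric `data.frame` of candidate predictors.
#' @param threshold Maximum tolerated VIF (default 3).
#' @param protect Covariate names never dropped (the ecological predictor
#'   of interest, typically SST); when a protected and an unprotected
#'   covariate are collinear, the unprotected one falls.
#' @return A list: `retained` (names kept), `dropped` (names removed, in
#'   drop order), `vif` (final VIF table), `initial_vif` (before any
#'   drop).
#' @export
vif_screen <- function(covariates, threshold = 3, protect = character(0)) {
  X <- as.data.frame(covariates)
  if (ncol(X) < 2) stop("need at least two covariates")
  if (nrow(X) <= ncol(X)) stop("need more rows than covariates")
  vif_of <- function(X) {
    vapply(names(X), function(j) {
      r2 <- suppressWarnings(
        summary(stats::lm(stats::reformulate(setdiff(names(X), j),
                                             response = j),
                          data = X))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  initial <- vif_of(X)
  dropped <- character(0)
  v <- initial
  while (ncol(X) >= 2 && max(v) > threshold) {
    droppable <- v[setdiff(names(v), protect)]
    if (length(droppable) == 0 || max(droppable) <= threshold) break
    worst <- names(which.max(droppable))
    dropped <- c(dropped, worst)
    X <- X[setdiff(names(X), worst)]
    if (ncol(X) < 2) {
      v <- stats::setNames(1, names(X))
      break
    }
    v <- vif_of(X)
  }
  list(retained = names(X), dropped = dropped, vif = v,
       initial_vif = initial)
}

.tidy_glmmTMB <- function(fit, zi = FALSE) {
  s <- summary(fit)
  co <- s$coefficients$cond
  out <- list(
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, 1], se = co[, 2],
                              z = co[, 3], p = co[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    theta = stats::sigma(fit),
    ranef_sd = sqrt(as.numeric(glmmTMB::VarCorr(fit)$cond[[1]])),
    loglik = as.numeric(stats::logLik(fit)),
    converged = isTRUE(fit$fit$convergence == 0) &&
      !isTRUE(fit$sdr$pdHess == FALSE),
    n = stats::nobs(fit),
    n_subjects = unname(s$ngrps$cond[1]),
    fit = fit)
  if (zi) {
    zc <- s$coefficients$zi
    out$zi_intercept <- zc[1, 1]
    out$zi_prob <- stats::plogis(zc[1, 1])
    out$zi_se <- zc[1, 2]
  }
  out
}

#' Negative binomial mixed model with a per-fish random intercept
#'
#' Fits a count response with a log link, NB2 variance (`mu + mu^2/theta`),
#' the given fixed effects and a normal random intercept per subject —
#' the model used for weekly node strength against environmental
#' predictors. Estimation is by maximum likelihood via `glmmTMB`.
#'
#' @param formula Fixed-effects formula, e.g. `strength ~ sst +
#'   log_wind_speed + wind_direction`. The random intercept is added
#'   internally.
#' @param data Model frame containing the response, predictors and the
#'   subject column.
#' @param subject Name of the subject (random intercept) column.
#' @return A `glmm_fit` list: `coefficients` (term, estimate, se, z, p on
#'   the log-link scale), `theta` (NB dispersion), `ranef_sd`, `loglik`,
#'   `converged`, `n`, `n_subjects`, and the underlying `fit`. A fit that
#'   fails returns `converged = FALSE` with `$note`, never an error.
#' @export
fit_nb_glmm <- function(formula, data, subject) {
  if (!subject %in% names(data)) stop("subject column not found: ", subject)
  f <- stats::update(formula,
                     paste(". ~ . + (1 |", subject, ")"))
  res <- tryCatch({
    fit <- glmmTMB::glmmTMB(f, data = data, family = glmmTMB::nbinom2())
    .tidy_glmmTMB(fit)
  }, error = function(e) list(converged = FALSE, note = conditionMessage(e),
                              coefficients = NULL))
  res$formula <- f
  res$family <- "nbinom2"
  class(res) <- "glmm_fit"
  res
}

#' Zero-inflated negative binomial mixed model
#'
#' As [fit_nb_glmm()] plus an intercept-only structural-zero component on
#' the logit scale — the model used for weekly degree, whose series contain
#' more zero weeks than an NB count process alone produces.
#'
#' @inheritParams fit_nb_glmm
#' @return A `glmm_fit` with additional elements `zi_intercept` (logit
#'   scale), `zi_prob` and `zi_se`. A response with no zeros leaves the
#'   zero-inflation non-identifiable; the fit is then flagged.
#' @export
fit_zinb_glmm <- function(formula, data, subject) {
  if (!subject %in% names(data)) stop("subject column not found: ", subject)
  response <- all.vars(formula)[1]
  f <- stats::update(formula, paste(". ~ . + (1 |", subject, ")"))
  res <- tryCatch({
    fit <- glmmTMB::glmmTMB(f, data = data, family = glmmTMB::nbinom2(),
                            ziformula = ~1)
    .tidy_glmmTMB(fit, zi = TRUE)
  }, error = function(e) list(converged = FALSE, note = conditionMessage(e),
                              coefficients = NULL))
  if (is.null(res$note) && sum(data[[response]] == 0, na.rm = TRUE) == 0) {
    res$converged <- FALSE
    res$note <- "no zeros in response: zero-inflation non-identifiable"
  }
  res$formula <- f
  res$family <- "zinb2"
  class(res) <- "glmm_fit"
  res
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Count mixed model (", x$family, ")\n", sep = "")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  if (!is.null(x$coefficients)) {
    print(x$coefficients, digits = 4)
    cat("theta =", signif(x$theta, 4),
        " random-intercept SD =", signif(x$ranef_sd, 4),
        " logLik =", signif(x$loglik, 6), "\n")
    if (!is.null(x$zi_prob)) {
      cat("zero-inflation probability =", signif(x$zi_prob, 4), "\n")
    }
    cat("n =", x$n, "obs,", x$n_subjects, "subjects; converged:",
        x$converged, "\n")
  }
  invisible(x)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares group means without assuming equal variances, with the
#' Welch--Satterthwaite denominator degrees of freedom. Used for seasonal
#' comparisons of relative daily movement counts.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (coerced to factor).
#' @return A list: `statistic` (F), `df1`, `df2` (fractional), `p_value`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least two groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("every group needs at least two values")
  vs <- tapply(values, groups, stats::var)
  if (any(vs == 0)) stop("every group needs positive variance")
  ow <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  list(statistic = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p_value = unname(ow$p.value),
       method = "Welch ANOVA")
}

#' Games--Howell post hoc pairwise comparisons
#'
#' Pairwise comparisons after a Welch ANOVA, robust to unequal variances
#' and sample sizes: the studentized-range statistic
#' `q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j) / 2)` referred to the
#' studentized range distribution with `k` groups and Welch--Satterthwaite
#' degrees of freedom.
#'
#' @inheritParams welch_anova
#' @return A `data.frame` with one row per group pair: `group1`, `group2`,
#'   `diff` (mean difference, group2 - group1), `q`, `df`, `p_value`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("every group needs at least two values")
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, stats::var)
  if (any(vs == 0)) stop("every group needs positive variance")
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(gp) {
    i <- gp[1]; j <- gp[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    q <- abs(ms[i] - ms[j]) / sqrt(se2 / 2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                     (vs[j] / ns[j])^2 / (ns[j] - 1))
    c(diff = unname(ms[j] - ms[i]), q = unname(q), df = unname(df),
      p_value = stats::ptukey(unname(q), k, unname(df), lower.tail = FALSE))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], t(res),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Tie-corrected Spearman correlation (Pearson correlation of mid-ranks)
#' with a two-sided p-value obtained by permuting one variable — either
#' exhaustively over all `n!` permutations (`exact = TRUE`, feasible for
#' n up to ~9) or by Monte Carlo sampling. Suited to the small cohort
#' sizes of tagging studies, where the asymptotic t approximation is
#' doubtful.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param n_perm Number of random permutations when `exact = FALSE`.
#' @param exact Enumerate all permutations instead of sampling.
#' @return A list: `rho`, `p_value`, `method`, `n_perm`.
#' @export
spearman_test <- function(x, y, n_perm = 10000, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("rank correlation undefined for constant input")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  eps <- 1e-12
  if (exact) {
    if (n > 9) stop("exact enumeration is limited to n <= 9")
    perms <- .all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "exact permutation"
    n_used <- nrow(perms)
  } else {
    rhos <- vapply(seq_len(n_perm),
                   function(i) stats::cor(rx, sample(ry)), numeric(1))
    p_value <- (1 + sum(abs(rhos) >= abs(rho) - eps)) / (n_perm + 1)
    method <- "Monte Carlo permutation"
    n_used <- n_perm
  }
  list(rho = rho, p_value = p_value, method = method, n_perm = n_used)
}

# all n! permutations of 1..n, one per row (n small)
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Two-sample comparison between sites
#'
#' Welch's t-test or the Wilcoxon rank-sum test for comparing residency or
#' movement indices between the two sites.
#'
#' @param values Numeric vector.
#' @param site Two-level grouping vector.
#' @param method `"t"` (Welch) or `"wilcoxon"`.
#' @return A list: `statistic`, `p_value`, `method` (plus `df` for the
#'   t-test).
#' @export
site_comparison <- function(values, site, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  site <- factor(site)
  if (nlevels(droplevels(site)) != 2) stop("site must have exactly 2 levels")
  ns <- table(droplevels(site))
  if (any(ns < 2)) stop("every site needs at least two values")
  if (method == "t") {
    tt <- stats::t.test(values ~ site)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, method = "Welch two-sample t-test")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values ~ site))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "Wilcoxon rank-sum")
  }
}
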