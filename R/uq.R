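#' Confidence summary of a calibrated subject
#'
#' Per-parameter Wald 95% (or `level`) intervals, the 2-D confidence
#' ellipse for the first two free parameters (center, covariance and
#' chi-squared radius), and per-parameter boundedness verdicts. Intervals
#' use t quantiles with `N - p` degrees of freedom by default (see
#' [confint.bv_fit()] for why); `asymptotic = TRUE` gives z quantiles. A
#' parameter is reported unbounded when the covariance is non-finite or
#' ill-conditioned (condition number above `cond_cap`) or its interval
#' crosses the unidentifiability cap.
#'
#' @param fit A converged [bv_fit()].
#' @param level Confidence level.
#' @param asymptotic Use z instead of t quantiles for the intervals.
#' @param cond_cap Condition-number threshold on the covariance.
#' @return A list of class `"bv_confidence"`: `intervals` (matrix with
#'   `estimate`, `low`, `high`), `bounded` (named logical), `ellipse`
#'   (`center`, `cov`, `radius2`).
#' @export
confidence_summary <- function(fit, level = 0.95, asymptotic = FALSE,
                               cond_cap = 1e10) {
  stopifnot(inherits(fit, "bv_fit"))
  if (!isTRUE(fit$converged) || is.null(fit$vcov))
    stop("fit did not converge or has no covariance")
  est <- fit$coefficients
  se <- fit$se
  ci <- confint(fit, level = level, asymptotic = asymptotic)
  intervals <- cbind(estimate = est, low = ci[, "low"], high = ci[, "high"])
  finite <- all(is.finite(fit$vcov))
  cond <- if (finite) {
    ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
    if (max(ev) == 0) 1  # exact-fit degeneracy: zero uncertainty is bounded
    else if (min(ev) <= 0) Inf
    else max(ev) / min(ev)
  } else Inf
  bounded <- vapply(fit$free, function(nm) {
    if (!finite || cond > cond_cap || !is.finite(se[[nm]])) return(FALSE)
    if (grepl("^alpha", nm) && (abs(intervals[nm, "low"]) > fit$cap ||
                                abs(intervals[nm, "high"]) > fit$cap))
      return(FALSE)
    TRUE
  }, logical(1))
  pair <- fit$free[seq_len(min(2L, length(fit$free)))]
  ellipse <- list(center = est[pair],
                  cov = fit$vcov[pair, pair, drop = FALSE],
                  radius2 = stats::qchisq(level, df = 2))
  structure(list(intervals = intervals, bounded = bounded, ellipse = ellipse,
                 level = level),
            class = "bv_confidence")
}

#' @export
print.bv_confidence <- function(x, ...) {
  cat(sprintf("Asymptotic %g%% confidence intervals:\n", 100 * x$level))
  print(round(x$intervals, 4))
  if (!all(x$bounded))
    cat("Unbounded:", names(x$bounded)[!x$bounded], "\n")
  invisible(x)
}

#' Cost-function contours over a parameter pair
#'
#' Evaluates the calibration cost (sum of squared proportional residuals)
#' over a grid in one parameter pair, remaining parameters held at their
#' estimates, and classifies the sublevel set at threshold
#' `SSR * (1 + 2/(N - p))` as bounded or unbounded along each axis by
#' whether it touches the grid boundary. The default grid spans +/- 6
#' standard errors around each estimate (clipped to the parameter's valid
#' domain); pass `ranges` when a standard error is unbounded.
#'
#' @param fit A converged [bv_fit()].
#' @param pair Character vector of two free parameter names.
#' @param n Grid points per axis.
#' @param ranges Optional named list of explicit axis ranges.
#' @param extent Half-width of the default grid in standard errors.
#' @return A list of class `"bv_contour"`: grid vectors `x`, `y`, matrix
#'   `cost`, `threshold`, and named logical `bounded`.
#' @export
cost_contours <- function(fit, pair = utils::tail(fit$free, 2), n = 41,
                          ranges = NULL, extent = 6) {
  stopifnot(inherits(fit, "bv_fit"), length(pair) == 2L,
            all(pair %in% fit$free))
  est <- fit$coefficients
  axis_range <- function(nm) {
    if (!is.null(ranges[[nm]])) return(ranges[[nm]])
    se <- fit$se[[nm]]
    if (!is.finite(se) || se == 0) se <- max(abs(est[[nm]]), 1) # fallback span
    lo <- est[[nm]] - extent * se
    hi <- est[[nm]] + extent * se
    min_ok <- if (nm == "k_p") 1e-4 else -0.9
    c(max(lo, min_ok), hi)
  }
  rx <- axis_range(pair[1L]); ry <- axis_range(pair[2L])
  # the grid always contains the estimate itself, so the threshold sublevel
  # set is never empty at finite resolution
  gx <- sort(unique(c(seq(rx[1L], rx[2L], length.out = n),
                      min(max(est[[pair[1L]]], rx[1L]), rx[2L]))))
  gy <- sort(unique(c(seq(ry[1L], ry[2L], length.out = n),
                      min(max(est[[pair[2L]]], ry[1L]), ry[2L]))))
  n_x <- length(gx); n_y <- length(gy)
  cost <- matrix(NA_real_, n_x, n_y)
  th <- est
  for (i in seq_len(n_x)) for (j in seq_len(n_y)) {
    th[pair[1L]] <- gx[i]; th[pair[2L]] <- gy[j]
    au <- if (is.null(fit$fixed_alpha_u)) th[["alpha_u"]] else fit$fixed_alpha_u
    cost[i, j] <- tryCatch(
      sum(bv_objective(bv_params(au, th[["alpha_v"]], th[["k_p"]]),
                       fit$subject, fit$window, delta = fit$delta)^2),
      error = function(e) Inf)
  }
  threshold <- fit$ssr * (1 + 2 / max(1, fit$df))
  inside <- cost <= threshold
  bounded <- c(!any(inside[c(1L, n_x), ], na.rm = TRUE),
               !any(inside[, c(1L, n_y)], na.rm = TRUE))
  names(bounded) <- pair
  structure(list(x = gx, y = gy, cost = cost, threshold = threshold,
                 pair = pair, bounded = bounded),
            class = "bv_contour")
}

#' @export
print.bv_contour <- function(x, ...) {
  cat(sprintf("Cost contours over (%s, %s); threshold %.4g\n",
              x$pair[1L], x$pair[2L], x$threshold))
  for (nm in x$pair)
    cat(sprintf("  sublevel set %s along %s\n",
                if (x$bounded[[nm]]) "bounded" else "UNBOUNDED", nm))
  invisible(x)
}

#' @export
plot.bv_contour <- function(x, ...) {
  graphics::contour(x$x, x$y, log10(pmax(x$cost, 1e-12)),
                    xlab = x$pair[1L], ylab = x$pair[2L], ...)
  graphics::contour(x$x, x$y, x$cost, levels = x$threshold, add = TRUE,
                    col = "red3", lwd = 2, drawlabels = FALSE)
  invisible(x)
}

#' Monte-Carlo parameter draws from the calibrated uncertainty
#'
#' Draws `n` parameter vectors from the multivariate normal distribution
#' centered at the estimates with the asymptotic covariance, then excludes
#' physiologically implausible draws. Rule `"simulable"` (default) excludes
#' `k_p <= 0` or `1 + alpha_v <= 0` (or `1 + alpha_u <= 0` when free), the
#' minimal set under which the model can be simulated; rule `"kp_only"`
#' applies only the `k_p <= 0` exclusion. A covariance that is not positive
#' semidefinite is repaired by clipping negative eigenvalues to zero, with a
#' warning.
#'
#' @param fit A converged [bv_fit()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param rule `"simulable"` or `"kp_only"`.
#' @return A list of class `"bv_draws"`: `draws` (matrix of retained draws,
#'   columns `alpha_u`, `alpha_v`, `k_p`), `n_requested`,
#'   `exclusion_fraction`, `rule`.
#' @export
sample_parameters <- function(fit, n = 10000, seed = NULL,
                              rule = c("simulable", "kp_only")) {
  stopifnot(inherits(fit, "bv_fit"))
  rule <- match.arg(rule)
  if (!isTRUE(fit$converged) || !all(is.finite(fit$vcov)))
    stop("fit must be converged with a finite (bounded) covariance")
  Sigma <- fit$vcov
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values))) {
    warning("covariance not positive semidefinite; clipping negative eigenvalues")
    Sigma <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(Sigma)) %*%
      t(ev$vectors)
    dimnames(Sigma) <- dimnames(fit$vcov)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  free_draws <- MASS::mvrnorm(n, mu = fit$coefficients, Sigma = Sigma)
  if (n == 1L) free_draws <- matrix(free_draws, nrow = 1,
                                    dimnames = list(NULL, fit$free))
  draws <- matrix(NA_real_, n, 3, dimnames = list(NULL,
                  c("alpha_u", "alpha_v", "k_p")))
  draws[, fit$free] <- free_draws
  if (!is.null(fit$fixed_alpha_u)) draws[, "alpha_u"] <- fit$fixed_alpha_u
  bad <- draws[, "k_p"] <= 0
  if (rule == "simulable")
    bad <- bad | (1 + draws[, "alpha_v"] <= 0) | (1 + draws[, "alpha_u"] <= 0)
  structure(list(draws = draws[!bad, , drop = FALSE], n_requested = n,
                 exclusion_fraction = mean(bad), rule = rule),
            class = "bv_draws")
}

#' @export
print.bv_draws <- function(x, ...) {
  cat(sprintf("%d retained parameter draws (%d requested, %.2f%% excluded, rule '%s')\n",
              nrow(x$draws), x$n_requested, 100 * x$exclusion_fraction,
              x$rule))
  invisible(x)
}
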