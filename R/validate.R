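#' Experimental-uncertainty model for blood volume measurements
#'
#' The standard deviation of a measured change in blood volume is modelled
#' as proportional to its magnitude, `sd = c_exp * |delta_vb|`, with a small
#' absolute floor: `sd = max(c_exp * |delta_vb|, sigma_floor)`. The
#' proportionality constant defaults to 0.2 (derived from published
#' repeatability of dilution-based blood volume measurement). The floor
#' avoids the degenerate zero-uncertainty the pure proportional model
#' implies at normovolemia; set `sigma_floor = 0` for the strict
#' proportional model.
#'
#' @param c_exp Proportionality constant, dimensionless, `>= 0`.
#' @param sigma_floor Absolute floor, mL (default 1 mL per 10 kg body weight
#'   when constructed via [validate_subject()]).
#' @return A list of class `"bv_exp_unc"`.
#' @export
exp_uncertainty <- function(c_exp = 0.2, sigma_floor = 0) {
  stopifnot(c_exp >= 0, sigma_floor >= 0)
  structure(list(c_exp = c_exp, sigma_floor = sigma_floor),
            class = "bv_exp_unc")
}

exp_sd <- function(exp_unc, measured) {
  pmax(exp_unc$c_exp * abs(measured), exp_unc$sigma_floor)
}

#' Propagate parameter uncertainty through the model
#'
#' Simulates every retained Monte-Carlo parameter draw over a time grid and
#' summarizes the trajectory ensemble by pointwise 2.5/50/97.5 percentiles.
#'
#' @param draws A [sample_parameters()] result (or a numeric matrix with
#'   columns `alpha_u`, `alpha_v`, `k_p`).
#' @param protocol A [bv_protocol()].
#' @param times Output time grid, min.
#' @return A list of class `"bv_ensemble"`: `times`, `trajectories`
#'   (draws x times matrix) and `quantiles` (3 x times, rows `2.5%`, `50%`,
#'   `97.5%`).
#' @export
propagate_uncertainty <- function(draws, protocol, times) {
  m <- if (inherits(draws, "bv_draws")) draws$draws else draws
  if (is.null(dim(m)) || nrow(m) == 0L) stop("empty draw set")
  traj <- t(apply(m, 1L, function(p)
    bv_simulate(bv_params(p[["alpha_u"]], p[["alpha_v"]], p[["k_p"]]),
                protocol, times)$delta_vb))
  if (length(times) == 1L) traj <- matrix(traj, ncol = 1L)
  q <- apply(traj, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(times = times, trajectories = traj, quantiles = q),
            class = "bv_ensemble")
}

#' Binary fluid-responsiveness agreement probability
#'
#' Responsiveness is the rise of blood volume above normovolemia
#' (`delta_vb > 0`). The model's classification probability is the ensemble
#' fraction `p_m` of trajectories above zero at time `t`; the experimental
#' classification probability is `p_e = Phi(measured / sd)` with the
#' measurement standard deviation from the experimental-uncertainty model.
#' Treating the two uncertainty sources as independent, the probability of
#' agreement is `p_m * p_e + (1 - p_m) * (1 - p_e)`.
#'
#' @param ensemble A [propagate_uncertainty()] result.
#' @param measured Measured `delta_vb` at time `t`, mL.
#' @param exp_unc An [exp_uncertainty()] model.
#' @param t Evaluation time (must be on the ensemble grid).
#' @return Probability in `[0, 1]`.
#' @export
agreement_probability <- function(ensemble, measured, exp_unc, t) {
  stopifnot(inherits(ensemble, "bv_ensemble"), inherits(exp_unc, "bv_exp_unc"))
  i <- which(abs(ensemble$times - t) < 1e-9)
  if (length(i) != 1L) stop("t is not on the ensemble time grid")
  p_m <- mean(ensemble$trajectories[, i] > 0)
  sd_e <- exp_sd(exp_unc, measured)
  if (sd_e == 0) {
    if (measured == 0)
      stop("sd = 0 with measured = 0: sign undefined; set a positive sigma_floor")
    p_e <- as.numeric(measured > 0)
  } else {
    p_e <- stats::pnorm(measured / sd_e)
  }
  p_m * p_e + (1 - p_m) * (1 - p_e)
}

#' Validation report for one subject
#'
#' Runs the two binary fluid-responsiveness validation tests on the
#' validation window: agreement probability at the end of the study
#' (`t_eval`, default 180 min; the last available measurement is used if
#' sampling jitter displaced the grid) and, when it exists, at `T*` — the
#' time at which cumulative infusion first equals cumulative hemorrhage.
#' The measurement nearest each requested time is used, provided it lies
#' within half the local sampling interval; otherwise an error is raised.
#'
#' @param subject A [bv_subject()].
#' @param draws A [sample_parameters()] result for this subject's fit.
#' @param exp_unc An [exp_uncertainty()] model; `NULL` gives the default
#'   `c_exp = 0.2` with floor 1 mL per 10 kg body weight.
#' @param t_eval End-of-study evaluation time, min.
#' @return A list of class `"bv_agreement"`: `p_agreement_180`, `t_star`
#'   (`NA` if none), `p_agreement_tstar` (`NA` iff `t_star` is `NA`), and
#'   the `ensemble` used.
#' @export
validate_subject <- function(subject, draws, exp_unc = NULL, t_eval = 180) {
  stopifnot(inherits(subject, "bv_subject"))
  if (is.null(exp_unc))
    exp_unc <- exp_uncertainty(0.2, sigma_floor = subject$weight / 10)
  tt <- subject$times
  t_eval <- min(t_eval, max(tt))
  ts <- t_star(subject$protocol)
  eval_times <- c(t_eval, if (!is.na(ts)) ts)
  nearest <- function(t) {
    i <- which.min(abs(tt - t))
    half <- max(diff(tt)) / 2
    if (abs(tt[i] - t) > half + 1e-9)
      stop("no measurement within half a sampling interval of t = ", t)
    i
  }
  idx <- vapply(eval_times, nearest, integer(1))
  grid <- sort(unique(tt[idx]))
  ens <- propagate_uncertainty(draws, subject$protocol, grid)
  p180 <- agreement_probability(ens, subject$measured[idx[1L]], exp_unc,
                                tt[idx[1L]])
  pts <- if (is.na(ts)) NA_real_
         else agreement_probability(ens, subject$measured[idx[2L]], exp_unc,
                                    tt[idx[2L]])
  structure(list(p_agreement_180 = p180, t_star = ts,
                 p_agreement_tstar = pts, ensemble = ens),
            class = "bv_agreement")
}

#' @export
print.bv_agreement <- function(x, ...) {
  cat(sprintf("P_agreement(180) = %.3f; T* = %s; P_agreement(T*) = %s\n",
              x$p_agreement_180,
              if (is.na(x$t_star)) "none" else sprintf("%.0f min", x$t_star),
              if (is.na(x$p_agreement_tstar)) "n/a"
              else sprintf("%.3f", x$p_agreement_tstar)))
  invisible(x)
}

#' Validation-stage plot for one subject
#'
#' Measured points with their experimental 95% band, the calibrated model's
#' median trajectory and 95% Monte-Carlo prediction band, and the
#' calibration-window boundary.
#'
#' @param subject A [bv_subject()].
#' @param fit The subject's [bv_fit()].
#' @param draws A [sample_parameters()] result.
#' @param exp_unc An [exp_uncertainty()] model (`NULL` for defaults as in
#'   [validate_subject()]).
#' @param n_grid Plot grid resolution.
#' @export
plot_validation <- function(subject, fit, draws, exp_unc = NULL,
                            n_grid = 121) {
  if (is.null(exp_unc))
    exp_unc <- exp_uncertainty(0.2, sigma_floor = subject$weight / 10)
  grid <- seq(0, max(subject$times), length.out = n_grid)
  ens <- propagate_uncertainty(draws, subject$protocol, grid)
  sd_e <- exp_sd(exp_unc, subject$measured)
  ylim <- range(ens$quantiles, subject$measured + 2 * sd_e,
                subject$measured - 2 * sd_e, na.rm = TRUE)
  graphics::plot(NA, xlim = range(grid), ylim = ylim, xlab = "time (min)",
                 ylab = expression(Delta * V[B] ~ (mL)))
  graphics::polygon(c(grid, rev(grid)),
                    c(ens$quantiles[1L, ], rev(ens$quantiles[3L, ])),
                    col = grDevices::adjustcolor("red3", 0.2), border = NA)
  graphics::arrows(subject$times, subject$measured - 1.96 * sd_e,
                   subject$times, subject$measured + 1.96 * sd_e,
                   angle = 90, code = 3, length = 0.02,
                   col = grDevices::adjustcolor("blue3", 0.5))
  graphics::lines(grid, ens$quantiles[2L, ], col = "red3", lwd = 2)
  graphics::points(subject$times, subject$measured, pch = 2, col = "grey20")
  graphics::abline(v = fit$window[2L], lty = 3)
  graphics::abline(h = 0, col = "grey80")
  invisible(NULL)
}
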