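#' Estimate time derivatives of the measured blood volume series
#'
#' The linear-regression form of the model needs the first and second time
#' derivatives of the measured `delta_vb` series. The default estimator fits
#' a cubic smoothing spline (smoothing parameter chosen by generalized
#' cross-validation) and differentiates it analytically; noisy sparse series
#' need the smoothing before a second derivative is meaningful. The
#' alternative, `"finite_diff"`, uses three-point Lagrange differentiation
#' on the (possibly non-uniform) grid — exact for quadratics — and serves as
#' a smoothing-free diagnostic.
#'
#' @param subject A [bv_subject()], or a list with numeric `times` and
#'   `measured`.
#' @param method `"spline"` (default) or `"finite_diff"`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` lets GCV choose.
#' @return A data.frame with columns `time`, `d1` (mL/min), `d2` (mL/min^2).
#' @export
estimate_derivatives <- function(subject, method = c("spline", "finite_diff"),
                                 spar = NULL) {
  method <- match.arg(method)
  tt <- subject$times
  yy <- subject$measured
  ok <- !is.na(yy)
  tt <- tt[ok]; yy <- yy[ok]
  if (length(tt) < 5L) stop("need at least 5 measurements to estimate derivatives")
  if (any(diff(tt) <= 0)) stop("measurement times must be strictly increasing")
  if (method == "spline") {
    fit <- if (is.null(spar))
      stats::smooth.spline(tt, yy, cv = FALSE, all.knots = TRUE)
    else
      stats::smooth.spline(tt, yy, spar = spar, all.knots = TRUE)
    d1 <- stats::predict(fit, tt, deriv = 1)$y
    d2 <- stats::predict(fit, tt, deriv = 2)$y
  } else {
    n <- length(tt)
    d1 <- numeric(n); d2 <- numeric(n)
    for (i in seq_len(n)) {
      j <- if (i == 1L) 1L:3L else if (i == n) (n - 2L):n else (i - 1L):(i + 1L)
      t0 <- tt[j[1L]]; t1 <- tt[j[2L]]; t2 <- tt[j[3L]]
      y0 <- yy[j[1L]]; y1 <- yy[j[2L]]; y2 <- yy[j[3L]]
      ti <- tt[i]
      d1[i] <- y0 * (2 * ti - t1 - t2) / ((t0 - t1) * (t0 - t2)) +
               y1 * (2 * ti - t0 - t2) / ((t1 - t0) * (t1 - t2)) +
               y2 * (2 * ti - t0 - t1) / ((t2 - t0) * (t2 - t1))
      d2[i] <- 2 * (y0 / ((t0 - t1) * (t0 - t2)) +
                    y1 / ((t1 - t0) * (t1 - t2)) +
                    y2 / ((t2 - t0) * (t2 - t1)))
    }
  }
  data.frame(time = tt, d1 = d1, d2 = d2)
}
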