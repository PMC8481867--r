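#' Simulate blood volume change under an infusion/hemorrhage protocol
#'
#' Forward-simulates the three-parameter BV kinetics model
#' \deqn{\ddot{\Delta V_B} + K_p \dot{\Delta V_B} =
#'   [\dot U - \dot V] + \frac{K_p}{1+\alpha_u} U(t)
#'   - \frac{K_p}{1+\alpha_v} V(t)}
#' with initial conditions \eqn{\Delta V_B(0) = 0} (normovolemia) and
#' \eqn{\dot{\Delta V_B}(0) = U(0) - V(0)}.
#'
#' Internally the equivalent first-order realization is used,
#' \eqn{\dot{\Delta V_B} = U - V - K_p[\Delta V_B - x_T(t)]} with the target
#' fluid-shift state
#' \eqn{x_T(t) = (1+\alpha_u)^{-1}\int_0^t U - (1+\alpha_v)^{-1}\int_0^t V};
#' differentiating this realization reproduces the second-order form, and it
#' contains no input derivatives, so rate discontinuities at segment
#' boundaries need no special treatment. Within each constant-rate segment
#' the state equation is linear with affine forcing and is solved in closed
#' form (`method = "closed_form"`, the reference path); `method = "ode"`
#' integrates the same realization with a generic stiff solver
#' ([deSolve::ode()]) as an independent cross-check.
#'
#' @param params A [bv_params()] object.
#' @param protocol A [bv_protocol()].
#' @param times Numeric vector of output times (min) within
#'   `[0, t_final]`, strictly increasing.
#' @param derivative If `TRUE`, include the first derivative (mL/min).
#' @param method `"closed_form"` (exact, default) or `"ode"`.
#' @return A data.frame of class `"bv_trajectory"` with columns `time`,
#'   `delta_vb` (mL) and, optionally, `d_delta_vb` (mL/min).
#' @examples
#' p <- bv_params(3, 1.4, 0.14)
#' pr <- bv_protocol(data.frame(t_start = c(0, 30), t_end = c(30, 300),
#'                              infusion = c(10, 0), hemorrhage = 0))
#' tr <- bv_simulate(p, pr, times = seq(0, 300, 10))
#' tail(tr, 1)  # approaches 300/(1 + 3) = 75 mL
#' @export
bv_simulate <- function(params, protocol, times, derivative = FALSE,
                        method = c("closed_form", "ode")) {
  stopifnot(inherits(params, "bv_params"), inherits(protocol, "bv_protocol"))
  method <- match.arg(method)
  t_final <- attr(protocol, "t_final")
  if (length(times) == 0L) stop("times must be non-empty")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (min(times) < -1e-9 || max(times) > t_final + 1e-9)
    stop("times outside [0, t_final]")
  out <- switch(method,
                closed_form = simulate_closed_form(params, protocol, times),
                ode = simulate_ode(params, protocol, times))
  tr <- data.frame(time = times, delta_vb = out$y)
  if (derivative) tr$d_delta_vb <- out$dy
  class(tr) <- c("bv_trajectory", "data.frame")
  tr
}

# Exact per-segment solution. With constant rates (u, v) on [t0, t1], the
# shift target is x_T(t) = x0 + c (t - t0), c = u/(1+au) - v/(1+av), and
#   y' = -k y + a + b (t - t0),  a = u - v + k x0,  b = k c,
# whose solution is
#   y(s) = y0 e^{-ks} + (a/k)(1 - e^{-ks}) + (b/k)(s - (1 - e^{-ks})/k).
simulate_closed_form <- function(params, protocol, times) {
  seg <- as.data.frame(protocol)
  k <- params$k_p
  gu <- 1 / (1 + params$alpha_u)
  gv <- 1 / (1 + params$alpha_v)
  y <- numeric(length(times)); dy <- numeric(length(times))
  y0 <- 0; x0 <- 0
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t_start[i]; t1 <- seg$t_end[i]
    u <- seg$infusion[i]; v <- seg$hemorrhage[i]
    cc <- u * gu - v * gv
    a <- u - v + k * x0
    b <- k * cc
    # open at t0 except the very first segment, closed at t1: output times on
    # a boundary take the later segment's closed form, which is continuous.
    sel <- if (i == 1L) which(times >= t0 - 1e-12 & times <= t1 + 1e-12)
           else which(times > t0 + 1e-12 & times <= t1 + 1e-12)
    if (length(sel)) {
      s <- times[sel] - t0
      em <- exp(-k * s)
      ys <- y0 * em + (a / k) * (1 - em) + (b / k) * (s - (1 - em) / k)
      y[sel] <- ys
      dy[sel] <- -k * ys + a + b * s
    }
    s1 <- t1 - t0
    em1 <- exp(-k * s1)
    y0 <- y0 * em1 + (a / k) * (1 - em1) + (b / k) * (s1 - (1 - em1) / k)
    x0 <- x0 + cc * s1
  }
  list(y = y, dy = dy)
}

# Generic-integrator cross-check on the 2-state realization (y, x_T),
# integrated segment by segment so rate discontinuities fall on mesh points.
simulate_ode <- function(params, protocol, times, rtol = 1e-10, atol = 1e-8) {
  seg <- as.data.frame(protocol)
  k <- params$k_p
  gu <- 1 / (1 + params$alpha_u)
  gv <- 1 / (1 + params$alpha_v)
  state <- c(y = 0, x = 0)
  y <- numeric(length(times)); dy <- numeric(length(times))
  if (times[1L] <= 1e-12) {
    y[1L] <- 0
    dy[1L] <- seg$infusion[1L] - seg$hemorrhage[1L]
  }
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t_start[i]; t1 <- seg$t_end[i]
    u <- seg$infusion[i]; v <- seg$hemorrhage[i]
    rhs <- function(t, st, p) {
      list(c(u - v - k * (st[1L] - st[2L]), u * gu - v * gv))
    }
    sel <- which(times > t0 + 1e-12 & times <= t1 + 1e-12)
    tt <- sort(unique(c(t0, times[sel], t1)))
    sol <- deSolve::ode(y = state, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (length(sel)) {
      m <- match(round(times[sel], 12), round(sol[, "time"], 12))
      y[sel] <- sol[m, "y"]
      dy[sel] <- u - v - k * (sol[m, "y"] - sol[m, "x"])
    }
    state <- c(y = unname(sol[nrow(sol), "y"]), x = unname(sol[nrow(sol), "x"]))
  }
  list(y = y, dy = dy)
}

#' Long-time blood volume change after all inputs cease
#'
#' Analytic limit of the model once infusion and hemorrhage have stopped:
#' the intravascular compartment relaxes to the shift target, so
#' \eqn{\Delta V_B(\infty) = U_{tot}/(1+\alpha_u) - V_{tot}/(1+\alpha_v)}.
#'
#' @param params A [bv_params()] object.
#' @param total_infused Total infused volume, mL.
#' @param total_hemorrhaged Total hemorrhaged volume, mL.
#' @return Steady-state change in blood volume, mL.
#' @export
bv_steady_state <- function(params, total_infused, total_hemorrhaged) {
  stopifnot(inherits(params, "bv_params"),
            total_infused >= 0, total_hemorrhaged >= 0)
  total_infused / (1 + params$alpha_u) -
    total_hemorrhaged / (1 + params$alpha_v)
}

#' Blood volume change from serial hematocrit
#'
#' Under constant red-blood-cell volume, hematocrit encodes fractional blood
#' volume change: `RBCV = hct0 * bv0 = hct_t * (bv0 + delta)`, hence
#' `delta = bv0 * (hct0/hct_t - 1)`.
#'
#' @param bv0 Baseline blood volume, mL (`> 0`).
#' @param hct0 Baseline hematocrit, fraction in (0, 1).
#' @param hct_t Hematocrit at the evaluation time, fraction in (0, 1);
#'   may be a vector.
#' @return Change in blood volume, mL (vectorized over `hct_t`).
#' @examples
#' delta_vb_from_hct(3000, 0.30, 0.25)  # +600 mL (hemodilution)
#' delta_vb_from_hct(3000, 0.30, 0.40)  # -750 mL (hemoconcentration)
#' @export
delta_vb_from_hct <- function(bv0, hct0, hct_t) {
  if (bv0 <= 0) stop("bv0 must be positive")
  if (hct0 <= 0 || hct0 >= 1 || any(hct_t <= 0) || any(hct_t >= 1))
    stop("hematocrit values must lie in (0, 1)")
  bv0 * (hct0 / hct_t - 1)
}
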