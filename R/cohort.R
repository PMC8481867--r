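#' A single subject's record
#'
#' Bundles everything known about one (real or synthetic) subject: weight,
#' the input protocol actually delivered, the measurement times and measured
#' change in blood volume, and — for synthetic subjects only — the generating
#' parameters and any injected model violation.
#'
#' @param subject_id Identifier (character or integer).
#' @param weight Weight in kg.
#' @param protocol A [bv_protocol()].
#' @param times Measurement times, min; must start at 0.
#' @param measured Measured change in blood volume at `times`, mL; the first
#'   value must be 0 (baseline normovolemia). `NA` marks prediction-only rows.
#' @param true_params Generating [bv_params()] for synthetic subjects, else
#'   `NULL`.
#' @param mismatch_tag `"none"`, or the label of an injected model violation.
#' @param noise_sd Proportional noise level used to generate `measured`
#'   (synthetic subjects; informational).
#' @return An object of class `"bv_subject"`.
#' @export
bv_subject <- function(subject_id, weight, protocol, times, measured,
                       true_params = NULL, mismatch_tag = "none",
                       noise_sd = NA_real_) {
  stopifnot(inherits(protocol, "bv_protocol"),
            length(times) == length(measured))
  if (any(diff(times) <= 0)) stop("measurement times must be strictly increasing")
  t_final <- attr(protocol, "t_final")
  if (times[1L] > 1e-9 || min(times) < 0 || max(times) > t_final + 1e-9)
    stop("measurement times must lie in [0, t_final] and start at 0")
  if (!is.na(measured[1L]) && abs(measured[1L]) > 1e-9)
    stop("first measurement (t = 0) must be 0: baseline is normovolemia")
  structure(list(subject_id = subject_id, weight = weight,
                 protocol = protocol, times = as.numeric(times),
                 measured = as.numeric(measured), true_params = true_params,
                 mismatch_tag = mismatch_tag, noise_sd = noise_sd),
            class = "bv_subject")
}

#' @export
print.bv_subject <- function(x, ...) {
  cat(sprintf("BV subject '%s': %.1f kg, %d measurements on [0, %g] min",
              as.character(x$subject_id), x$weight, length(x$times),
              max(x$times)))
  if (!is.null(x$true_params))
    cat(sprintf("\n  synthetic (alpha_u=%.3g, alpha_v=%.3g, k_p=%.3g; noise_sd=%.3g, mismatch=%s)",
                x$true_params$alpha_u, x$true_params$alpha_v,
                x$true_params$k_p, x$noise_sd, x$mismatch_tag))
  cat("\n")
  invisible(x)
}

#' Configuration of the synthetic ovine cohort
#'
#' Defines the statistical population from which virtual subjects are drawn.
#' Defaults emulate the controlled ovine hemorrhage/resuscitation study the
#' package is designed around: 180 min records, the fixed weight-normalized
#' hemorrhage schedule of [hemorrhage_schedule()], subject-specific infusion
#' starting at 30 min, blood volume sampled every 5 min (optionally jittered
#' to 5–10 min), and multiplicative measurement noise.
#'
#' Parameter-sampling defaults are anchored to published cohort estimates:
#' `alpha_u` is log-normal around a nominal 3, `alpha_v` log-uniform on
#' 0.35–3.2 and `k_p` log-uniform on 0.07–0.27 1/min.
#'
#' @param n_subjects Number of virtual subjects.
#' @param weight_range Uniform weight range, kg.
#' @param alpha_u_nominal,alpha_u_spread `alpha_u` is drawn as
#'   `alpha_u_nominal * exp(rnorm(1, 0, alpha_u_spread))`.
#' @param alpha_v_range,k_p_range Log-uniform sampling ranges.
#' @param noise_sd Proportional measurement noise standard deviation
#'   (dimensionless); `measured = true * (1 + eps)`, `eps ~ N(0, noise_sd)`.
#' @param sampling_interval Nominal measurement spacing, min.
#' @param jitter_sampling If `TRUE`, gaps are drawn uniformly from
#'   `[sampling_interval, 2 * sampling_interval]` (emulating 5–10 min
#'   intervals at the default spacing).
#' @param infusion_family One of `"constant"`, `"stepped"`,
#'   `"proportional"` — see [sample_infusion_schedule()].
#' @param infusion_total_range For the constant and stepped families, the
#'   total infused volume is this factor range times the total hemorrhage
#'   volume (35 mL/kg), spanning under- to over-resuscitation.
#' @param t_final Record duration, min.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A list of class `"bv_cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 20, weight_range = c(25, 45),
                          alpha_u_nominal = 3, alpha_u_spread = 0.2,
                          alpha_v_range = c(0.35, 3.2),
                          k_p_range = c(0.07, 0.27),
                          noise_sd = 0.10, sampling_interval = 5,
                          jitter_sampling = FALSE,
                          infusion_family = c("constant", "stepped",
                                              "proportional"),
                          infusion_total_range = c(0.5, 1.5),
                          t_final = 180, seed = 1L) {
  infusion_family <- match.arg(infusion_family)
  stopifnot(n_subjects >= 0, noise_sd >= 0, sampling_interval > 0,
            diff(weight_range) >= 0, all(alpha_v_range > 0),
            all(k_p_range > 0), alpha_u_spread >= 0)
  structure(list(n_subjects = n_subjects, weight_range = weight_range,
                 alpha_u_nominal = alpha_u_nominal,
                 alpha_u_spread = alpha_u_spread,
                 alpha_v_range = alpha_v_range, k_p_range = k_p_range,
                 noise_sd = noise_sd, sampling_interval = sampling_interval,
                 jitter_sampling = jitter_sampling,
                 infusion_family = infusion_family,
                 infusion_total_range = infusion_total_range,
                 t_final = t_final, seed = as.integer(seed)),
            class = "bv_cohort_config")
}

#' Draw a subject-specific infusion schedule
#'
#' Infusion is zero before 30 min (15 min after the end of the initial
#' hemorrhage) and piecewise-constant on `[30, t_final]`, drawn from one of
#' three families:
#' * `"constant"` — a single rate; total volume is a uniform draw from
#'   `infusion_total_range` times the 35 mL/kg hemorrhage total.
#' * `"stepped"` — rates change only at multiples of the sampling interval,
#'   rescaled to a drawn total as above.
#' * `"proportional"` — rate updated every sampling interval in proportion
#'   to the current cumulative fluid deficit (a crude closed-loop
#'   resuscitation emulation).
#'
#' Draws use the current RNG state; [generate_cohort()] wraps this with its
#' seed discipline.
#'
#' @param config A [cohort_config()].
#' @param weight Subject weight, kg.
#' @return Infusion schedule data.frame (`t_start`, `t_end`, `rate`) for
#'   [combine_schedules()]; zero rows if the drawn total is 0.
#' @export
sample_infusion_schedule <- function(config, weight) {
  t0 <- 30; t1 <- config$t_final
  target_total <- stats::runif(1, config$infusion_total_range[1L],
                               config$infusion_total_range[2L]) * 35 * weight
  switch(config$infusion_family,
    constant = {
      if (target_total <= 0)
        return(data.frame(t_start = numeric(0), t_end = numeric(0),
                          rate = numeric(0)))
      data.frame(t_start = t0, t_end = t1, rate = target_total / (t1 - t0))
    },
    stepped = {
      step <- config$sampling_interval * sample(c(2, 3, 4), 1)
      starts <- t0 + step * seq_len(ceiling((t1 - t0) / step - 1e-9)) - step
      ends <- pmin(starts + step, t1)
      raw <- stats::runif(length(starts), 0.3, 1.7)
      rate <- raw * target_total / sum(raw * (ends - starts))
      data.frame(t_start = starts, t_end = ends, rate = rate)
    },
    proportional = {
      gain <- stats::runif(1, 0.3, 0.9)
      tau <- 60  # min; response time of the emulated resuscitation rule
      hem <- hemorrhage_schedule(weight)
      hem_proto <- combine_schedules(
        data.frame(t_start = numeric(0), t_end = numeric(0), rate = numeric(0)),
        hem, t_final = t1)
      h <- config$sampling_interval
      starts <- t0 + h * seq_len(ceiling((t1 - t0) / h - 1e-9)) - h
      ends <- pmin(starts + h, t1)
      rate <- numeric(length(starts))
      infused <- 0
      for (i in seq_along(starts)) {
        deficit <- protocol_cumulative(hem_proto, starts[i])[2L] - infused
        rate[i] <- max(0, gain * deficit / tau)
        infused <- infused + rate[i] * (ends[i] - starts[i])
      }
      data.frame(t_start = starts, t_end = ends, rate = rate)
    })
}

#' Generate a synthetic ovine cohort
#'
#' For each subject: draw weight and true parameters from the configured
#' distributions, build the protocol (fixed hemorrhage schedule plus a drawn
#' infusion schedule), simulate the exact model, sample it at the
#' measurement times, and apply multiplicative noise
#' `measured = true * (1 + eps)`, `eps ~ N(0, noise_sd)`. The first
#' measurement is at t = 0 with value 0. A fixed config (including its seed)
#' regenerates the cohort bit-identically.
#'
#' @param config A [cohort_config()].
#' @return A list of [bv_subject()] records, class `"bv_cohort"`, with the
#'   config attached as attribute `"config"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "bv_cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    w <- stats::runif(1, config$weight_range[1L], config$weight_range[2L])
    au <- config$alpha_u_nominal * exp(stats::rnorm(1, 0, config$alpha_u_spread))
    av <- exp(stats::runif(1, log(config$alpha_v_range[1L]),
                           log(config$alpha_v_range[2L])))
    kp <- exp(stats::runif(1, log(config$k_p_range[1L]),
                           log(config$k_p_range[2L])))
    params <- bv_params(au, av, kp)
    infusion <- sample_infusion_schedule(config, w)
    protocol <- combine_schedules(infusion, hemorrhage_schedule(w),
                                  t_final = config$t_final)
    times <- sample_measurement_times(config)
    truth <- bv_simulate(params, protocol, times)$delta_vb
    eps <- stats::rnorm(length(times), 0, config$noise_sd)
    measured <- truth * (1 + eps)
    measured[1L] <- 0
    subjects[[i]] <- bv_subject(subject_id = i, weight = w,
                                protocol = protocol, times = times,
                                measured = measured, true_params = params,
                                mismatch_tag = "none",
                                noise_sd = config$noise_sd)
  }
  structure(subjects, class = "bv_cohort", config = config)
}

sample_measurement_times <- function(config) {
  if (!config$jitter_sampling)
    return(seq(0, config$t_final, by = config$sampling_interval))
  tt <- 0
  while (tt[length(tt)] < config$t_final) {
    gap <- stats::runif(1, config$sampling_interval,
                        2 * config$sampling_interval)
    tt <- c(tt, min(tt[length(tt)] + gap, config$t_final))
  }
  tt
}

#' @export
print.bv_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic BV cohort: %d subjects (noise_sd=%.3g, family=%s, seed=%d)\n",
              length(x), cfg$noise_sd, cfg$infusion_family, cfg$seed))
  invisible(x)
}

#' Inject a model violation into a synthetic subject
#'
#' Regenerates a synthetic subject's measurements from a perturbed generator
#' to emulate subjects for which the nominal model structure fails:
#'
#' * `"compensatory-gain"`: an endogenous first-order refill term recruits
#'   fluid into circulation at rate `gain * max(0, -delta_vb)` (mL/min per
#'   mL of deficit), driving blood volume back toward baseline even with
#'   little infusion — an unmodeled compensatory mechanism.
#' * `"asymmetric-kp"`: the fluid-shift rate differs by direction:
#'   `k_p` applies while volume shifts out of the vasculature, and
#'   `asymmetry * k_p` while it shifts in.
#' * `"none"`: record returned unchanged.
#'
#' The perturbed dynamics are integrated numerically; fresh proportional
#' noise at the record's `noise_sd` is applied using the current RNG state.
#'
#' @param subject A synthetic [bv_subject()] (must carry `true_params`).
#' @param kind `"none"`, `"compensatory-gain"` or `"asymmetric-kp"`.
#' @param gain Refill gain, 1/min (compensatory-gain).
#' @param asymmetry Multiplier on `k_p` for inward shift (asymmetric-kp);
#'   `1` reproduces the nominal model.
#' @return The modified [bv_subject()] with `mismatch_tag` set.
#' @export
inject_model_mismatch <- function(subject, kind = c("none",
                                                    "compensatory-gain",
                                                    "asymmetric-kp"),
                                  gain = 0.2, asymmetry = 4) {
  kind <- match.arg(kind)
  stopifnot(inherits(subject, "bv_subject"))
  if (is.null(subject$true_params))
    stop("mismatch can only be injected into synthetic subjects")
  if (kind == "none") return(subject)
  truth <- simulate_mismatch(subject$true_params, subject$protocol,
                             subject$times, kind, gain, asymmetry)
  noise_sd <- if (is.na(subject$noise_sd)) 0 else subject$noise_sd
  eps <- stats::rnorm(length(subject$times), 0, noise_sd)
  measured <- truth * (1 + eps)
  measured[1L] <- 0
  subject$measured <- measured
  subject$mismatch_tag <- kind
  subject
}

# Perturbed-generator trajectories (numerical integration; the perturbations
# break the per-segment linearity the closed form relies on).
simulate_mismatch <- function(params, protocol, times, kind, gain, asymmetry) {
  seg <- as.data.frame(protocol)
  k <- params$k_p
  gu <- 1 / (1 + params$alpha_u)
  gv <- 1 / (1 + params$alpha_v)
  state <- c(y = 0, x = 0)
  out <- numeric(length(times))
  if (times[1L] <= 1e-12) out[1L] <- 0
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t_start[i]; t1 <- seg$t_end[i]
    u <- seg$infusion[i]; v <- seg$hemorrhage[i]
    rhs <- switch(kind,
      "compensatory-gain" = function(t, st, p) {
        refill <- gain * max(0, -st[1L])
        list(c(u - v - k * (st[1L] - st[2L]) + refill,
               u * gu - v * gv + refill))
      },
      "asymmetric-kp" = function(t, st, p) {
        keff <- if (st[1L] > st[2L]) k else asymmetry * k
        list(c(u - v - keff * (st[1L] - st[2L]), u * gu - v * gv))
      })
    sel <- which(times > t0 + 1e-12 & times <= t1 + 1e-12)
    tt <- sort(unique(c(t0, times[sel], t1)))
    sol <- deSolve::ode(y = state, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    if (length(sel)) {
      m <- match(round(times[sel], 12), round(sol[, "time"], 12))
      out[sel] <- sol[m, "y"]
    }
    state <- c(y = unname(sol[nrow(sol), "y"]), x = unname(sol[nrow(sol), "x"]))
  }
  out
}
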