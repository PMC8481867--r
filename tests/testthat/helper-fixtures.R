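# Shared fixtures: random parameter/protocol generators and noise replicates.

random_params <- function() {
  bv_params(alpha_u = exp(stats::runif(1, log(0.5), log(8))),
            alpha_v = exp(stats::runif(1, log(0.3), log(4))),
            k_p = exp(stats::runif(1, log(0.03), log(0.4))))
}

# Random contiguous piecewise-constant protocol with 2-6 segments.
random_protocol <- function(t_final = 180) {
  n_seg <- sample(2:6, 1)
  brk <- sort(c(0, stats::runif(n_seg - 1, 5, t_final - 5), t_final))
  bv_protocol(data.frame(
    t_start = brk[-length(brk)], t_end = brk[-1L],
    infusion = stats::runif(n_seg, 0, 15) * stats::rbinom(n_seg, 1, 0.7),
    hemorrhage = stats::runif(n_seg, 0, 40) * stats::rbinom(n_seg, 1, 0.5)),
    t_final = t_final)
}

# The reference ovine protocol with a constant-rate infusion (fraction of
# the 35 mL/kg hemorrhage total, delivered over 30-180 min).
reference_protocol <- function(weight, infusion_fraction = 1) {
  total <- infusion_fraction * 35 * weight
  inf <- if (total > 0)
    data.frame(t_start = 30, t_end = 180, rate = total / 150)
  else data.frame(t_start = numeric(0), t_end = numeric(0), rate = numeric(0))
  combine_schedules(inf, hemorrhage_schedule(weight), t_final = 180)
}

# Fresh multiplicative-noise replicate of a synthetic subject.
replicate_with_noise <- function(subject, noise_sd) {
  truth <- bv_simulate(subject$true_params, subject$protocol,
                       subject$times)$delta_vb
  meas <- truth * (1 + stats::rnorm(length(truth), 0, noise_sd))
  meas[1L] <- 0
  subject$measured <- meas
  subject$noise_sd <- noise_sd
  subject
}

# Exact derivatives of the model trajectory (oracle for regressor tests).
exact_derivatives <- function(subject, h = 1e-4) {
  tr <- bv_simulate(subject$true_params, subject$protocol, subject$times,
                    derivative = TRUE)
  t_final <- attr(subject$protocol, "t_final")
  up <- bv_simulate(subject$true_params, subject$protocol,
                    pmin(subject$times + h, t_final))$delta_vb
  dn <- bv_simulate(subject$true_params, subject$protocol,
                    pmax(subject$times - h, 0))$delta_vb
  data.frame(time = subject$times, d1 = tr$d_delta_vb,
             d2 = (up - 2 * tr$delta_vb + dn) / h^2)
}
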