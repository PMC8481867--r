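test_that("a single-draw ensemble collapses to its trajectory", {
  p <- bv_params(3, 1.4, 0.14)
  pr <- reference_protocol(30)
  draws <- matrix(c(3, 1.4, 0.14), 1, 3,
                  dimnames = list(NULL, c("alpha_u", "alpha_v", "k_p")))
  tt <- seq(0, 180, 30)
  ens <- propagate_uncertainty(draws, pr, tt)
  ref <- bv_simulate(p, pr, tt)$delta_vb
  expect_equal(unname(ens$quantiles["2.5%", ]), ref)
  expect_equal(unname(ens$quantiles["97.5%", ]), ref)
  expect_error(propagate_uncertainty(draws[0, , drop = FALSE], pr, tt),
               "empty")
})

test_that("percentile bands are nested and contain the truth when calibrated", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0.1, seed = 6)
  s <- generate_cohort(cfg)[[1L]]
  f <- bv_fit(s, c(0, 50), fix_alpha_u = s$true_params$alpha_u, seed = 42)
  d <- sample_parameters(f, n = 2000, seed = 9)
  tt <- seq(5, 180, 5)
  ens <- propagate_uncertainty(d, s$protocol, tt)
  expect_true(all(ens$quantiles["2.5%", ] <= ens$quantiles["50%", ]))
  expect_true(all(ens$quantiles["50%", ] <= ens$quantiles["97.5%", ]))
  truth <- bv_simulate(s$true_params, s$protocol, tt)$delta_vb
  inside <- truth >= ens$quantiles["2.5%", ] & truth <= ens$quantiles["97.5%", ]
  expect_gte(mean(inside), 0.9)
})

test_that("agreement probability follows the independence product form", {
  pr <- reference_protocol(30)
  mk_ens <- function(values, t = 180) {
    structure(list(times = t,
                   trajectories = matrix(values, ncol = 1),
                   quantiles = NULL), class = "bv_ensemble")
  }
  eu <- exp_uncertainty(c_exp = 0.2)
  # all trajectories positive, measurement clearly positive: certain agreement
  expect_equal(agreement_probability(mk_ens(rep(1, 100)), 50, eu, 180), 1,
               tolerance = 1e-6)
  # all trajectories negative, measurement clearly positive: certain miss
  expect_lt(agreement_probability(mk_ens(rep(-1, 100)), 50, eu, 180), 1e-6)
  # p_m = 0.6 with p_e ~ Phi(5) ~ 1: agreement equals p_m
  ens <- mk_ens(c(rep(1, 60), rep(-1, 40)))
  expect_equal(agreement_probability(ens, 50, eu, 180), 0.6,
               tolerance = 1e-6)
  # explicit product form at an intermediate p_e
  p_e <- stats::pnorm(10 / (0.2 * 10))
  expect_equal(agreement_probability(ens, 10, eu, 180),
               0.6 * p_e + 0.4 * (1 - p_e))
  # symmetric under simultaneous sign flip of model and measurement
  expect_equal(agreement_probability(mk_ens(-c(rep(1, 60), rep(-1, 40))),
                                     -10, eu, 180),
               agreement_probability(ens, 10, eu, 180), tolerance = 1e-12)
  # degenerate zero-sd, zero-measurement case is rejected with guidance
  expect_error(agreement_probability(ens, 0, exp_uncertainty(0.2, 0), 180),
               "sigma_floor")
  expect_error(agreement_probability(ens, 10, eu, 90), "grid")
})

test_that("subject validation reports both tests and handles missing T*", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0.1, seed = 6)
  s <- generate_cohort(cfg)[[1L]]
  f <- bv_fit(s, c(0, 50), fix_alpha_u = 3, seed = 42)
  d <- sample_parameters(f, n = 500, seed = 9)
  rep <- validate_subject(s, d)
  expect_true(rep$p_agreement_180 >= 0 && rep$p_agreement_180 <= 1)
  expect_identical(is.na(rep$p_agreement_tstar), is.na(rep$t_star))
  # a never-resuscitated subject has no T*
  cfg0 <- cohort_config(n_subjects = 1, noise_sd = 0.1, seed = 6,
                        infusion_total_range = c(0, 0))
  s0 <- generate_cohort(cfg0)[[1L]]
  f0 <- bv_fit(s0, c(0, 50), fix_alpha_u = 3, seed = 42)
  d0 <- sample_parameters(f0, n = 200, seed = 9)
  rep0 <- validate_subject(s0, d0)
  expect_true(is.na(rep0$t_star))
  expect_true(is.na(rep0$p_agreement_tstar))
})

test_that("agreement is near-certain for a confidently correct prediction", {
  # over-resuscitated subject: model and measurement both end clearly
  # positive with tight bands
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0.05, seed = 20,
                       alpha_v_range = c(3, 3.2),
                       infusion_total_range = c(1.6, 1.6))
  s <- generate_cohort(cfg)[[1L]]
  expect_gt(s$measured[length(s$measured)], 0)
  f <- bv_fit(s, c(0, 50), fix_alpha_u = s$true_params$alpha_u, seed = 1)
  d <- sample_parameters(f, n = 1000, seed = 2)
  rep <- validate_subject(s, d)
  expect_gt(rep$p_agreement_180, 0.95)
})

test_that("experimental uncertainty applies the proportional-sd model", {
  eu <- exp_uncertainty(0.2, sigma_floor = 3)
  expect_equal(bvkinetics:::exp_sd(eu, c(-100, 0, 10)), c(20, 3, 3))
  expect_error(exp_uncertainty(-0.1), "c_exp")
})
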