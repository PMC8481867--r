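test_that("proportional residuals follow the error-model definition", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0, seed = 4)
  s <- generate_cohort(cfg)[[1L]]
  # at the generating parameters on a noise-free record, residuals vanish
  r0 <- bv_objective(s$true_params, s, c(0, 50))
  expect_lt(max(abs(r0)), 1e-10)
  # at other parameters, residuals equal (model - measured) / max(|model|, delta)
  p <- bv_params(2, 1, 0.1)
  sel <- which(s$times > 0 & s$times <= 50)
  m <- bv_simulate(p, s$protocol, s$times[sel])$delta_vb
  e <- s$measured[sel]
  delta <- 0.01 * max(abs(e))
  expect_equal(bv_objective(p, s, c(0, 50)),
               (m - e) / pmax(abs(m), delta))
  # hand case: measurement at 100/110 of the model value gives the
  # model-110-vs-measured-100 residual, (110-100)/110 = 0.0909...
  s2 <- s
  j <- match(40, s$times[sel])
  s2$measured[sel[j]] <- m[j] * 100 / 110
  r <- bv_objective(p, s2, c(0, 50))
  expect_equal(abs(r[j]), 10 / 110, tolerance = 1e-12)
})

test_that("the denominator floor keeps residuals finite near normovolemia", {
  pr <- bv_protocol(data.frame(t_start = 0, t_end = 60,
                               infusion = 0, hemorrhage = 0))
  tt <- seq(0, 60, 5)
  meas <- c(0, rep(2, length(tt) - 1))  # pure noise around zero volume
  s <- bv_subject("z", 30, pr, tt, meas)
  # model is identically zero; only the floor delta = 1 bounds the weights
  r <- bv_objective(bv_params(1, 1, 0.1), s, c(0, 60), delta = 1)
  expect_true(all(is.finite(r)))
  expect_equal(r, rep(-2, length(r)))
})

test_that("rmsne matches its definition on hand-computed cases", {
  expect_equal(rmsne(c(5, 5), c(5, 5)), 0)
  expect_equal(rmsne(c(2, 2), c(1, 3)), 0.5)
  expect_equal(rmsne(c(11, -11), c(10, -10)), 0.1)
  expect_error(rmsne(c(1, 2), c(0, 0)), "all zero")
  expect_error(rmsne(1:3, 1:2), "length")
})

test_that("noise-free calibration recovers the generating parameters", {
  cfg <- cohort_config(n_subjects = 2, noise_sd = 0, seed = 4)
  for (s in generate_cohort(cfg)) {
    f <- bv_fit(s, c(0, 50), fix_alpha_u = s$true_params$alpha_u, seed = 2)
    expect_true(f$converged)
    expect_equal(unname(coef(f)["alpha_v"]), s$true_params$alpha_v,
                 tolerance = 1e-3)
    expect_equal(unname(coef(f)["k_p"]), s$true_params$k_p,
                 tolerance = 1e-3)
    expect_lt(f$rmsne, 0.005)
    expect_false(any(f$unidentifiable))
  }
})

test_that("repeated fits with the same seed are bit-identical", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0.1, seed = 6)
  s <- generate_cohort(cfg)[[1L]]
  f1 <- bv_fit(s, c(0, 50), fix_alpha_u = 3, seed = 42)
  f2 <- bv_fit(s, c(0, 50), fix_alpha_u = 3, seed = 42)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$vcov, f2$vcov)
  expect_identical(f1$rmsne, f2$rmsne)
})

test_that("alpha_u is unidentifiable when the window carries no infusion", {
  # calibration window ends before infusion starts: the objective is flat
  # (indeed decreasing) in alpha_u, so the three-parameter fit must flag it
  cfg <- cohort_config(n_subjects = 2, noise_sd = 0.05, seed = 13)
  for (s in generate_cohort(cfg)) {
    f <- bv_fit(s, c(0, 25), seed = 7)
    expect_true(f$unidentifiable[["alpha_u"]])
  }
})

test_that("the optimizer never loses to the generating parameters on SSR", {
  cfg <- cohort_config(n_subjects = 5, noise_sd = 0.1, seed = 19)
  for (s in generate_cohort(cfg)) {
    f <- bv_fit(s, c(0, 50), fix_alpha_u = s$true_params$alpha_u, seed = 3)
    ssr_true <- sum(bv_objective(s$true_params, s, c(0, 50),
                                 delta = f$delta)^2)
    expect_lte(f$ssr, ssr_true + 1e-10)
  }
})

test_that("fit accessors are mutually consistent", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0.1, seed = 6)
  s <- generate_cohort(cfg)[[1L]]
  f <- bv_fit(s, c(0, 50), fix_alpha_u = 3, seed = 42)
  expect_named(coef(f), c("alpha_v", "k_p"))
  expect_equal(dim(vcov(f)), c(2L, 2L))
  expect_equal(length(residuals(f)), f$n)
  expect_equal(length(fitted(f)), f$n)
  expect_equal(f$rmsne, rmsne(fitted(f),
                              s$measured[s$times > 0 & s$times <= 50]))
  pred <- predict(f, times = c(0, 90, 180))
  expect_equal(pred$delta_vb[1L], 0)
  ci <- confint(f)
  expect_true(all(ci[, "low"] <= coef(f) & coef(f) <= ci[, "high"]))
  # asymptotic (z) intervals are strictly narrower than t intervals
  ciz <- confint(f, asymptotic = TRUE)
  expect_true(all(ciz[, "high"] - ciz[, "low"] < ci[, "high"] - ci[, "low"]))
  expect_error(bv_fit(s, c(0, 10)), "at least 4")
})

test_that("cohort calibration applies the two-stage policy and exclusions", {
  expect_length(calibrate_cohort(list())$fits, 0L)
  cfg <- cohort_config(n_subjects = 6, noise_sd = 0.1, seed = 42)
  coh <- generate_cohort(cfg)
  cc <- calibrate_cohort(coh, c(0, 50), fix_alpha_u = 3, seed = 100)
  expect_length(cc$fits, 6L)
  expect_length(cc$stage1, 6L)
  if (cc$refit_triggered)
    expect_true(all(vapply(cc$fits,
                           function(f) identical(f$fixed_alpha_u, 3),
                           logical(1))))
  expect_true(all(cc$excluded$subject_id %in%
                    vapply(coh, function(s) as.character(s$subject_id),
                           character(1))))
  retained <- setdiff(vapply(coh, function(s) as.character(s$subject_id),
                             character(1)), cc$excluded$subject_id)
  if (length(retained)) expect_gt(cc$summary$mean_rmsne, 0)
})
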