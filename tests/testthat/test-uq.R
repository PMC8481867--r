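make_fit <- function(noise_sd = 0.1, seed = 6, fit_seed = 42) {
  cfg <- cohort_config(n_subjects = 1, noise_sd = noise_sd, seed = seed)
  s <- generate_cohort(cfg)[[1L]]
  bv_fit(s, c(0, 50), fix_alpha_u = 3, seed = fit_seed)
}

# Minimal hand-built fit object for distributional checks with a known
# covariance (bypasses the optimizer entirely).
synthetic_fit <- function(est, Sigma, free = names(est), df = 8) {
  dimnames(Sigma) <- list(free, free)
  se <- sqrt(diag(Sigma))
  names(se) <- free
  structure(list(coefficients = est, free = free, vcov = Sigma, se = se,
                 converged = TRUE, df = df,
                 fixed_alpha_u = if (!"alpha_u" %in% free) 3,
                 cap = 1e3, n = df + length(free)),
            class = "bv_fit")
}

test_that("interval arithmetic matches the hand-computed normal case", {
  f <- synthetic_fit(c(alpha_v = 1, k_p = 0.13),
                     diag(c(0.04, 0.0049)))
  cs <- confidence_summary(f, asymptotic = TRUE)
  # k_p: 0.13 +/- 1.96 * 0.07
  expect_equal(unname(cs$intervals["k_p", c("low", "high")]),
               c(0.13 - stats::qnorm(0.975) * 0.07,
                 0.13 + stats::qnorm(0.975) * 0.07), tolerance = 1e-10)
  expect_equal(unname(cs$intervals["k_p", "high"]), 0.2672, tolerance = 1e-4)
  expect_true(all(cs$bounded))
  expect_equal(cs$ellipse$radius2, stats::qchisq(0.95, 2))
})

test_that("noise-free fits have near-zero interval half-widths", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0, seed = 4)
  s <- generate_cohort(cfg)[[1L]]
  f <- bv_fit(s, c(0, 50), fix_alpha_u = s$true_params$alpha_u, seed = 2)
  cs <- confidence_summary(f)
  half <- (cs$intervals[, "high"] - cs$intervals[, "low"]) / 2
  expect_lt(max(half / abs(cs$intervals[, "estimate"])), 1e-3)
  expect_true(all(cs$bounded))
})

test_that("interval endpoints transform linearly under rescaling", {
  f <- make_fit()
  cs <- confidence_summary(f)
  g <- f
  a <- 10
  g$coefficients <- a * f$coefficients
  g$vcov <- a^2 * f$vcov
  g$se <- a * f$se
  cs2 <- confidence_summary(g)
  expect_equal(cs2$intervals[, "low"], a * cs$intervals[, "low"])
  expect_equal(cs2$intervals[, "high"], a * cs$intervals[, "high"])
})

test_that("cost contours are bounded around an identifiable pair", {
  f <- make_fit()
  cg <- cost_contours(f, pair = c("alpha_v", "k_p"), n = 21)
  expect_true(all(cg$bounded))
  # the estimate's cost is the minimum of the evaluated surface (to grid
  # resolution) and lies inside the threshold sublevel set
  expect_lte(f$ssr, min(cg$cost) + 1e-8)
  expect_gt(cg$threshold, f$ssr)
  # near the optimum the surface matches its quadratic (Gauss-Newton) model
  H <- 2 * crossprod(f$jacobian)
  d <- c(0.02 * f$se[1L], 0.02 * f$se[2L])
  th <- f$coefficients + d
  au <- f$fixed_alpha_u
  actual <- sum(bv_objective(bv_params(au, th[["alpha_v"]], th[["k_p"]]),
                             f$subject, f$window, delta = f$delta)^2)
  predicted <- f$ssr + 0.5 * drop(t(d) %*% H %*% d)
  expect_equal(actual, predicted, tolerance = 0.05)
})

test_that("cost contours are unbounded along alpha_u without infusion data", {
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0.05, seed = 13)
  s <- generate_cohort(cfg)[[1L]]
  f <- bv_fit(s, c(0, 25), seed = 7)  # window ends before infusion starts
  cg <- cost_contours(f, pair = c("alpha_u", "alpha_v"), n = 15,
                      ranges = list(alpha_u = c(0.5, 500),
                                    alpha_v = c(0.2, 4)))
  expect_false(cg$bounded[["alpha_u"]])
})

test_that("parameter draws respect the covariance and exclusion rules", {
  # zero covariance: every draw equals the estimate, nothing excluded
  f0 <- synthetic_fit(c(alpha_v = 1.2, k_p = 0.15),
                      matrix(0, 2, 2, dimnames = list(c("alpha_v", "k_p"),
                                                      c("alpha_v", "k_p"))))
  d0 <- sample_parameters(f0, n = 50, seed = 1)
  expect_equal(nrow(d0$draws), 50L)
  expect_true(all(d0$draws[, "alpha_v"] == 1.2))
  expect_true(all(d0$draws[, "k_p"] == 0.15))
  expect_identical(d0$exclusion_fraction, 0)
  expect_true(all(d0$draws[, "alpha_u"] == 3))
  # reproducibility
  f <- make_fit()
  d1 <- sample_parameters(f, n = 500, seed = 9)
  d2 <- sample_parameters(f, n = 500, seed = 9)
  expect_identical(d1$draws, d2$draws)
  # exclusion fraction matches the normal tail mass for k_p <= 0
  fk <- synthetic_fit(c(alpha_v = 1.2, k_p = 0.13),
                      diag(c(1e-6, 0.069^2)))
  dk <- sample_parameters(fk, n = 10000, seed = 11)
  expect_lt(abs(dk$exclusion_fraction - stats::pnorm(-0.13 / 0.069)), 0.005)
  # the k_p-only rule ignores implausible alpha_v draws
  dk2 <- sample_parameters(fk, n = 10000, seed = 11, rule = "kp_only")
  expect_gte(dk$exclusion_fraction, dk2$exclusion_fraction)
})

test_that("a non-PSD covariance is repaired with a warning", {
  S <- matrix(c(1, 2, 2, 1), 2, 2,
              dimnames = list(c("alpha_v", "k_p"), c("alpha_v", "k_p")))
  f <- synthetic_fit(c(alpha_v = 5, k_p = 0.2), S)
  expect_warning(d <- sample_parameters(f, n = 100, seed = 2),
                 "positive semidefinite")
  expect_true(all(is.finite(d$draws)))
})
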