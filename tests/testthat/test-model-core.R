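test_that("parameter and protocol constructors enforce their invariants", {
  expect_error(bv_params(3, 1.4, 0), "k_p")
  expect_error(bv_params(-1.2, 1.4, 0.1), "alpha_u")
  expect_error(bv_params(3, -1, 0.1), "alpha_v")
  expect_error(bv_protocol(data.frame(t_start = c(0, 20), t_end = c(10, 30),
                                      infusion = 0, hemorrhage = 0)),
               "contiguous")
  expect_error(bv_protocol(data.frame(t_start = 0, t_end = 30,
                                      infusion = -1, hemorrhage = 0)),
               "non-negative")
  expect_error(bv_protocol(data.frame(t_start = 5, t_end = 30,
                                      infusion = 0, hemorrhage = 0)),
               "t = 0")
})

test_that("zero input and symmetric input give identically zero volume change", {
  tt <- seq(0, 180, 5)
  p <- bv_params(2, 0.8, 0.12)
  quiet <- bv_protocol(data.frame(t_start = 0, t_end = 180,
                                  infusion = 0, hemorrhage = 0))
  expect_equal(bv_simulate(p, quiet, tt)$delta_vb, rep(0, length(tt)))
  # alpha_u = alpha_v and U == V: gains and losses cancel exactly
  ps <- bv_params(1.5, 1.5, 0.2)
  sym <- bv_protocol(data.frame(t_start = c(0, 60), t_end = c(60, 180),
                                infusion = c(8, 0), hemorrhage = c(8, 0)))
  expect_equal(bv_simulate(ps, sym, tt)$delta_vb, rep(0, length(tt)),
               tolerance = 1e-12)
})

test_that("single-infusion trajectory approaches its closed-form plateau", {
  p <- bv_params(3, 1.40, 0.14)  # reference cohort subject values
  pr <- bv_protocol(data.frame(t_start = c(0, 30), t_end = c(30, 500),
                               infusion = c(10, 0), hemorrhage = 0))
  tr <- bv_simulate(p, pr, c(0, 30, 100, 300, 500))
  expect_equal(tr$delta_vb[1L], 0)
  # 300 mL infused; long-time retention 300/(1 + alpha_u) = 75 mL
  expect_equal(tr$delta_vb[5L], 75, tolerance = 1e-4)
  expect_equal(tr$delta_vb[5L],
               bv_steady_state(p, 300, 0), tolerance = 1e-4)
})

test_that("steady state matches the analytic limit and the simulated limit", {
  p <- bv_params(3, 1, 0.1)
  expect_equal(bv_steady_state(p, 0, 0), 0)
  expect_equal(bv_steady_state(p, 1000, 800), -150)  # 1000/4 - 800/2
  ps <- bv_params(2, 2, 0.3)
  expect_equal(bv_steady_state(ps, 500, 500), 0)
  # oracle: simulate far past input end (10 / k_p after cessation)
  pr <- bv_protocol(data.frame(t_start = c(0, 40), t_end = c(40, 140),
                               infusion = c(25, 0), hemorrhage = c(20, 0)))
  lim <- bv_simulate(p, pr, 140)$delta_vb
  expect_equal(lim, bv_steady_state(p, 1000, 800), tolerance = 1e-4)
})

test_that("transfer-coefficient map round-trips (structural identifiability)", {
  p <- bv_params(3, 1.40, 0.14)
  tc <- transfer_coeffs(p)
  expect_equal(unname(tc), c(0.14, 0.035, 0.14 / 2.4), tolerance = 1e-12)
  back <- params_from_transfer(tc)
  expect_equal(as.numeric(back), as.numeric(p), tolerance = 1e-12)
  # alpha_u = 0 collapses zero_u onto the pole
  expect_equal(unname(transfer_coeffs(bv_params(0, 1, 0.2))["zero_u"]), 0.2)
  expect_error(params_from_transfer(c(pole = -1, zero_u = 1, zero_v = 1)),
               "pole")
  expect_error(params_from_transfer(c(pole = 0.1, zero_u = 0, zero_v = 0.05)),
               "non-finite")
})

test_that("hematocrit conversion follows the constant-red-cell-volume relation", {
  expect_equal(delta_vb_from_hct(3000, 0.30, 0.30), 0)
  expect_equal(delta_vb_from_hct(3000, 0.30, 0.25), 600)
  expect_equal(delta_vb_from_hct(3000, 0.30, 0.40), -750)
  expect_error(delta_vb_from_hct(3000, 0.30, 1.2), "hematocrit")
  expect_error(delta_vb_from_hct(-1, 0.30, 0.25), "bv0")
})

test_that("closed-form and generic integrator agree on random problems", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_params()
    pr <- random_protocol()
    tt <- seq(0, 180, by = 7.5)
    a <- bv_simulate(p, pr, tt, method = "closed_form")$delta_vb
    b <- bv_simulate(p, pr, tt, method = "ode")$delta_vb
    expect_lt(max(abs(a - b)) / max(max(abs(a)), 1), 1e-6)
  }
})

test_that("simulated trajectories satisfy the second-order model equation", {
  # finite-difference residual of the governing equation shrinks as the
  # grid refines, within a smooth segment
  p <- bv_params(2.5, 0.9, 0.15)
  pr <- bv_protocol(data.frame(t_start = c(0, 20), t_end = c(20, 120),
                               infusion = c(0, 6), hemorrhage = c(30, 0)))
  resid_norm <- function(h) {
    tt <- seq(25, 115, by = h)  # interior of the second segment
    y <- bv_simulate(p, pr, tt)$delta_vb
    n <- length(tt)
    d1 <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
    d2 <- (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2
    u <- 6; v <- 0
    res <- d2 + p$k_p * d1 - (p$k_p / (1 + p$alpha_u) * u -
                              p$k_p / (1 + p$alpha_v) * v)
    max(abs(res))
  }
  r1 <- resid_norm(1); r01 <- resid_norm(0.1)
  expect_lt(r01, r1 / 50)  # ~O(h^2) convergence
  expect_lt(r01, 1e-4)
})

test_that("initial slope equals the net input rate at time zero", {
  p <- bv_params(1, 2, 0.2)
  pr <- bv_protocol(data.frame(t_start = 0, t_end = 60,
                               infusion = 4, hemorrhage = 30))
  tr <- bv_simulate(p, pr, c(0, 0.01), derivative = TRUE)
  expect_equal(tr$d_delta_vb[1L], 4 - 30)
  expect_equal(tr$delta_vb[2L] / 0.01, 4 - 30, tolerance = 1e-3)
})

test_that("simulation rejects invalid times and protocols", {
  p <- bv_params(1, 1, 0.1)
  pr <- bv_protocol(data.frame(t_start = 0, t_end = 60,
                               infusion = 0, hemorrhage = 0))
  expect_error(bv_simulate(p, pr, c(0, 70)), "outside")
  expect_error(bv_simulate(p, pr, c(10, 5)), "increasing")
})
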