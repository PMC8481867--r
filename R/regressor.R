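#' Linear-regression form of the BV kinetics model
#'
#' Rearranged, the model is linear in the transfer coefficients
#' `theta = (k_p/(1+alpha_u), k_p/(1+alpha_v), k_p)`:
#' \deqn{\ddot{\Delta V_B}(t_i) - [\dot U(t_i) - \dot V(t_i)] =
#'   [U(t_i),\; -V(t_i),\; -\dot{\Delta V_B}(t_i)] \,\theta}
#' This builds the response vector and design (regressor) matrix from a
#' subject's measurements restricted to `t_i <= t_c`. Within protocol
#' segments the input-derivative term is zero; samples falling exactly on a
#' protocol breakpoint (where the input derivative is a Dirac impulse) are
#' excluded, as is t = 0.
#'
#' @param subject A [bv_subject()].
#' @param t_c Calibration-window end, min.
#' @param derivatives Optional precomputed output of
#'   [estimate_derivatives()] (reused across windows); computed if `NULL`.
#' @param method Derivative method if `derivatives` is `NULL`.
#' @return A list of class `"bv_regressor"`: `response` (length N), `design`
#'   (N x 3 matrix, columns `zero_u`, `zero_v`, `pole`), `times`, `n`.
#' @export
build_regressor <- function(subject, t_c, derivatives = NULL,
                            method = "spline") {
  stopifnot(inherits(subject, "bv_subject"))
  if (t_c > attr(subject$protocol, "t_final") + 1e-9)
    stop("t_c beyond protocol end")
  if (is.null(derivatives))
    derivatives <- estimate_derivatives(subject, method = method)
  brk <- protocol_breakpoints(subject$protocol)
  on_brk <- vapply(derivatives$time,
                   function(t) any(abs(t - brk) < 1e-9), logical(1))
  keep <- derivatives$time > 1e-9 & derivatives$time <= t_c + 1e-9 & !on_brk
  if (!any(keep)) stop("empty calibration window at t_c = ", t_c)
  tt <- derivatives$time[keep]
  rates <- protocol_rates(subject$protocol, tt)
  design <- cbind(zero_u = rates[, "infusion"],
                  zero_v = -rates[, "hemorrhage"],
                  pole = -derivatives$d1[keep])
  structure(list(response = derivatives$d2[keep], design = design,
                 times = tt, n = length(tt)),
            class = "bv_regressor")
}

#' SVD data-quality profile over candidate calibration windows
#'
#' For each candidate window end `t_c`, takes the singular value
#' decomposition of the regressor matrix and assigns each singular value to
#' the parameter axis its right singular vector is most aligned with
#' (greedily, largest singular value first, each axis used once). An
#' assignment whose maximum absolute right-singular-vector component falls
#' below `mixed_threshold` is flagged `mixed`: the principal direction is
#' not cleanly axis-aligned and the per-axis reading is qualitative.
#' Columns are not normalized, so raw singular values are comparable across
#' `t_c` (they are non-decreasing as rows accumulate).
#'
#' @param subject A [bv_subject()].
#' @param t_c_grid Candidate window ends, min.
#' @param derivatives,method As in [build_regressor()].
#' @param mixed_threshold Alignment below which the `mixed` flag is set.
#' @return A data.frame of class `"bv_svd_profile"` with columns
#'   `subject_id`, `t_c`, `axis` (`"zero_u"`, `"zero_v"`, `"pole"`),
#'   `sigma`, `alignment`, `mixed`.
#' @export
svd_profile <- function(subject, t_c_grid, derivatives = NULL,
                        method = "spline", mixed_threshold = 0.8) {
  stopifnot(length(t_c_grid) >= 1)
  if (is.null(derivatives))
    derivatives <- estimate_derivatives(subject, method = method)
  axes <- c("zero_u", "zero_v", "pole")
  rows <- lapply(t_c_grid, function(tc) {
    reg <- build_regressor(subject, tc, derivatives = derivatives)
    if (reg$n < 3L)
      stop("fewer than 3 usable samples at t_c = ", tc)
    sv <- svd(reg$design)
    assigned <- integer(3)
    free <- rep(TRUE, 3)
    alignment <- numeric(3)
    for (j in 1:3) {  # greedy, in decreasing singular-value order
      comp <- abs(sv$v[, j]); comp[!free] <- -Inf
      ax <- which.max(comp)
      assigned[j] <- ax
      alignment[j] <- abs(sv$v[ax, j])
      free[ax] <- FALSE
    }
    data.frame(subject_id = as.character(subject$subject_id), t_c = tc,
               axis = axes[assigned], sigma = sv$d,
               alignment = alignment, mixed = alignment < mixed_threshold)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bv_svd_profile", "data.frame")
  out
}

#' Select the calibration/validation split from cohort SVD profiles
#'
#' Chooses the smallest candidate `t_c` such that (i) the calibration
#' window `[0, t_c]` contains at least one hemorrhage and one infusion
#' event, (ii) for more than half of the subjects every singular value at
#' `t_c` is at least `f` times its value at the largest grid point, and
#' (iii) the validation window `(t_c, t_final]` still contains a hemorrhage
#' event. If no candidate satisfies (iii), the largest `t_c` satisfying
#' (i)–(ii) is returned with a warning; if none satisfies (i), an error is
#' raised.
#'
#' @param profiles A list of [svd_profile()] results on a common `t_c` grid
#'   (one per subject).
#' @param protocol The shared [bv_protocol()] event structure (any
#'   representative subject's protocol; only segment timing of nonzero rates
#'   is used).
#' @param f Singular-value threshold fraction (0 disables criterion ii).
#' @return A list of class `"bv_window"`: `t_c` and logical rationale flags
#'   `has_hemorrhage`, `has_infusion`, `sv_threshold_met`,
#'   `validation_has_hemorrhage`.
#' @export
select_window <- function(profiles, protocol, f = 0.5) {
  stopifnot(length(profiles) >= 1, inherits(protocol, "bv_protocol"))
  grid <- sort(unique(profiles[[1L]]$t_c))
  t_final <- attr(protocol, "t_final")
  seg <- as.data.frame(protocol)
  overlaps_event <- function(lo, hi, rates) {
    any(rates > 0 & pmin(seg$t_end, hi) - pmax(seg$t_start, lo) > 1e-9)
  }
  crit_i <- vapply(grid, function(tc)
    overlaps_event(0, tc, seg$hemorrhage) && overlaps_event(0, tc, seg$infusion),
    logical(1))
  crit_iii <- vapply(grid, function(tc)
    overlaps_event(tc, t_final, seg$hemorrhage), logical(1))
  t_ref <- max(grid)
  crit_ii <- vapply(grid, function(tc) {
    ok <- vapply(profiles, function(pr) {
      now <- pr[pr$t_c == tc, ]
      ref <- pr[pr$t_c == t_ref, ]
      now <- now[order(now$axis), ]; ref <- ref[order(ref$axis), ]
      all(now$sigma >= f * ref$sigma)
    }, logical(1))
    mean(ok) > 0.5
  }, logical(1))
  if (!any(crit_i))
    stop("no candidate window contains both hemorrhage and infusion events")
  full <- crit_i & crit_ii & crit_iii
  if (any(full)) {
    tc <- grid[which(full)[1L]]
  } else if (any(crit_i & crit_ii)) {
    tc <- grid[max(which(crit_i & crit_ii))]
    warning("no window leaves a hemorrhage event for validation; ",
            "returning largest window meeting criteria (i)-(ii)")
  } else {
    tc <- grid[which(crit_i)[1L]]
    warning("singular-value threshold unmet at every candidate; ",
            "returning smallest window meeting criterion (i)")
  }
  i <- match(tc, grid)
  structure(list(t_c = tc,
                 has_hemorrhage = TRUE, has_infusion = TRUE,
                 sv_threshold_met = crit_ii[i],
                 validation_has_hemorrhage = crit_iii[i]),
            class = "bv_window")
}

#' @export
print.bv_window <- function(x, ...) {
  cat(sprintf("Selected calibration window: [0, %g] min\n", x$t_c))
  cat(sprintf("  singular-value threshold met: %s; validation window has hemorrhage: %s\n",
              x$sv_threshold_met, x$validation_has_hemorrhage))
  invisible(x)
}
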