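#' Piecewise-constant infusion/hemorrhage protocol
#'
#' An input protocol is an ordered set of contiguous time segments, each with
#' a constant fluid infusion rate `U` and hemorrhage rate `V` (mL/min).
#' Segments must tile `[0, t_final]` without gaps or overlaps and all rates
#' must be non-negative, so the cumulative infused and hemorrhaged volumes
#' are piecewise-linear and non-decreasing.
#'
#' @param segments A data.frame with numeric columns `t_start`, `t_end`,
#'   `infusion`, `hemorrhage` (rates in mL/min, times in min).
#' @param t_final End of the protocol in min; defaults to the last `t_end`.
#' @return An object of class `"bv_protocol"`: the segment data.frame with a
#'   `t_final` attribute.
#' @examples
#' # 10 mL/min infusion for 30 min, then nothing, over a 3 h protocol
#' pr <- bv_protocol(data.frame(t_start = c(0, 30), t_end = c(30, 180),
#'                              infusion = c(10, 0), hemorrhage = 0))
#' @export
bv_protocol <- function(segments, t_final = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("t_start", "t_end", "infusion", "hemorrhage") %in%
                  names(segments)))
  seg <- segments[order(segments$t_start),
                  c("t_start", "t_end", "infusion", "hemorrhage")]
  if (is.null(t_final)) t_final <- max(seg$t_end)
  if (nrow(seg) == 0L) stop("protocol needs at least one segment")
  if (any(seg$t_end <= seg$t_start)) stop("segments must have t_end > t_start")
  if (any(seg$infusion < 0) || any(seg$hemorrhage < 0))
    stop("rates must be non-negative")
  if (abs(seg$t_start[1L]) > 1e-9) stop("protocol must start at t = 0")
  if (nrow(seg) > 1L) {
    gaps <- seg$t_start[-1L] - seg$t_end[-nrow(seg)]
    if (any(abs(gaps) > 1e-9))
      stop("segments must be contiguous and non-overlapping")
  }
  if (abs(seg$t_end[nrow(seg)] - t_final) > 1e-9)
    stop("segments must cover [0, t_final]")
  rownames(seg) <- NULL
  structure(seg, t_final = t_final, class = c("bv_protocol", "data.frame"))
}

#' @export
print.bv_protocol <- function(x, ...) {
  cat(sprintf("BV input protocol, %d segment(s) on [0, %g] min\n",
              nrow(x), attr(x, "t_final")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Assemble a protocol from separate infusion and hemorrhage schedules
#'
#' Merges two independent piecewise-constant rate schedules (each a
#' data.frame `t_start`, `t_end`, `rate`, possibly empty, covering any subset
#' of `[0, t_final]`; uncovered time has rate 0) into a single
#' [bv_protocol()].
#'
#' @param infusion,hemorrhage Schedules as described above (mL/min).
#' @param t_final Protocol duration, min.
#' @return A [bv_protocol()].
#' @export
combine_schedules <- function(infusion, hemorrhage, t_final = 180) {
  rate_at <- function(sched, t) {
    if (is.null(sched) || nrow(sched) == 0L) return(0)
    hit <- which(sched$t_start <= t & t < sched$t_end)
    if (length(hit) == 0L) 0 else sum(sched$rate[hit])
  }
  brk <- sort(unique(c(0, t_final,
                       infusion$t_start, infusion$t_end,
                       hemorrhage$t_start, hemorrhage$t_end)))
  brk <- brk[brk >= 0 & brk <= t_final]
  mid <- (brk[-length(brk)] + brk[-1L]) / 2
  seg <- data.frame(
    t_start = brk[-length(brk)], t_end = brk[-1L],
    infusion = vapply(mid, function(t) rate_at(infusion, t), numeric(1)),
    hemorrhage = vapply(mid, function(t) rate_at(hemorrhage, t), numeric(1)))
  # collapse runs of identical rates to keep the segment list minimal
  keep <- c(TRUE, seg$infusion[-1L] != seg$infusion[-nrow(seg)] |
                  seg$hemorrhage[-1L] != seg$hemorrhage[-nrow(seg)])
  idx <- cumsum(keep)
  seg2 <- seg[keep, ]
  seg2$t_end <- as.numeric(tapply(seg$t_end, idx, max))
  bv_protocol(seg2, t_final = t_final)
}

#' Evaluate a protocol's rates, cumulative volumes and breakpoints
#'
#' `protocol_rates()` returns the infusion and hemorrhage rates at given
#' times (right-continuous: a time on a segment boundary takes the later
#' segment's rates; the final time takes the last segment's).
#' `protocol_cumulative()` returns the cumulative infused and hemorrhaged
#' volumes (mL), which are piecewise-linear and non-decreasing.
#' `protocol_breakpoints()` returns the sorted segment boundary times.
#'
#' @param protocol A [bv_protocol()].
#' @param times Numeric vector of times, min.
#' @return For the first two, a matrix with columns `infusion` and
#'   `hemorrhage` (one row per time); for the last, a numeric vector.
#' @export
protocol_rates <- function(protocol, times) {
  seg <- as.data.frame(protocol)
  idx <- findInterval(times, seg$t_start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  cbind(infusion = seg$infusion[idx], hemorrhage = seg$hemorrhage[idx])
}

#' @rdname protocol_rates
#' @export
protocol_cumulative <- function(protocol, times) {
  seg <- as.data.frame(protocol)
  dur <- seg$t_end - seg$t_start
  cu <- c(0, cumsum(seg$infusion * dur))
  cv <- c(0, cumsum(seg$hemorrhage * dur))
  idx <- findInterval(times, seg$t_start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  dt <- pmax(0, pmin(times, seg$t_end[idx]) - seg$t_start[idx])
  cbind(infusion = cu[idx] + seg$infusion[idx] * dt,
        hemorrhage = cv[idx] + seg$hemorrhage[idx] * dt)
}

#' @rdname protocol_rates
#' @export
protocol_breakpoints <- function(protocol) {
  sort(unique(c(protocol$t_start, protocol$t_end)))
}

#' Ovine controlled-hemorrhage schedule
#'
#' The weight-normalized hemorrhage schedule of the emulated animal study:
#' an initial hemorrhage of 25 mL/kg over the first 15 min, then two further
#' bleeds of 5 mL/kg each, starting 50 and 70 min after the start of the
#' initial hemorrhage and lasting 5 min each. Total blood withdrawn is
#' 35 mL/kg over a 180 min study.
#'
#' @param weight Subject weight in kg, `> 0`.
#' @return Hemorrhage schedule data.frame (`t_start`, `t_end`, `rate` in
#'   mL/min) suitable for [combine_schedules()].
#' @examples
#' hemorrhage_schedule(30)  # initial rate 50 mL/min, bleeds at 30 mL/min
#' @export
hemorrhage_schedule <- function(weight) {
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("weight must be a positive scalar (kg)")
  data.frame(t_start = c(0, 50, 70), t_end = c(15, 55, 75),
             rate = c(25 * weight / 15, 5 * weight / 5, 5 * weight / 5))
}

#' Time at which cumulative infusion first equals cumulative hemorrhage
#'
#' Finds the smallest `t > 0` with equal, strictly positive cumulative
#' infused and hemorrhaged volumes. Both cumulatives are piecewise-linear,
#' so crossings are located segment-analytically. When the two cumulatives
#' coincide over an interval of positive length (infusion exactly tracking
#' hemorrhage), the earliest breakpoint at which both are positive and equal
#' is returned.
#'
#' @param protocol A [bv_protocol()].
#' @return Time in min, or `NA_real_` if the cumulatives are never equal and
#'   positive.
#' @export
t_star <- function(protocol) {
  stopifnot(inherits(protocol, "bv_protocol"))
  seg <- as.data.frame(protocol)
  eps <- 1e-9
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t_start[i]; t1 <- seg$t_end[i]
    c0 <- protocol_cumulative(protocol, t0)
    c1 <- protocol_cumulative(protocol, t1)
    d0 <- c0[1] - c0[2]; d1 <- c1[1] - c1[2]
    if (t0 > 0 && abs(d0) <= eps && c0[1] > eps) return(t0)
    if ((d0 < -eps && d1 > -eps) || (d0 > eps && d1 < eps)) {
      tc <- t0 + (0 - d0) * (t1 - t0) / (d1 - d0)
      cc <- protocol_cumulative(protocol, tc)
      if (cc[1] > eps) return(tc)
    }
    if (abs(d1) <= eps && c1[1] > eps && abs(d0) <= eps && t0 == 0)
      return(t1)  # tracking from t = 0: first breakpoint with positive volume
  }
  cf <- protocol_cumulative(protocol, attr(protocol, "t_final"))
  if (abs(cf[1] - cf[2]) <= eps && cf[1] > eps)
    return(attr(protocol, "t_final"))
  NA_real_
}
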