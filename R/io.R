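SUBJECT_CSV_HEADER <- "t_min,infusion_ml_min,hemorrhage_ml_min,delta_vb_ml"

#' Write / read a subject time-series CSV
#'
#' The on-disk format is a plain CSV with the exact header
#' `t_min,infusion_ml_min,hemorrhage_ml_min,delta_vb_ml`: measurement times
#' in min, the protocol's infusion and hemorrhage rates at those times
#' (mL/min), and the measured change in blood volume (mL; empty for
#' prediction-only rows). The rate columns are a sampled view of the
#' protocol; the exact piecewise-constant protocol round-trips through
#' [write_protocol_json()].
#'
#' @param subject A [bv_subject()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subject_csv <- function(subject, path) {
  stopifnot(inherits(subject, "bv_subject"))
  rates <- protocol_rates(subject$protocol, subject$times)
  df <- data.frame(t_min = subject$times,
                   infusion_ml_min = rates[, "infusion"],
                   hemorrhage_ml_min = rates[, "hemorrhage"],
                   delta_vb_ml = subject$measured)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_csv
#' @param path CSV file path to read.
#' @param weight Subject weight in kg (not stored in the CSV).
#' @param protocol Optional exact [bv_protocol()]; if `NULL`, a
#'   sample-and-hold protocol is reconstructed from the rate columns.
#' @param subject_id Identifier; defaults to the file name.
#' @return `read_subject_csv()` returns a [bv_subject()].
#' @export
read_subject_csv <- function(path, weight = NA_real_, protocol = NULL,
                             subject_id = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1L]) != SUBJECT_CSV_HEADER)
    stop("malformed header: expected '", SUBJECT_CSV_HEADER, "'")
  if (length(lines) < 2L || all(trimws(lines[-1L]) == ""))
    stop("empty data section (line 2)")
  df <- utils::read.csv(path)
  if (any(diff(df$t_min) <= 0)) stop("non-monotone time")
  if (is.null(protocol)) {
    tt <- df$t_min
    t_final <- max(tt)
    if (t_final <= min(tt)) stop("degenerate time range")
    protocol <- bv_protocol(data.frame(
      t_start = tt[-length(tt)], t_end = tt[-1L],
      infusion = df$infusion_ml_min[-length(tt)],
      hemorrhage = df$hemorrhage_ml_min[-length(tt)]), t_final = t_final)
  }
  bv_subject(subject_id = subject_id %||% basename(path),
             weight = weight, protocol = protocol, times = df$t_min,
             measured = df$delta_vb_ml)
}

#' Write / read a protocol as JSON
#'
#' Lossless round-trip of the piecewise-constant segment list.
#'
#' @param protocol A [bv_protocol()].
#' @param path File path.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "bv_protocol"))
  seg <- protocol
  class(seg) <- "data.frame"
  attr(seg, "t_final") <- NULL
  jsonlite::write_json(list(t_final = attr(protocol, "t_final"),
                            segments = seg),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bv_protocol(obj$segments, t_final = obj$t_final)
}

#' Write a cohort to a directory
#'
#' One CSV per subject plus a manifest JSON holding ids, weights, true
#' parameters, mismatch tags, noise level and the cohort config.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(s) {
    csv <- sprintf("subject_%s.csv", s$subject_id)
    proto <- sprintf("subject_%s_protocol.json", s$subject_id)
    write_subject_csv(s, file.path(dir, csv))
    write_protocol_json(s$protocol, file.path(dir, proto))
    list(subject_id = s$subject_id, weight = s$weight, csv = csv,
         protocol = proto, mismatch_tag = s$mismatch_tag,
         noise_sd = s$noise_sd,
         true_params = if (!is.null(s$true_params))
           as.list(unclass(s$true_params)))
  })
  cfg <- attr(cohort, "config")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = if (!is.null(cfg)) unclass(cfg),
                            subjects = manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and the per-subject
#'   files.
#' @return A list of [bv_subject()]s, class `"bv_cohort"`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  subjects <- lapply(man$subjects, function(m) {
    proto <- read_protocol_json(file.path(dir, m$protocol))
    s <- read_subject_csv(file.path(dir, m$csv), weight = m$weight,
                          protocol = proto, subject_id = m$subject_id)
    s$mismatch_tag <- m$mismatch_tag
    s$noise_sd <- m$noise_sd %||% NA_real_
    if (!is.null(m$true_params))
      s$true_params <- bv_params(m$true_params$alpha_u,
                                 m$true_params$alpha_v, m$true_params$k_p)
    s
  })
  structure(subjects, class = "bv_cohort")
}
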