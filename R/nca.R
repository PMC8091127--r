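#' Concentration-time profile for non-compartmental analysis
#'
#' One dosing occasion (`first_dose` or `last_dose`) of one subject; times
#' are hours since the start of that infusion.  Concentrations below the
#' assay limit of quantification (0.1 ng/mL) should be handled before
#' construction with [apply_lloq()].
#'
#' @param id subject label.
#' @param occasion `"first_dose"` or `"last_dose"`.
#' @param time sampling times, h, strictly increasing, within `[0, 24]`.
#' @param conc concentrations, ng/mL, `>= 0`.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(id, occasion, time, conc) {
  occasion <- match.arg(occasion, c("first_dose", "last_dose"))
  if (length(time) != length(conc))
    stop_validation("time and conc must have equal length")
  if (any(!is.finite(time)) || any(time < 0) || any(time > 24))
    stop_validation("times must lie in [0, 24] h")
  if (any(diff(time) <= 0))
    stop_validation("times must be strictly increasing")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_validation("negative or non-finite concentration for subject %s", id)
  structure(list(id = as.character(id), occasion = occasion,
                 time = as.numeric(time), conc = as.numeric(conc)),
            class = "concentration_profile")
}

#' Apply the lower limit of quantification
#'
#' Below-LLOQ concentrations are set to 0 at `t = 0` (pre-dose) and dropped
#' elsewhere, matching an assay LLOQ of 0.1 ng/mL.
#'
#' @param time,conc paired sampling times (h) and concentrations (ng/mL).
#' @param lloq limit of quantification, ng/mL.
#' @return list with filtered `time` and `conc`.
#' @export
apply_lloq <- function(time, conc, lloq = 0.1) {
  blq <- conc < lloq
  conc[blq & time == 0] <- 0
  keep <- !blq | time == 0
  list(time = time[keep], conc = conc[keep])
}

#' AUC over the first 8 hours of a dosing interval
#'
#' Linear trapezoidal integral of the concentration-time profile over
#' `[0, 8]` h.  When 8 h falls strictly between two samples the
#' concentration at 8 h is obtained by linear interpolation (within the
#' sampled range, as commercial NCA software does); when the last sample
#' precedes 8 h the integral stops there with a warning -- the tail is never
#' extrapolated.
#'
#' @param profile a [concentration_profile()].
#' @return AUC(0-8h), h*ng/mL.
#' @export
auc_0_8 <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  tt <- profile$time; cc <- profile$conc
  if (!any(tt == 0))
    stop_validation("profile for %s lacks a t = 0 sample", profile$id)
  if (max(tt) > 8 && !any(tt == 8)) {
    c8 <- approx(tt, cc, xout = 8)$y
    keep <- tt < 8
    tt <- c(tt[keep], 8); cc <- c(cc[keep], c8)
  } else {
    keep <- tt <= 8
    tt <- tt[keep]; cc <- cc[keep]
  }
  if (length(tt) < 2L)
    stop_validation("fewer than 2 usable samples in [0, 8] h for %s",
                    profile$id)
  if (max(tt) < 8)
    warning(sprintf("profile %s/%s: last sample at %g h < 8 h; partial AUC, no extrapolation",
                    profile$id, profile$occasion, max(tt)), call. = FALSE)
  pracma::trapz(tt, cc)
}

#' Subject-level exposure summary
#'
#' The model input exposure is the average of the first-dose and last-dose
#' AUC(0-8h) when both occasions are available.  When the last-dose samples
#' are missing (early withdrawal) the first-dose AUC is used alone; the
#' symmetric first-dose-missing fallback is also supported and flagged.
#'
#' @param first,last [concentration_profile()] objects or `NULL`.
#' @return list of class `exposure_summary` with `id`, `auc_first`,
#'   `auc_last`, `auc_used`.
#' @export
subject_exposure <- function(first = NULL, last = NULL) {
  if (is.null(first) && is.null(last))
    stop_validation("at least one of first/last profile is required")
  a1 <- if (!is.null(first)) auc_0_8(first) else NA_real_
  a2 <- if (!is.null(last)) auc_0_8(last) else NA_real_
  id <- if (!is.null(first)) first$id else last$id
  if (is.na(a2))
    message(sprintf("subject %s: last-dose profile missing, first-dose AUC used", id))
  if (is.na(a1))
    message(sprintf("subject %s: first-dose profile missing, last-dose AUC used", id))
  used <- mean(c(a1, a2), na.rm = TRUE)
  structure(list(id = id, auc_first = a1, auc_last = a2, auc_used = used),
            class = "exposure_summary")
}

#' Read concentration profiles from CSV
#'
#' Columns: `ID, OCC (FIRST/LAST), TIME_H, CONC` (case-insensitive).
#' The LLOQ rule of [apply_lloq()] is applied per profile.
#'
#' @param path CSV file path.
#' @param lloq assay limit of quantification, ng/mL.
#' @return list of [concentration_profile()] objects.
#' @export
read_conc_profiles <- function(path, lloq = 0.1) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  need <- c("ID", "OCC", "TIME_H", "CONC")
  for (cn in need)
    if (!cn %in% names(raw))
      stop_validation("required column '%s' missing in %s", cn, path)
  occ_map <- c(FIRST = "first_dose", LAST = "last_dose")
  key <- interaction(raw$ID, raw$OCC, drop = TRUE)
  lapply(split(raw, key), function(d) {
    d <- d[order(d$TIME_H), ]
    occ <- occ_map[[toupper(as.character(d$OCC[1L]))]]
    if (is.null(occ)) stop_validation("unknown occasion '%s'", d$OCC[1L])
    f <- apply_lloq(d$TIME_H, d$CONC, lloq)
    concentration_profile(d$ID[1L], occ, f$time, f$conc)
  })
}

#' Exposure summaries for a list of profiles
#'
#' Groups profiles by subject id and applies [subject_exposure()].
#'
#' @param profiles list of [concentration_profile()] objects.
#' @return data.frame `ID, AUC_FIRST, AUC_LAST, AUC_USED`.
#' @export
exposure_from_profiles <- function(profiles) {
  ids <- vapply(profiles, `[[`, character(1), "id")
  occ <- vapply(profiles, `[[`, character(1), "occasion")
  out <- lapply(unique(ids), function(i) {
    f <- profiles[ids == i & occ == "first_dose"]
    l <- profiles[ids == i & occ == "last_dose"]
    s <- subject_exposure(if (length(f)) f[[1L]] else NULL,
                          if (length(l)) l[[1L]] else NULL)
    data.frame(ID = s$id, AUC_FIRST = s$auc_first, AUC_LAST = s$auc_last,
               AUC_USED = s$auc_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write exposure summaries to CSV
#' @param summaries data.frame from [exposure_from_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_summary <- function(summaries, path) {
  write.csv(summaries, path, row.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}
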