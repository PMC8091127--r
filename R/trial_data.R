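#' Assemble a trial dataset
#'
#' The modelling dataset holds one record per subject (id, arm label,
#' baseline SOFA, steady-state AUC) and one row per subject-day observation.
#' Exposure enters the model only as this per-subject AUC summary; there are
#' no dosing-event records.
#'
#' Validated invariants:
#' * subject ids unique; at least one observation in total;
#' * `arm == "placebo"` if and only if `auc == 0`;
#' * `base > 0`, `auc >= 0`, `day >= 0`;
#' * days unique within subject (observations are stored sorted by day);
#' * when a day-0 observation exists its value equals `base` (the baseline
#'   is the pre-dose score).
#'
#' SOFA values outside `[0, 24]` trigger a warning, not an error: model
#' predictions and simulated scores are continuous and may stray slightly
#' outside the clinical range.
#'
#' @param subjects data.frame with columns `id`, `arm`, `base`, `auc`.
#' @param observations data.frame with columns `id`, `day`, `dv`.
#' @return An object of class `trial_dataset` with elements `subjects` and
#'   `observations` (sorted by id, day).
#' @export
trial_dataset <- function(subjects, observations) {
  need_s <- c("id", "arm", "base", "auc")
  need_o <- c("id", "day", "dv")
  if (!all(need_s %in% names(subjects)))
    stop_validation("subjects must have columns %s", paste(need_s, collapse = ", "))
  if (!all(need_o %in% names(observations)))
    stop_validation("observations must have columns %s", paste(need_o, collapse = ", "))
  subjects <- as.data.frame(subjects)[need_s]
  observations <- as.data.frame(observations)[need_o]
  subjects$id <- as.character(subjects$id)
  observations$id <- as.character(observations$id)

  if (anyDuplicated(subjects$id))
    stop_validation("duplicate subject id(s): %s",
                    paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  if (nrow(observations) < 1L)
    stop_validation("dataset must contain at least one observation")
  orphan <- setdiff(observations$id, subjects$id)
  if (length(orphan))
    stop_validation("observations reference unknown subject id(s): %s",
                    paste(orphan, collapse = ", "))
  for (col in c("base", "auc")) {
    if (any(!is.finite(subjects[[col]])))
      stop_validation("non-finite values in subjects$%s", col)
  }
  if (any(subjects$base <= 0)) stop_validation("base must be > 0 for every subject")
  if (any(subjects$auc < 0)) stop_validation("auc must be >= 0 for every subject")
  plc <- subjects$arm == "placebo"
  bad <- plc != (subjects$auc == 0)
  if (any(bad))
    stop_validation("arm = placebo must coincide with auc = 0 (violated for %s)",
                    paste(subjects$id[bad], collapse = ", "))
  if (any(!is.finite(observations$day)) || any(observations$day < 0))
    stop_validation("day must be finite and >= 0")
  if (any(!is.finite(observations$dv)))
    stop_validation("dv must be finite")

  observations <- observations[order(match(observations$id, subjects$id),
                                     observations$day), , drop = FALSE]
  rownames(observations) <- NULL
  dup <- duplicated(observations[c("id", "day")])
  if (any(dup))
    stop_validation("duplicate (id, day) observation(s): %s",
                    paste(sprintf("(%s, %g)", observations$id[dup],
                                  observations$day[dup]), collapse = ", "))
  d0 <- observations[observations$day == 0, , drop = FALSE]
  if (nrow(d0)) {
    b <- subjects$base[match(d0$id, subjects$id)]
    off <- abs(d0$dv - b) > 1e-8
    if (any(off))
      stop_validation("day-0 observation differs from base for subject(s): %s",
                      paste(d0$id[off], collapse = ", "))
  }
  structure(list(subjects = subjects, observations = observations),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Trial dataset: %d subjects (%d placebo), %d observations\n",
              nrow(x$subjects), sum(x$subjects$arm == "placebo"),
              nrow(x$observations)))
  tab <- table(x$subjects$arm)
  cat("  arms:", paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects / observations in a trial dataset
#' @param dataset a [trial_dataset()].
#' @return integer count.
#' @export
n_subjects <- function(dataset) nrow(dataset$subjects)

#' @rdname n_subjects
#' @export
n_observations <- function(dataset) nrow(dataset$observations)

#' Extract one subject as a record usable by [subject_nll()]
#' @param dataset a [trial_dataset()].
#' @param id subject id.
#' @return list with `id`, `arm`, `base`, `auc`, `days`, `dv`.
#' @export
get_subject <- function(dataset, id) {
  i <- match(as.character(id), dataset$subjects$id)
  if (is.na(i)) stop_validation("unknown subject id '%s'", id)
  o <- dataset$observations[dataset$observations$id == dataset$subjects$id[i], ]
  list(id = dataset$subjects$id[i], arm = dataset$subjects$arm[i],
       base = dataset$subjects$base[i], auc = dataset$subjects$auc[i],
       days = o$day, dv = o$dv)
}

#' Read a NONMEM-style modelling dataset from CSV
#'
#' Expected columns (case-insensitive, remappable through `schema`):
#' `ID, ARM, DAY, DV, BASE, AUC`.  Missing values are encoded as `"."`
#' (blank cells are also accepted); rows with a missing `DV` are dropped
#' and counted in a message.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical names to
#'   file column names, e.g. `c(DV = "SOFA")`.
#' @return A validated [trial_dataset()].
#' @export
read_dataset <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  strip.white = TRUE)
  canon <- c("ID", "ARM", "DAY", "DV", "BASE", "AUC")
  have <- toupper(names(raw))
  wanted <- setNames(canon, canon)
  if (!is.null(schema)) wanted[names(schema)] <- toupper(schema)
  for (cn in canon) {
    j <- match(wanted[[cn]], have)
    if (is.na(j)) stop_validation("required column '%s' missing in %s", cn, path)
    names(raw)[j] <- cn
  }
  num <- function(col) {
    v <- raw[[col]]
    v[v %in% c(".", "")] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop_validation("non-numeric value '%s' in column %s, row %d",
                      v[bad[1L]], col, bad[1L] + 1L)  # +1 for the header row
    out
  }
  day <- num("DAY"); dv <- num("DV"); base <- num("BASE"); auc <- num("AUC")
  miss <- is.na(dv)
  if (any(miss))
    message(sprintf("read_dataset: dropped %d row(s) with missing DV", sum(miss)))
  keep <- !miss
  obs <- data.frame(id = raw$ID[keep], day = day[keep], dv = dv[keep],
                    stringsAsFactors = FALSE)
  dup <- duplicated(obs[c("id", "day")])
  if (any(dup))
    stop_validation("duplicate (ID, DAY) rows in %s: %s", path,
                    paste(sprintf("(%s, %g)", obs$id[dup], obs$day[dup]),
                          collapse = ", "))
  ids <- unique(raw$ID)
  subj <- data.frame(
    id = ids,
    arm = raw$ARM[match(ids, raw$ID)],
    base = base[match(ids, raw$ID)],
    auc = auc[match(ids, raw$ID)],
    stringsAsFactors = FALSE)
  ds <- trial_dataset(subj, obs)
  out_range <- obs$dv < 0 | obs$dv > 24
  if (any(out_range))
    warning(sprintf("%d SOFA value(s) outside [0, 24] (continuous model scale)",
                    sum(out_range)), call. = FALSE)
  message(sprintf("read_dataset: %d subjects, %d observations loaded",
                  n_subjects(ds), n_observations(ds)))
  ds
}

#' Write a modelling dataset to CSV
#'
#' Deterministic column order `ID, ARM, DAY, DV, BASE, AUC`; missing values
#' are written as `"."`.  An empty subject list yields a header-only file.
#'
#' @param dataset a [trial_dataset()] (validation is re-run).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  s <- dataset$subjects; o <- dataset$observations
  i <- match(o$id, s$id)
  fmt <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 15, format = "g"))
  out <- data.frame(ID = o$id, ARM = s$arm[i],
                    DAY = fmt(o$day), DV = fmt(o$dv),
                    BASE = fmt(s$base[i]), AUC = fmt(s$auc[i]),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_validation("cannot write to %s", path)
  invisible(path)
}

#' Flatten a dataset into the vector form used by the likelihood
#'
#' Internal: returns per-observation vectors plus a subject index, with
#' subjects ordered as in `dataset$subjects`.  Day-0 rows reproduce the
#' baseline exactly by construction, so they are excluded from the
#' likelihood by default (including them would understate sigma).
#'
#' @noRd
flatten_dataset <- function(dataset, include_day0 = FALSE) {
  s <- dataset$subjects
  o <- dataset$observations
  if (!include_day0) o <- o[o$day > 0, , drop = FALSE]
  idx <- match(o$id, s$id)
  ord <- order(idx, o$day)
  o <- o[ord, , drop = FALSE]
  idx <- idx[ord]
  nobs <- tabulate(idx, nbins = nrow(s))
  list(t = o$day, y = o$dv, idx = idx,
       base = s$base[idx], auc = s$auc[idx],
       n_sub = nrow(s), ids = s$id, sub_base = s$base, sub_auc = s$auc,
       sub_arm = s$arm, nobs = nobs, obs_id = o$id)
}
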