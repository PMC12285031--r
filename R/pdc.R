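#' Study window on the integer day grid
#'
#' A half-open window `[start_day, end_day)` of whole days, expressed as
#' offsets from a patient's index date (first statin prescription = day 0).
#'
#' @param start_day Integer, inclusive start of the window.
#' @param end_day Integer, exclusive end of the window; must exceed
#'   `start_day`.
#' @return An object of class `study_window`: a length-2 integer vector.
#' @examples
#' study_window(0, 365)
#' @export
study_window <- function(start_day, end_day) {
  start_day <- as.integer(start_day)
  end_day <- as.integer(end_day)
  if (length(start_day) != 1L || length(end_day) != 1L ||
      is.na(start_day) || is.na(end_day)) {
    stop("window bounds must be single finite integers")
  }
  if (end_day <= start_day) {
    stop("end_day must be strictly greater than start_day")
  }
  structure(c(start = start_day, end = end_day), class = "study_window")
}

#' Proportion of days covered over a window
#'
#' PDC is the number of tablets prescribed within the study window divided by
#' the window length in days, times 100. Values above 100% are possible
#' (e.g. two-tablet regimens or early refills) and are deliberately not
#' capped here; capping/exclusion is a cohort-level decision
#' (see [apply_cohort_exclusions()]).
#'
#' @param records Data frame of dispensing events for a single patient with
#'   columns `date_day` (integer day offset) and `n_tablets`.
#' @param window A [study_window()] or a length-2 numeric `c(start, end)`;
#'   the window is half-open, `start <= date_day < end`.
#' @return PDC as a percentage (numeric scalar, `>= 0`). An empty window of
#'   records yields 0.
#' @examples
#' rx <- data.frame(date_day = c(0, 28, 56), n_tablets = 28)
#' compute_pdc(rx, study_window(0, 84)) # 100
#' @export
compute_pdc <- function(records, window) {
  window <- as_window(window)
  len <- window[["end"]] - window[["start"]]
  if (is.null(records) || nrow(records) == 0L) {
    return(0)
  }
  stopifnot(all(c("date_day", "n_tablets") %in% names(records)))
  if (any(!is.finite(records$date_day))) stop("prescription dates must be finite")
  if (any(records$n_tablets < 1)) stop("n_tablets must be >= 1")
  keep <- records$date_day >= window[["start"]] & records$date_day < window[["end"]]
  100 * sum(records$n_tablets[keep]) / len
}

as_window <- function(window) {
  if (inherits(window, "study_window")) return(window)
  if (is.numeric(window) && length(window) == 2L) {
    return(study_window(window[1L], window[2L]))
  }
  stop("window must be a study_window or c(start, end)")
}

#' First-year PDC with trailing-prescription window rules
#'
#' Computes PDC over the first year of treatment (PDC1). The nominal window
#' is the 365 days from the first prescription, with two adjustments for the
#' prescription that straddles the year boundary:
#' \itemize{
#'   \item if a later prescription exists on day `d >= 365`, the window is
#'     extended to `[0, d)` so that the straddling supply contributes both
#'     its tablets and its days;
#'   \item if the patient's last-ever prescription falls inside year 1, its
#'     coverage period is unobserved: that script's tablets are dropped and
#'     the window ends at its issue date (`trailing_script_dropped` flag).
#' }
#' A patient whose only prescription has no successor has no observable
#' coverage period and gets `NA` (flag `pdc1_undefined`).
#'
#' @param records All dispensing events for one patient, dated relative to
#'   the first prescription (which need not be exactly day 0; dates are
#'   re-anchored to the earliest record).
#' @param year_days Length of the nominal first-year window (default 365).
#' @return A list with `pdc1` (percent or `NA`), `window` (the realized
#'   `study_window`), and `flags` (character vector, possibly empty, among
#'   `"trailing_script_dropped"`, `"pdc_gt_200"`, `"pdc1_undefined"`).
#' @export
compute_pdc_year1 <- function(records, year_days = 365L) {
  stopifnot(nrow(records) >= 1L)
  d <- records$date_day - min(records$date_day)
  tab <- records$n_tablets
  flags <- character(0)
  after <- d[d >= year_days]
  if (length(after) > 0L) {
    wend <- min(after)
  } else {
    last_day <- max(d)
    if (last_day <= 0L) {
      # only script(s) on the index day and nothing afterwards
      return(list(pdc1 = NA_real_, window = NULL, flags = "pdc1_undefined"))
    }
    wend <- last_day
    flags <- c(flags, "trailing_script_dropped")
  }
  window <- study_window(0L, wend)
  pdc1 <- 100 * sum(tab[d < wend]) / (wend - 0)
  if (is.finite(pdc1) && pdc1 > 200) flags <- c(flags, "pdc_gt_200")
  list(pdc1 = pdc1, window = window, flags = flags)
}

#' Three-level adherence category
#'
#' Partitions first-year PDC into the exposure categories `<50`, `50-95`
#' (closed at both ends) and `>95`.
#'
#' @param pdc Numeric vector of PDC percentages, all `>= 0`.
#' @return Factor with levels `"<50"`, `"50-95"`, `">95"`.
#' @examples
#' categorize_pdc(c(49.9, 50, 95, 95.1))
#' @export
categorize_pdc <- function(pdc) {
  if (any(is.finite(pdc) & pdc < 0)) stop("PDC cannot be negative")
  out <- ifelse(pdc < 50, "<50", ifelse(pdc <= 95, "50-95", ">95"))
  factor(out, levels = c("<50", "50-95", ">95"))
}

#' Interval PDC between successive follow-up visits
#'
#' For visits `k = 1..K`, PDC_k is the PDC over the half-open window from the
#' previous time point to visit `k`, where time point 0 is the later of the
#' baseline measurement day and the first prescription day (so coverage is
#' never assessed before treatment could have started). A prescription issued
#' exactly on a visit day belongs to the following window.
#'
#' @param records Dispensing events for one patient (`date_day`,
#'   `n_tablets`).
#' @param visit_days Strictly increasing integer days of the follow-up
#'   visits, all after `baseline_day`.
#' @param baseline_day Day of the baseline LDL measurement (default 0).
#' @return Data frame with columns `k`, `start_day`, `end_day`, `pdc`.
#' @export
compute_interval_pdc <- function(records, visit_days, baseline_day = 0L) {
  if (length(visit_days) < 1L) stop("at least one visit day required")
  if (any(diff(visit_days) <= 0)) stop("visit days must be strictly increasing")
  if (any(visit_days <= baseline_day)) stop("visit days must follow the baseline day")
  first_rx <- if (nrow(records) > 0L) min(records$date_day) else baseline_day
  start0 <- max(baseline_day, first_rx)
  starts <- c(start0, visit_days[-length(visit_days)])
  ends <- visit_days
  pdc <- vapply(seq_along(ends), function(k) {
    compute_pdc(records, study_window(starts[k], ends[k]))
  }, numeric(1))
  data.frame(k = seq_along(ends), start_day = starts, end_day = ends, pdc = pdc)
}

#' Adherence series for a whole cohort
#'
#' Convenience wrapper applying [compute_pdc_year1()] and, when visit days
#' are supplied, [compute_interval_pdc()] per patient.
#'
#' @param prescriptions Data frame with `patient_id`, `date_day`,
#'   `n_tablets`.
#' @param visits Optional data frame with `patient_id` and `visit_day_1..K`
#'   columns (and optionally `baseline_day`).
#' @return Data frame with one row per patient: `patient_id`, `pdc1`,
#'   `pdc1_category`, `flags` (comma-joined), and `pdc_k` columns when
#'   `visits` is given. Patients in `visits` without prescriptions get
#'   interval PDCs of 0.
#' @export
compute_adherence <- function(prescriptions, visits = NULL) {
  ids <- unique(prescriptions$patient_id)
  by_id <- split(prescriptions, prescriptions$patient_id)
  rows <- lapply(ids, function(id) {
    y1 <- compute_pdc_year1(by_id[[as.character(id)]])
    data.frame(patient_id = id, pdc1 = y1$pdc1,
               flags = paste(y1$flags, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$pdc1_category <- categorize_pdc(ifelse(is.na(out$pdc1), 0, out$pdc1))
  out$pdc1_category[is.na(out$pdc1)] <- NA
  out <- out[, c("patient_id", "pdc1", "pdc1_category", "flags")]
  if (!is.null(visits)) {
    kcols <- grep("^visit_day_", names(visits), value = TRUE)
    K <- length(kcols)
    bday <- if ("baseline_day" %in% names(visits)) visits$baseline_day else rep(0L, nrow(visits))
    pm <- matrix(NA_real_, nrow(visits), K,
                 dimnames = list(NULL, paste0("pdc_", seq_len(K))))
    for (i in seq_len(nrow(visits))) {
      id <- as.character(visits$patient_id[i])
      rx <- by_id[[id]]
      if (is.null(rx)) rx <- prescriptions[0, ]
      vd <- as.numeric(visits[i, kcols])
      ip <- compute_interval_pdc(rx, vd, baseline_day = min(bday[i], 0L))
      pm[i, ] <- ip$pdc
    }
    out <- merge(visits[, "patient_id", drop = FALSE],
                 out, by = "patient_id", all.x = TRUE)
    out <- cbind(out, pm[match(out$patient_id, visits$patient_id), , drop = FALSE])
  }
  out
}

#' Cohort-level adherence exclusions
#'
#' Removes patients who died within 3 months (90 days) of starting statins,
#' and patients with first-year PDC above 200% (implausible dispensing,
#' likely data errors or irregular supply).
#'
#' @param series Adherence table with `patient_id` and `pdc1` (e.g. from
#'   [compute_adherence()]).
#' @param events Clinical events table with `patient_id`, `date_day`,
#'   `event_type`; deaths are rows with `event_type == "death"`.
#' @param death_days Exclusion horizon for early deaths (default 90).
#' @param pdc_cap Upper PDC1 bound (default 200).
#' @return List with `series` (filtered table, exclusion flags appended to
#'   `flags`) and `report`, a named list of per-reason patient counts
#'   (`died_lt_3mo`, `pdc_gt_200`).
#' @export
apply_cohort_exclusions <- function(series, events, death_days = 90L, pdc_cap = 200) {
  died <- character(0)
  if (!is.null(events) && nrow(events) > 0L) {
    dth <- events[events$event_type == "death", , drop = FALSE]
    if (nrow(dth) > 0L) {
      first_death <- tapply(dth$date_day, dth$patient_id, min)
      died <- names(first_death)[first_death < death_days]
    }
  }
  is_dead <- as.character(series$patient_id) %in% died
  is_high <- !is.na(series$pdc1) & series$pdc1 > pdc_cap
  report <- list(died_lt_3mo = sum(is_dead), pdc_gt_200 = sum(is_high))
  keep <- !(is_dead | is_high)
  list(series = series[keep, , drop = FALSE], report = report)
}
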