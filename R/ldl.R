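#' Baseline LDL-c selection
#'
#' Chooses the pre-treatment LDL-c value: among measures taken within
#' `window_days` days before (and including the day of) the first
#' prescription, the one closest to treatment start. Duplicate measures on
#' the qualifying day are averaged and flagged.
#'
#' @param measures Data frame for one patient with `date_day` (relative to
#'   first prescription) and `ldl_mmol_l`.
#' @param window_days Look-back window (default 180).
#' @param allow_same_day Accept a measure dated the first-prescription day
#'   itself as pre-treatment (default TRUE).
#' @return List with `baseline` (one-row data frame or `NULL`) and `flags`
#'   (possibly containing `"baseline_tie_averaged"`).
#' @export
select_baseline <- function(measures, window_days = 180L, allow_same_day = TRUE) {
  hi <- if (allow_same_day) 0L else -1L
  ok <- measures$date_day >= -window_days & measures$date_day <= hi
  cand <- measures[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(baseline = NULL, flags = character(0)))
  best_day <- max(cand$date_day)
  sel <- cand[cand$date_day == best_day, , drop = FALSE]
  flags <- character(0)
  if (nrow(sel) > 1L) {
    sel <- sel[1L, , drop = FALSE]
    sel$ldl_mmol_l <- mean(cand$ldl_mmol_l[cand$date_day == best_day])
    flags <- "baseline_tie_averaged"
  }
  list(baseline = sel, flags = flags)
}

#' Follow-up LDL-c selection
#'
#' In `"year1"` mode, the earliest post-treatment measure within 12 months
#' (365 days). In `"longitudinal"` mode, the first three post-treatment
#' measures within a 10-year window (3652 days); patients with fewer than
#' three are excluded (empty result).
#'
#' @param measures Data frame for one patient (`date_day`, `ldl_mmol_l`).
#' @param mode `"year1"` or `"longitudinal"`.
#' @param year1_days,horizon_days,n_required Window lengths in days and the
#'   number of longitudinal measures required.
#' @return Data frame of selected follow-ups (possibly 0 rows), ordered by
#'   date.
#' @export
select_followups <- function(measures, mode = c("year1", "longitudinal"),
                             year1_days = 365L, horizon_days = 3652L,
                             n_required = 3L) {
  mode <- match.arg(mode)
  post <- measures[measures$date_day > 0, , drop = FALSE]
  post <- post[order(post$date_day), , drop = FALSE]
  if (mode == "year1") {
    post <- post[post$date_day <= year1_days, , drop = FALSE]
    return(post[seq_len(min(1L, nrow(post))), , drop = FALSE])
  }
  post <- post[post$date_day <= horizon_days, , drop = FALSE]
  if (nrow(post) < n_required) return(post[0, , drop = FALSE])
  post[seq_len(n_required), , drop = FALSE]
}

#' Measurement and patient validity filters
#'
#' Applies the two validity rules before any baseline/follow-up selection:
#' individual LDL-c measures outside the plausible (1, 8) mmol/L open
#' interval are removed (values exactly 1 or 8 are retained), and patients
#' whose first prescription falls within `discharge_days` days after a
#' cardiovascular hospital discharge are removed entirely (their early
#' prescriptions may be hospital-issued and unrecorded).
#'
#' @param ldl LDL measures table (`patient_id`, `date_day`, `ldl_mmol_l`).
#' @param events Clinical events table (`patient_id`, `date_day`,
#'   `event_type`); discharges are `event_type == "hospital_discharge_cvd"`
#'   with `date_day` relative to the first prescription (negative = before).
#' @param ldl_range Plausible LDL-c bounds, exclusive (default `c(1, 8)`).
#' @param discharge_days Post-discharge horizon in days (default 90).
#' @param patient_level If TRUE (default) the discharge rule removes the
#'   patient; if FALSE only measures before the first prescription + 0 days
#'   are kept unaffected and the rule is skipped (measurement-level variant
#'   retains the patient).
#' @return List with `ldl` (filtered measures), `dropped_patients`
#'   (character ids removed by the discharge rule) and `report` (counts:
#'   `ldl_low`, `ldl_high`, `post_discharge`).
#' @export
apply_ldl_filters <- function(ldl, events = NULL, ldl_range = c(1, 8),
                              discharge_days = 90L, patient_level = TRUE) {
  low <- ldl$ldl_mmol_l < ldl_range[1]
  high <- ldl$ldl_mmol_l > ldl_range[2]
  report <- list(ldl_low = sum(low), ldl_high = sum(high), post_discharge = 0L)
  ldl <- ldl[!(low | high), , drop = FALSE]
  dropped <- character(0)
  if (!is.null(events) && nrow(events) > 0L && patient_level) {
    dis <- events[events$event_type == "hospital_discharge_cvd", , drop = FALSE]
    # first prescription = day 0 by convention; discharge within the 90 days
    # before (or on) that day triggers removal
    hit <- dis$date_day >= -discharge_days & dis$date_day <= 0
    dropped <- unique(as.character(dis$patient_id[hit]))
    report$post_discharge <- length(dropped)
    ldl <- ldl[!(as.character(ldl$patient_id) %in% dropped), , drop = FALSE]
  }
  list(ldl = ldl, dropped_patients = dropped, report = report)
}

#' LDL change ratio and per-visit reduction
#'
#' Fills in the outcome scales: the change ratio `Y = LDL1 / LDL0` (first
#' follow-up over baseline; values below 1 indicate reduction) and the
#' per-visit fractional reduction `LR_k = (LDL_k - LDL_0) / LDL_0`
#' (negative = reduction). The two are linked by `Y = 1 + LR_1`.
#'
#' @param baseline One-row data frame with `ldl_mmol_l` (the baseline).
#' @param followups Data frame of follow-up measures, ordered by date.
#' @return List with `y_ratio` and `lr` (data frame `k`, `date_day`, `lr`).
#' @export
compute_y_and_lr <- function(baseline, followups) {
  stopifnot(nrow(baseline) == 1L, nrow(followups) >= 1L)
  ldl0 <- baseline$ldl_mmol_l
  if (ldl0 <= 0) stop("baseline LDL-c must be positive")
  lr <- (followups$ldl_mmol_l - ldl0) / ldl0
  list(y_ratio = followups$ldl_mmol_l[1L] / ldl0,
       lr = data.frame(k = seq_len(nrow(followups)),
                       date_day = followups$date_day, lr = lr))
}

#' Build per-patient LDL-c trajectories
#'
#' Runs the full selection pipeline: measure/patient validity filters, then
#' baseline selection, then follow-up selection in the requested mode, then
#' outcome computation. Patients lacking a baseline or the required
#' follow-ups are dropped.
#'
#' @param ldl LDL measures table for the cohort.
#' @param events Clinical events table (may be `NULL` or empty).
#' @param mode `"year1"` or `"longitudinal"` (see [select_followups()]).
#' @param ... Passed to [apply_ldl_filters()] and [select_followups()].
#' @return List with `trajectories` (one row per retained patient:
#'   `patient_id`, `baseline_day`, `ldl0`, `visit_day_k`, `ldl_k`, `lr_k`,
#'   `y_ratio`, `flags`) and `report` (filter counts plus `no_baseline`,
#'   `insufficient_followup`).
#' @export
build_trajectories <- function(ldl, events = NULL,
                               mode = c("year1", "longitudinal"), ...) {
  mode <- match.arg(mode)
  dots <- list(...)
  filt_args <- dots[names(dots) %in% c("ldl_range", "discharge_days", "patient_level")]
  sel_args <- dots[names(dots) %in% c("year1_days", "horizon_days", "n_required")]
  filt <- do.call(apply_ldl_filters, c(list(ldl = ldl, events = events), filt_args))
  report <- filt$report
  report$no_baseline <- 0L
  report$insufficient_followup <- 0L
  by_id <- split(filt$ldl, as.character(filt$ldl$patient_id))
  K <- if (mode == "year1") 1L else {
    if (!is.null(sel_args$n_required)) sel_args$n_required else 3L
  }
  rows <- vector("list", length(by_id))
  for (i in seq_along(by_id)) {
    m <- by_id[[i]]
    bl <- select_baseline(m)
    if (is.null(bl$baseline)) {
      report$no_baseline <- report$no_baseline + 1L
      next
    }
    fu <- do.call(select_followups, c(list(measures = m, mode = mode), sel_args))
    if (nrow(fu) < K) {
      report$insufficient_followup <- report$insufficient_followup + 1L
      next
    }
    out <- compute_y_and_lr(bl$baseline, fu)
    row <- data.frame(patient_id = m$patient_id[1L],
                      baseline_day = bl$baseline$date_day,
                      ldl0 = bl$baseline$ldl_mmol_l,
                      y_ratio = out$y_ratio,
                      flags = paste(bl$flags, collapse = ","))
    for (k in seq_len(K)) {
      row[[paste0("visit_day_", k)]] <- fu$date_day[k]
      row[[paste0("ldl_", k)]] <- fu$ldl_mmol_l[k]
      row[[paste0("lr_", k)]] <- out$lr$lr[k]
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  traj <- if (length(rows)) do.call(rbind, rows) else NULL
  list(trajectories = traj, report = report)
}
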