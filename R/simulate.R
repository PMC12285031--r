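#' Simulation configuration
#'
#' All data-generating parameters of the synthetic statin cohort. The
#' defaults emulate a UK primary-care statin population: age at first
#' prescription ~ Normal(61, 7.3) truncated to [40, 79]; 42.3% female;
#' baseline LDL-c ~ Normal(3.8, 1.05) mmol/L truncated to [1, 8]; six
#' education categories and six assessment centres; inter-visit gaps
#' Uniform(180, 550) days so the mean time to the third follow-up measure is
#' about three years.
#'
#' The longitudinal structure is a linear-Gaussian structural equation
#' system over `K` post-baseline visits with latent interval adherence
#' `PDC_k` (percent, clipped to [0, 150]) and fractional LDL reduction
#' `LR_k`:
#' \deqn{PDC_k = \mu + \gamma_P' X + \phi\, LR_{k-1} + \epsilon_k}
#' \deqn{LR_k  = \beta_k PDC_k + \rho\, LR_{k-1} + \gamma_L' X + \eta_k}
#' with `LR_0 = 0` and `LDL_k = LDL_0 (1 + LR_k)`. The feedback coefficient
#' `phi` (`feedback_coef`, percent per LR unit) makes past response drive
#' future adherence, creating genuine time-varying confounding; the carry
#' coefficient `rho` (`carry_coef`) propagates response. The implied
#' marginal-structural coefficients are `b_{k,j} = beta_j * rho^(k-j)`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer RNG seed used by [generate_cohort()].
#' @param K Number of post-baseline visits (default 3).
#' @param beta_direct Length-`K` vector: direct effect of `PDC_k` on `LR_k`
#'   per PDC percentage point. Default sums to -0.0035 (35 LR percentage
#'   points at full adherence through the direct pathway).
#' @param carry_coef Effect of `LR_{k-1}` on `LR_k`.
#' @param feedback_coef Effect of `LR_{k-1}` on `PDC_k`, percent per LR
#'   unit; negative values mean a larger reduction raises later adherence.
#' @param conf_coefs List with elements `pdc` and `lr`: named vectors of
#'   fixed-confounder effects (`age` per year, `female`, `ldl0` per mmol/L,
#'   `education` per category step) entering both equations. Covariates are
#'   centred at their population means before multiplying.
#' @param pdc_mean Latent adherence intercept (percent).
#' @param pdc_noise_sd,lr_noise_sd Equation noise SDs (percent; LR units).
#' @param visit_gap_law List describing the inter-visit gap distribution;
#'   default `list(dist = "uniform", min = 180, max = 550)` days.
#' @param baseline_ldl_mean,baseline_ldl_sd Baseline LDL-c law (mmol/L).
#' @param tablets_per_script Tablets per dispensing event (default 28).
#' @param jitter_sd SD of the Gaussian day-jitter added to refill gaps when
#'   rendering prescriptions (default 1 day).
#' @return Object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [generate_msm_data()]
#' @export
sim_config <- function(n_patients = 1000L,
                       seed = 1L,
                       K = 3L,
                       beta_direct = c(-0.0015, -0.0008, -0.0012),
                       carry_coef = 0.25,
                       feedback_coef = -25,
                       conf_coefs = list(
                         pdc = c(age = 0.34, female = 0.64, ldl0 = 0.55,
                                 education = 0.5),
                         lr = c(age = 0.0015, female = 0.01, ldl0 = -0.02,
                                education = -0.002)),
                       pdc_mean = 80,
                       pdc_noise_sd = 18,
                       lr_noise_sd = 0.12,
                       visit_gap_law = list(dist = "uniform", min = 180, max = 550),
                       baseline_ldl_mean = 3.8,
                       baseline_ldl_sd = 1.05,
                       tablets_per_script = 28L,
                       jitter_sd = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (K < 1) stop("K must be >= 1")
  if (length(beta_direct) != K) {
    if (length(beta_direct) > K) beta_direct <- beta_direct[seq_len(K)]
    else beta_direct <- rep_len(beta_direct, K)
  }
  sds <- c(pdc_noise_sd, lr_noise_sd, baseline_ldl_sd, jitter_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (tablets_per_script < 1) stop("tablets_per_script must be >= 1")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    K = as.integer(K), beta_direct = beta_direct, carry_coef = carry_coef,
    feedback_coef = feedback_coef, conf_coefs = conf_coefs,
    pdc_mean = pdc_mean, pdc_noise_sd = pdc_noise_sd,
    lr_noise_sd = lr_noise_sd, visit_gap_law = visit_gap_law,
    baseline_ldl_mean = baseline_ldl_mean, baseline_ldl_sd = baseline_ldl_sd,
    tablets_per_script = as.integer(tablets_per_script),
    jitter_sd = jitter_sd), class = "sim_config")
}

# population means used to centre confounders in the structural equations
.conf_centers <- function() {
  edu_p <- c(0.287, 0.029, 0.124, 0.173, 0.146, 0.241)
  c(age = 61, female = 0.423, ldl0 = 3.8,
    education = sum(seq_len(6) * edu_p))
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

draw_gaps <- function(n, law) {
  if (identical(law$dist, "uniform")) {
    round(stats::runif(n, law$min, law$max))
  } else if (identical(law$dist, "gamma")) {
    round(stats::rgamma(n, shape = law$shape, rate = law$rate))
  } else {
    stop("unknown visit gap law: ", law$dist)
  }
}

# Core structural simulation: fixed confounders, latent interval PDCs,
# LR trajectory, visit times. Returns a per-patient data frame.
simulate_structural <- function(config) {
  n <- config$n_patients
  K <- config$K
  ctr <- .conf_centers()
  edu_p <- c(0.287, 0.029, 0.124, 0.173, 0.146, 0.241)
  age <- rnorm_trunc(n, 61, 7.3, 40, 79)
  female <- stats::rbinom(n, 1L, 0.423)
  ldl0 <- rnorm_trunc(n, config$baseline_ldl_mean, config$baseline_ldl_sd, 1, 8)
  education <- sample.int(6L, n, replace = TRUE, prob = edu_p)
  centre <- sample.int(6L, n, replace = TRUE)
  genotype <- stats::rbinom(n, 2L, 0.15)
  X <- cbind(age = age - ctr["age"], female = female - ctr["female"],
             ldl0 = ldl0 - ctr["ldl0"], education = education - ctr["education"])
  cc <- config$conf_coefs
  lin <- function(coefs) {
    coefs <- coefs[intersect(names(coefs), colnames(X))]
    if (length(coefs) == 0L) return(rep(0, n))
    drop(X[, names(coefs), drop = FALSE] %*% coefs)
  }
  xb_pdc <- lin(cc$pdc)
  xb_lr <- lin(cc$lr)

  gaps <- matrix(draw_gaps(n * K, config$visit_gap_law), n, K)
  visit_day <- t(apply(gaps, 1L, cumsum))
  if (K == 1L) visit_day <- matrix(visit_day, ncol = 1L)
  baseline_day <- -sample.int(30L, n, replace = TRUE)

  pdc <- matrix(NA_real_, n, K)
  lr <- matrix(NA_real_, n, K)
  lr_prev <- rep(0, n)
  for (k in seq_len(K)) {
    p <- config$pdc_mean + xb_pdc + config$feedback_coef * lr_prev +
      stats::rnorm(n, 0, config$pdc_noise_sd)
    p <- pmin(pmax(p, 0), 150)
    l <- config$beta_direct[k] * p + config$carry_coef * lr_prev + xb_lr +
      stats::rnorm(n, 0, config$lr_noise_sd)
    l <- pmax(l, -0.95)
    pdc[, k] <- p
    lr[, k] <- l
    lr_prev <- l
  }
  out <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                    age = age, female = female, ldl0 = ldl0,
                    education = education, centre = centre,
                    genotype = genotype, baseline_day = baseline_day)
  for (k in seq_len(K)) {
    out[[paste0("visit_day_", k)]] <- visit_day[, k]
    out[[paste0("pdc_", k)]] <- pdc[, k]
    out[[paste0("lr_", k)]] <- lr[, k]
    out[[paste0("ldl_", k)]] <- ldl0 * (1 + lr[, k])
  }
  out
}

#' Implied marginal-structural coefficients of a configuration
#'
#' For the linear structural system of [sim_config()], intervening to set
#' `PDC_j = a_j` for all `j <= k` gives
#' `E[LR_k(a)] = const + sum_j beta_j * carry^(k-j) * a_j`, so the true
#' marginal-structural coefficient of `PDC_j` on `LR_k` is
#' `beta_direct[j] * carry_coef^(k-j)`.
#'
#' @param config A [sim_config()].
#' @return Lower-triangular `K x K` matrix `b[k, j]`.
#' @export
true_msm_coef <- function(config) {
  K <- config$K
  b <- matrix(0, K, K, dimnames = list(paste0("lr_", 1:K), paste0("pdc_", 1:K)))
  for (k in seq_len(K)) for (j in seq_len(k)) {
    b[k, j] <- config$beta_direct[j] * config$carry_coef^(k - j)
  }
  b
}

#' Fast path: analysis-ready longitudinal data with latent adherence
#'
#' Runs only the structural simulation and returns the per-patient table
#' with the latent interval PDCs as the exposures (no prescription
#' rendering). Education and centre are returned as factors ready for
#' [msm_design()]. Intended for Monte-Carlo studies of the weighting
#' estimator; [generate_cohort()] + [assemble_msm_data()] exercise the same
#' structure through raw prescription/measurement tables.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return Data frame, one row per patient.
#' @export
generate_msm_data <- function(config, seed = config$seed) {
  set.seed(seed)
  dat <- simulate_structural(config)
  dat$education <- factor(dat$education, levels = 1:6)
  dat$centre <- factor(dat$centre, levels = 1:6)
  dat
}

#' Render a latent-adherence window as dispensing events
#'
#' Inverts the PDC formula: for a window of `W` days with latent adherence
#' `pdc` percent, emits refills of `tablets_per_script` tablets at intervals
#' of `tablets_per_script / (pdc/100)` days (plus optional Gaussian day
#' jitter, rounded to whole days), with the final refill carrying the
#' remaining tablets so that the total dispensed equals
#' `round(pdc/100 * W)`. Recomputing PDC over the window from the emitted
#' records then recovers the latent value to within half a tablet per
#' window (comfortably inside +-2 percentage points) at zero jitter.
#'
#' @param pdc Latent adherence percent, in [0, 150]; 0 emits no scripts.
#' @param window `c(start, end)` day offsets, half-open.
#' @param tablets_per_script Tablets per full refill.
#' @param jitter_sd Day jitter SD (0 = deterministic schedule).
#' @return Data frame with `date_day`, `n_tablets` (possibly 0 rows).
#' @export
render_prescriptions <- function(pdc, window, tablets_per_script = 28L,
                                 jitter_sd = 0) {
  if (pdc < 0 || pdc > 150) stop("latent PDC must lie in [0, 150]")
  start <- window[1L]; end <- window[2L]
  if (end <= start) stop("window must have positive length")
  if (pdc == 0) return(data.frame(date_day = integer(0), n_tablets = integer(0)))
  W <- end - start
  total <- round(pdc / 100 * W)
  if (total < 1) return(data.frame(date_day = integer(0), n_tablets = integer(0)))
  gap <- tablets_per_script / (pdc / 100)
  n_full <- total %/% tablets_per_script
  rem <- total - n_full * tablets_per_script
  sizes <- c(rep(tablets_per_script, n_full), if (rem > 0) rem)
  idx <- seq_along(sizes) - 1L
  days <- start + round(idx * gap +
                          if (jitter_sd > 0) stats::rnorm(length(idx), 0, jitter_sd) else 0)
  days[1L] <- max(days[1L], start)
  keep <- days >= start & days < end
  data.frame(date_day = as.integer(days[keep]), n_tablets = as.integer(sizes[keep]))
}

#' Generate a synthetic cohort with raw-style tables
#'
#' Draws the structural simulation of [sim_config()] and renders it as the
#' four raw tables a primary-care extract would provide: dispensing events
#' (refill streams whose gaps encode the latent interval adherence), dated
#' LDL-c measures (baseline a few weeks before treatment start, then one per
#' visit), fixed covariates, and clinical events (empty unless violations
#' are planted). Ground truth (latent PDCs, LR values and the generating
#' coefficients) is kept alongside.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return Object of class `cohort_bundle`: list with `prescriptions`,
#'   `ldl`, `covariates`, `events`, `truth` (list: `latent` per-patient
#'   table, `msm_coef`, `config`) and `config`.
#' @examples
#' b <- generate_cohort(sim_config(n_patients = 20, seed = 7))
#' head(b$prescriptions)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  set.seed(seed)
  dat <- simulate_structural(config)
  n <- nrow(dat)
  K <- config$K
  vcols <- paste0("visit_day_", seq_len(K))
  pcols <- paste0("pdc_", seq_len(K))
  rx_list <- vector("list", n)
  for (i in seq_len(n)) {
    vd <- as.numeric(dat[i, vcols])
    starts <- c(0, vd[-K])
    ends <- vd
    per <- lapply(seq_len(K), function(k) {
      render_prescriptions(dat[[pcols[k]]][i], c(starts[k], ends[k]),
                           tablets_per_script = config$tablets_per_script,
                           jitter_sd = config$jitter_sd)
    })
    rx <- do.call(rbind, per)
    if (nrow(rx) > 0L) {
      rx$patient_id <- dat$patient_id[i]
      rx_list[[i]] <- rx
    }
  }
  prescriptions <- do.call(rbind, rx_list[!vapply(rx_list, is.null, logical(1))])
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$date_day), ]
  prescriptions$drug <- "atorvastatin"
  prescriptions$dose_band <- "medium"
  prescriptions <- prescriptions[, c("patient_id", "date_day", "n_tablets",
                                     "drug", "dose_band")]
  rownames(prescriptions) <- NULL

  ldl_rows <- list(data.frame(patient_id = dat$patient_id,
                              date_day = dat$baseline_day,
                              ldl_mmol_l = dat$ldl0))
  for (k in seq_len(K)) {
    ldl_rows[[k + 1L]] <- data.frame(patient_id = dat$patient_id,
                                     date_day = dat[[vcols[k]]],
                                     ldl_mmol_l = dat[[paste0("ldl_", k)]])
  }
  ldl <- do.call(rbind, ldl_rows)
  ldl <- ldl[order(ldl$patient_id, ldl$date_day), ]
  rownames(ldl) <- NULL

  covariates <- dat[, c("patient_id", "age", "female", "education",
                        "centre", "genotype")]
  events <- data.frame(patient_id = character(0), date_day = integer(0),
                       event_type = character(0))
  truth <- list(latent = dat, msm_coef = true_msm_coef(config), config = config)
  structure(list(prescriptions = prescriptions, ldl = ldl,
                 covariates = covariates, events = events, truth = truth,
                 config = config, violations = NULL),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic statin cohort:", nrow(x$covariates), "patients,",
      nrow(x$prescriptions), "prescriptions,", nrow(x$ldl), "LDL measures\n")
  if (!is.null(x$violations)) {
    cat("Planted violations:",
        paste(names(table(x$violations$violation)),
              table(x$violations$violation), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plant known data-quality violations into a cohort
#'
#' Injects a requested number of each violation class so that the filter
#' stages can be tested against exact counts: implausible first-year
#' dispensing (duplicated same-day scripts driving PDC1 above 200%),
#' out-of-range LDL-c values, deaths within 90 days of treatment start, and
#' treatment initiation within 90 days of a cardiovascular hospital
#' discharge. Classes are assigned to disjoint patient sets, chosen
#' deterministically (first patients by id).
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param plan Named list of counts among `pdc_gt_200`, `ldl_low`,
#'   `ldl_high`, `death_lt_3mo`, `post_discharge`; missing entries default
#'   to 0.
#' @return The bundle with violations injected and `violations` set to a
#'   ledger data frame (`patient_id`, `violation`).
#' @export
plant_violations <- function(bundle, plan = list()) {
  classes <- c("pdc_gt_200", "ldl_low", "ldl_high", "death_lt_3mo",
               "post_discharge")
  unknown <- setdiff(names(plan), classes)
  if (length(unknown)) stop("unknown violation class: ", paste(unknown, collapse = ", "))
  counts <- vapply(classes, function(cl) {
    v <- plan[[cl]]
    if (is.null(v)) 0L else as.integer(v)
  }, integer(1))
  total <- sum(counts)
  ids <- sort(unique(as.character(bundle$covariates$patient_id)))
  if (total > length(ids)) stop("requested violations exceed number of patients")
  if (total == 0L) {
    bundle$violations <- data.frame(patient_id = character(0),
                                    violation = character(0))
    return(bundle)
  }
  pick <- split(ids[seq_len(total)], rep(classes, counts))
  ledger <- data.frame(patient_id = ids[seq_len(total)],
                       violation = rep(classes, counts))

  for (id in pick$pdc_gt_200) {
    # duplicated same-day scripts: enough tablets to exceed 200% over any
    # realized first-year window (which never exceeds ~600 days here)
    extra <- data.frame(patient_id = id, date_day = c(1L, 1L),
                        n_tablets = c(800L, 800L), drug = "atorvastatin",
                        dose_band = "medium")
    bundle$prescriptions <- rbind(bundle$prescriptions, extra)
  }
  for (id in pick$ldl_low) {
    i <- which(as.character(bundle$ldl$patient_id) == id &
                 bundle$ldl$date_day > 0)[1L]
    if (is.na(i)) i <- which(as.character(bundle$ldl$patient_id) == id)[1L]
    bundle$ldl$ldl_mmol_l[i] <- 0.5
  }
  for (id in pick$ldl_high) {
    i <- which(as.character(bundle$ldl$patient_id) == id &
                 bundle$ldl$date_day > 0)[1L]
    if (is.na(i)) i <- which(as.character(bundle$ldl$patient_id) == id)[1L]
    bundle$ldl$ldl_mmol_l[i] <- 9.5
  }
  ev <- list(bundle$events)
  if (length(pick$death_lt_3mo)) {
    ev <- c(ev, list(data.frame(patient_id = pick$death_lt_3mo,
                                date_day = 60L, event_type = "death")))
  }
  if (length(pick$post_discharge)) {
    ev <- c(ev, list(data.frame(patient_id = pick$post_discharge,
                                date_day = -30L,
                                event_type = "hospital_discharge_cvd")))
  }
  bundle$events <- do.call(rbind, ev)
  bundle$prescriptions <- bundle$prescriptions[
    order(bundle$prescriptions$patient_id, bundle$prescriptions$date_day), ]
  rownames(bundle$prescriptions) <- NULL
  bundle$violations <- ledger
  bundle
}

#' Write a cohort bundle as delimited text tables
#'
#' Emits `prescriptions.csv`, `ldl.csv`, `covariates.csv`, `events.csv` and
#' `truth.json` (generating parameters and latent per-patient values) into a
#' directory.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$prescriptions, file.path(dir, "prescriptions.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$ldl, file.path(dir, "ldl.csv"), row.names = FALSE)
  utils::write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  truth <- list(config = unclass(bundle$truth$config),
                msm_coef = bundle$truth$msm_coef,
                latent = bundle$truth$latent)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A `cohort_bundle` (without `truth` unless `truth.json` exists).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  out <- list(prescriptions = rd("prescriptions.csv"), ldl = rd("ldl.csv"),
              covariates = rd("covariates.csv"), events = rd("events.csv"),
              truth = NULL, config = NULL, violations = NULL)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    out$truth <- truth
    out$config <- truth$config
  }
  structure(out, class = "cohort_bundle")
}
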