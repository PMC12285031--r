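#' Design object for sequential-exposure weighting
#'
#' Assembles, from an analysis-ready longitudinal table (one row per
#' patient), the pieces the weighting and outcome stages need: the exposure
#' matrix `A` (interval PDCs), per-time-point confounder matrices `X[[k]]`
#' (fixed confounders, the visit time of measure `k`, and for `k > 1` the
#' lagged exposure and lagged outcome), and the outcome matrix `L` (LR
#' values). Factors are expanded to dummy columns; constant columns are
#' dropped.
#'
#' @param data Data frame with columns `pdc_1..K`, `lr_1..K`,
#'   `visit_day_1..K` and the fixed confounders.
#' @param K Number of time points.
#' @param fixed Character vector of fixed confounder column names.
#' @param exposures,outcomes,visit_times Column-name prefixes.
#' @return Object of class `msm_design`.
#' @export
msm_design <- function(data, K = 3L,
                       fixed = c("age", "female", "ldl0", "education", "centre"),
                       exposures = "pdc_", outcomes = "lr_",
                       visit_times = "visit_day_") {
  stopifnot(nrow(data) >= 1L)
  acols <- paste0(exposures, seq_len(K))
  lcols <- paste0(outcomes, seq_len(K))
  vcols <- paste0(visit_times, seq_len(K))
  need <- c(acols, lcols, vcols, fixed)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(data[need])) stop("msm_design requires complete cases")
  A <- as.matrix(data[acols])
  L <- as.matrix(data[lcols])
  Fm <- stats::model.matrix(~ ., data = data[fixed])[, -1L, drop = FALSE]
  keep <- apply(Fm, 2L, function(x) stats::var(x) > 0)
  if (nrow(Fm) > 1L && !all(keep)) Fm <- Fm[, keep, drop = FALSE]
  X <- vector("list", K)
  for (k in seq_len(K)) {
    xk <- cbind(Fm, visit_day = data[[vcols[k]]])
    colnames(xk)[ncol(xk)] <- vcols[k]
    if (k > 1L) {
      xk <- cbind(xk, prior_pdc = A[, k - 1L], prior_lr = L[, k - 1L])
    }
    X[[k]] <- xk
  }
  structure(list(A = A, L = L, X = X, K = K, n = nrow(data),
                 fixed_names = colnames(Fm), visit_names = vcols,
                 patient_id = if ("patient_id" %in% names(data))
                   data$patient_id else seq_len(nrow(data))),
            class = "msm_design")
}

subset_design <- function(design, idx) {
  design$A <- design$A[idx, , drop = FALSE]
  design$L <- design$L[idx, , drop = FALSE]
  design$X <- lapply(design$X, function(x) x[idx, , drop = FALSE])
  design$n <- length(idx)
  design$patient_id <- design$patient_id[idx]
  design
}

scale_cols <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  sweep(sweep(M, 2L, mu, "-"), 2L, sd, "/")
}

# balance moment matrix: standardized exposure_k x standardized covariate
# products, one block per time point
balance_moments <- function(design) {
  blocks <- lapply(seq_len(design$K), function(k) {
    z <- scale_cols(design$A[, k, drop = FALSE])
    C <- scale_cols(design$X[[k]])
    G <- C * as.vector(z)
    colnames(G) <- paste0("pdc_", k, ":", colnames(design$X[[k]]))
    G
  })
  do.call(cbind, blocks)
}

# entropy tilt: reweight base weights w0 -> w0 * exp(G delta) (normalized)
# so that the weighted mean of every balance moment is zero; convex dual
# solved by damped Newton
entropy_tilt <- function(w0, G, max_iter = 100L, tol = 1e-9) {
  m <- ncol(G)
  delta <- rep(0, m)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(G %*% delta)
    eta <- eta - max(eta)
    w <- w0 * exp(eta)
    p <- w / sum(w)
    g <- drop(crossprod(G, p))
    if (max(abs(g)) < tol) { conv <- TRUE; break }
    pG <- G * p
    H <- crossprod(G, pG) - tcrossprod(g)
    step <- tryCatch(solve(H + diag(1e-10, m), g),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(list(ok = FALSE))
    # damped update with simple halving on objective increase
    f0 <- log(sum(w0 * exp(drop(G %*% delta) - max(drop(G %*% delta)))))
    s <- 1
    repeat {
      cand <- delta - s * step
      eta_c <- drop(G %*% cand)
      fc <- log(sum(w0 * exp(eta_c - max(eta_c))))
      if (is.finite(fc)) { delta <- cand; break }
      s <- s / 2
      if (s < 1e-6) return(list(ok = FALSE))
    }
  }
  eta <- drop(G %*% delta)
  eta <- eta - max(eta)
  w <- w0 * exp(eta)
  list(ok = conv, w = w / mean(w), delta = delta)
}

#' Stabilized covariate-balancing weights for sequential continuous
#' exposures
#'
#' Two-layer construction of the inverse-probability-of-treatment weights
#' used to form the pseudo-population in which interval adherence is
#' unconfounded by measured covariates.
#'
#' Layer 1 (stabilized IPW): for each time point `k`, the conditional law of
#' `PDC_k` given the fixed confounders, the visit time and the lagged
#' exposure/outcome is modelled as Gaussian-linear; the weight numerator is
#' the marginal Gaussian density of `PDC_k`, and the per-patient weight is
#' the product over `k` of numerator/denominator ratios (cumulative-product
#' sequential weights, standard marginal-structural-model practice).
#'
#' Layer 2 (balance calibration, `method = "cbps"`): the stabilized weights
#' are exponentially tilted to solve the covariate-balancing moment
#' conditions exactly in sample — the weighted covariance between every
#' exposure and every covariate in its confounder set is driven to zero —
#' by minimizing the convex entropy dual (Newton iterations). This is the
#' direct-balancing analogue of the covariate-balancing propensity score
#' for continuous treatments. `method = "npcbps"` applies the same tilt
#' starting from uniform weights (no parametric exposure density);
#' `method = "ipw"` returns the untilted stabilized weights.
#'
#' If the balancing solve fails to converge the function falls back to the
#' stabilized weights and records `method = "stabilized_ipw"` with a
#' warning.
#'
#' @param design An [msm_design()].
#' @param method `"cbps"` (default), `"npcbps"` or `"ipw"`.
#' @param truncation Optional length-2 percentile pair (e.g. `c(0.01,
#'   0.99)`) at which the final weights are winsorized; default `NULL`
#'   (none).
#' @return Object of class `weight_set`: list with `w` (final weights, mean
#'   1), `sw` (stabilized-IPW layer), `method`, `converged`, `truncation`.
#' @export
estimate_weights <- function(design, method = c("cbps", "npcbps", "ipw"),
                             truncation = NULL) {
  method <- match.arg(method)
  n <- design$n
  if (n < 2L) {
    return(structure(list(w = rep(1, n), sw = rep(1, n),
                          method = "degenerate", converged = TRUE,
                          truncation = NULL), class = "weight_set"))
  }
  sw <- rep(1, n)
  for (k in seq_len(design$K)) {
    a <- design$A[, k]
    Xk <- design$X[[k]]
    qrX <- qr(cbind(1, Xk))
    if (qrX$rank < ncol(Xk) + 1L) {
      bad <- colnames(Xk)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xk) + 1L)] - 1L]
      stop("collinear covariate columns at time point ", k, ": ",
           paste(stats::na.omit(bad), collapse = ", "))
    }
    fit <- qr.fitted(qrX, a)
    res <- a - fit
    sd_c <- sqrt(mean(res^2))
    den <- stats::dnorm(a, fit, sd_c)
    # stabilizing numerator: marginal for k = 1, conditional on the past
    # exposure history for k > 1 (standard sequential stabilization)
    if (k == 1L) {
      num <- stats::dnorm(a, mean(a), stats::sd(a))
    } else {
      qrN <- qr(cbind(1, design$A[, seq_len(k - 1L), drop = FALSE]))
      fitn <- qr.fitted(qrN, a)
      sd_n <- sqrt(mean((a - fitn)^2))
      num <- stats::dnorm(a, fitn, sd_n)
    }
    sw <- sw * num / pmax(den, .Machine$double.xmin)
  }
  sw <- sw / mean(sw)
  converged <- TRUE
  used <- method
  if (method %in% c("cbps", "npcbps")) {
    base <- if (method == "cbps") sw else rep(1, n)
    G <- balance_moments(design)
    tilt <- entropy_tilt(base, G)
    if (isTRUE(tilt$ok)) {
      w <- tilt$w
    } else {
      warning("balancing calibration did not converge; ",
              "falling back to stabilized IPW")
      w <- sw
      used <- "stabilized_ipw"
      converged <- FALSE
    }
  } else {
    w <- sw
  }
  if (!is.null(truncation)) {
    q <- stats::quantile(w, truncation)
    w <- pmin(pmax(w, q[1L]), q[2L])
    w <- w / mean(w)
  }
  structure(list(w = w, sw = sw,
                 method = if (used == "cbps") "parametric_cbps"
                 else if (used == "npcbps") "npcbps_fallback" else used,
                 converged = converged, truncation = truncation),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Weight set (", x$method, "): n =", length(x$w),
      " sd(w) =", signif(stats::sd(x$w), 3), "\n")
  invisible(x)
}

weighted_pearson <- function(x, y, w) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

weighted_spearman <- function(x, y, w) {
  weighted_pearson(rank(x), rank(y), w)
}

#' Covariate balance diagnostics in the weighted pseudo-population
#'
#' Computes, for every (exposure time point, covariate) pair in the design,
#' the weighted Pearson correlation and the weighted Spearman correlation
#' (ranks, then weighted Pearson). A covariate passes when the average of
#' its mean absolute Pearson and mean absolute Spearman correlation across
#' time points falls below the cutoff (default 0.1). Zero-variance
#' covariates are reported as `NA` and never counted as passing.
#'
#' @param weights A `weight_set` (or bare numeric weight vector).
#' @param design The [msm_design()] the weights were estimated on.
#' @param threshold Balance cutoff on the average absolute correlation.
#' @return Object of class `balance_report`: list with `pairs` (long data
#'   frame: `k`, `covariate`, `pearson`, `spearman`), `summary`
#'   (per-covariate averages and `pass`), `failed_covariates`, `threshold`.
#' @export
check_balance <- function(weights, design, threshold = 0.1) {
  w <- if (inherits(weights, "weight_set")) weights$w else weights
  stopifnot(length(w) == design$n)
  rows <- list()
  for (k in seq_len(design$K)) {
    a <- design$A[, k]
    Xk <- design$X[[k]]
    for (j in seq_len(ncol(Xk))) {
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, covariate = colnames(Xk)[j],
        pearson = weighted_pearson(a, Xk[, j], w),
        spearman = weighted_spearman(a, Xk[, j], w))
    }
  }
  pairs <- do.call(rbind, rows)
  covs <- unique(pairs$covariate)
  summ <- do.call(rbind, lapply(covs, function(cv) {
    sub <- pairs[pairs$covariate == cv, ]
    mp <- mean(abs(sub$pearson))
    ms <- mean(abs(sub$spearman))
    avg <- (mp + ms) / 2
    data.frame(covariate = cv, mean_abs_pearson = mp, mean_abs_spearman = ms,
               avg_abs_corr = avg,
               pass = !is.na(avg) & avg < threshold)
  }))
  structure(list(pairs = pairs, summary = summ,
                 failed_covariates = summ$covariate[!summ$pass],
                 threshold = threshold),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report (cutoff", x$threshold, "):",
      sum(x$summary$pass), "of", nrow(x$summary), "covariates balanced\n")
  if (length(x$failed_covariates)) {
    cat("Failed:", paste(x$failed_covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

wls_coef <- function(y, Xmat, w) {
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, Xmat), y, w)
  fit$coefficients
}

#' Weighted marginal structural model of LDL reduction on interval
#' adherence
#'
#' Stage-2 of the IPTW procedure: for each time point `k`, the fractional
#' LDL reduction `LR_k` is regressed by weighted least squares on
#' `PDC_1 .. PDC_k` simultaneously (plus any covariates that failed the
#' balance diagnostic and are forced into the regression). Coefficients are
#' in LR units per PDC percentage point. Uncertainty is by nonparametric
#' bootstrap over patients with the weights re-estimated inside every
#' replicate.
#'
#' @param design An [msm_design()].
#' @param weights A `weight_set` for the full sample (re-used as the point
#'   estimate; bootstrap replicates re-estimate with the same `method`).
#' @param forced_covariates Character vector of covariate column names
#'   (from the design's confounder matrices) to include in the stage-2
#'   regressions; typically `failed_covariates` from [check_balance()].
#' @param n_boot Number of bootstrap replicates (0 = no bootstrap; CIs then
#'   come from the naive weighted-OLS covariance).
#' @param seed RNG seed for the bootstrap.
#' @param ci_type `"norm"` (bootstrap-SE normal interval, default) or
#'   `"perc"` (percentile).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `msm_estimate`: `coef` (lower-triangular `K x K`
#'   matrix, `coef[k, j]` = effect of `PDC_j` on `LR_k`), `se`, `ci_lo`,
#'   `ci_hi` (same shape), `boot` (replicate array `K x K x B` or `NULL`),
#'   `forced`, `K`, `n`, `method`, `n_boot`, `boot_dropped`, `seed`.
#' @export
fit_weighted_msm <- function(design, weights, forced_covariates = character(0),
                             n_boot = 0L, seed = 1L, ci_type = c("norm", "perc"),
                             conf_level = 0.95) {
  ci_type <- match.arg(ci_type)
  if (design$K > ncol(design$L)) stop("K exceeds available LR columns")
  w <- if (inherits(weights, "weight_set")) weights$w else weights
  method <- if (inherits(weights, "weight_set")) weights$method else "supplied"

  fit_once <- function(d, wt) {
    co <- matrix(NA_real_, d$K, d$K)
    for (k in seq_len(d$K)) {
      Xmat <- d$A[, seq_len(k), drop = FALSE]
      if (length(forced_covariates)) {
        Fc <- forced_matrix(d, forced_covariates, k)
        Xmat <- cbind(Xmat, Fc)
      }
      beta <- wls_coef(d$L[, k], Xmat, wt)
      co[k, seq_len(k)] <- beta[2:(k + 1L)]
    }
    co
  }
  coef_hat <- fit_once(design, w)

  boot <- NULL
  dropped <- 0L
  if (n_boot > 0L) {
    set.seed(seed)
    wm <- weight_method_arg(method)
    trunc_arg <- if (inherits(weights, "weight_set")) weights$truncation else NULL
    boot <- array(NA_real_, c(design$K, design$K, n_boot))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(design$n, design$n, replace = TRUE)
      db <- subset_design(design, idx)
      cb <- tryCatch({
        wb <- suppressWarnings(estimate_weights(db, method = wm,
                                                truncation = trunc_arg))
        fit_once(db, wb$w)
      }, error = function(e) NULL)
      if (is.null(cb)) dropped <- dropped + 1L else boot[, , b] <- cb
    }
  }
  alpha <- (1 - conf_level) / 2
  z <- stats::qnorm(1 - alpha)
  se <- ci_lo <- ci_hi <- matrix(NA_real_, design$K, design$K)
  if (!is.null(boot)) {
    for (k in seq_len(design$K)) for (j in seq_len(k)) {
      reps <- boot[k, j, ]
      reps <- reps[is.finite(reps)]
      se[k, j] <- stats::sd(reps)
      if (ci_type == "norm") {
        ci_lo[k, j] <- coef_hat[k, j] - z * se[k, j]
        ci_hi[k, j] <- coef_hat[k, j] + z * se[k, j]
      } else {
        qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
        ci_lo[k, j] <- qs[1L]; ci_hi[k, j] <- qs[2L]
      }
    }
  } else {
    # naive weighted-OLS covariance (ignores weight estimation uncertainty)
    for (k in seq_len(design$K)) {
      Xmat <- design$A[, seq_len(k), drop = FALSE]
      if (length(forced_covariates)) {
        Xmat <- cbind(Xmat, forced_matrix(design, forced_covariates, k))
      }
      Xf <- cbind(1, Xmat)
      fit <- stats::lm.wfit(Xf, design$L[, k], w)
      dfres <- design$n - fit$rank
      s2 <- sum(w * fit$residuals^2) / max(dfres, 1L)
      XtWX_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                     drop = FALSE])
      se_all <- sqrt(s2 * diag(XtWX_inv))
      se[k, seq_len(k)] <- se_all[2:(k + 1L)]
      ci_lo[k, seq_len(k)] <- coef_hat[k, seq_len(k)] - z * se[k, seq_len(k)]
      ci_hi[k, seq_len(k)] <- coef_hat[k, seq_len(k)] + z * se[k, seq_len(k)]
    }
  }
  dimnames(coef_hat) <- dimnames(se) <- dimnames(ci_lo) <- dimnames(ci_hi) <-
    list(paste0("lr_", seq_len(design$K)), paste0("pdc_", seq_len(design$K)))
  structure(list(coef = coef_hat, se = se, ci_lo = ci_lo, ci_hi = ci_hi,
                 boot = boot, forced = forced_covariates, K = design$K,
                 n = design$n, method = method, n_boot = n_boot,
                 boot_dropped = dropped, seed = seed,
                 conf_level = conf_level, ci_type = ci_type),
            class = "msm_estimate")
}

weight_method_arg <- function(method) {
  switch(method,
         parametric_cbps = "cbps", npcbps_fallback = "npcbps",
         stabilized_ipw = "ipw", ipw = "ipw", "cbps")
}

forced_matrix <- function(design, forced, k) {
  cols <- lapply(forced, function(nm) {
    # a forced covariate may exist at several time points (e.g. visit_day_k);
    # take it from the latest confounder set at or before k that has it
    for (kk in rev(seq_len(design$K))) {
      if (nm %in% colnames(design$X[[kk]])) return(design$X[[kk]][, nm])
    }
    stop("forced covariate not found in design: ", nm)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- forced
  out
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat("Marginal structural model, K =", x$K, " n =", x$n,
      " weights:", x$method, "\n")
  cat("Coefficients (LR units per PDC percentage point):\n")
  print(signif(x$coef, 4))
  if (!is.null(x$boot)) {
    cat("Bootstrap:", x$n_boot, "replicates (", x$boot_dropped, "dropped )\n")
  }
  invisible(x)
}

#' Static intervention contrast
#'
#' Expected difference in `LR_k` between two fixed adherence profiles under
#' the fitted marginal structural model:
#' `sum_j coef[k, j] * (a_j - b_j)`. The sustained full-adherence contrast
#' of the paper-style analysis is `intervention_contrast(est, rep(100, K),
#' rep(0, K))`.
#'
#' @param estimate An [fit_weighted_msm()] result.
#' @param profile_a,profile_b Length-`k` PDC vectors (percent).
#' @param k Time point (default the last).
#' @return List with `contrast` (LR units), `ci_lo`, `ci_hi` (bootstrap
#'   quantiles, `NA` without bootstrap).
#' @export
intervention_contrast <- function(estimate, profile_a, profile_b,
                                  k = estimate$K) {
  if (length(profile_a) != k || length(profile_b) != k) {
    stop("profiles must have length k = ", k)
  }
  d <- profile_a - profile_b
  point <- sum(estimate$coef[k, seq_len(k)] * d)
  lo <- hi <- NA_real_
  if (!is.null(estimate$boot)) {
    reps <- apply(estimate$boot[k, seq_len(k), , drop = FALSE], 3L,
                  function(bb) sum(bb * d))
    reps <- reps[is.finite(reps)]
    alpha <- (1 - estimate$conf_level) / 2
    if (estimate$ci_type == "norm") {
      z <- stats::qnorm(1 - alpha)
      s <- stats::sd(reps)
      lo <- point - z * s; hi <- point + z * s
    } else {
      qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
      lo <- qs[1L]; hi <- qs[2L]
    }
  }
  list(contrast = point, ci_lo = lo, ci_hi = hi, k = k)
}

#' Personal-maximum adherence contrast
#'
#' For each patient, the model-implied difference in `LR_K` between holding
#' adherence constant at their own maximum observed interval PDC and their
#' actually observed PDC profile; returns the cohort mean. A patient whose
#' adherence never varied contributes zero.
#'
#' @param estimate An [fit_weighted_msm()] result.
#' @param observed_pdc `n x K` matrix (or data frame) of observed interval
#'   PDCs.
#' @return List with `contrast` (mean LR difference), `ci_lo`, `ci_hi`
#'   (bootstrap, coefficient uncertainty), `per_patient` vector.
#' @export
personal_max_contrast <- function(estimate, observed_pdc) {
  A <- as.matrix(observed_pdc)
  K <- estimate$K
  stopifnot(ncol(A) == K)
  bK <- estimate$coef[K, seq_len(K)]
  mx <- apply(A, 1L, max)
  D <- mx - A                      # n x K gaps to personal maximum
  per <- drop(D %*% bK)
  point <- mean(per)
  lo <- hi <- NA_real_
  if (!is.null(estimate$boot)) {
    reps <- apply(estimate$boot[K, seq_len(K), , drop = FALSE], 3L,
                  function(bb) mean(drop(D %*% as.vector(bb))))
    reps <- reps[is.finite(reps)]
    alpha <- (1 - estimate$conf_level) / 2
    if (estimate$ci_type == "norm") {
      z <- stats::qnorm(1 - alpha)
      s <- stats::sd(reps)
      lo <- point - z * s; hi <- point + z * s
    } else {
      qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
      lo <- qs[1L]; hi <- qs[2L]
    }
  }
  list(contrast = point, ci_lo = lo, ci_hi = hi, per_patient = per)
}

#' Assemble analysis-ready longitudinal data from raw tables
#'
#' End-to-end plumbing from a cohort bundle (or the tables read back from
#' disk) to the input of [msm_design()]: builds longitudinal LDL
#' trajectories (validity filters, baseline, first three follow-ups),
#' recomputes interval PDCs from the dispensing records over the realized
#' visit windows, and joins the fixed covariates.
#'
#' @param bundle A `cohort_bundle` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param K Number of follow-up visits required (default 3).
#' @return Data frame with one row per retained patient and the columns
#'   [msm_design()] expects.
#' @export
assemble_msm_data <- function(bundle, K = 3L) {
  tr <- build_trajectories(bundle$ldl, bundle$events, mode = "longitudinal",
                           n_required = K)
  traj <- tr$trajectories
  if (is.null(traj)) stop("no patients with complete trajectories")
  visits <- traj[, c("patient_id", "baseline_day",
                     paste0("visit_day_", seq_len(K)))]
  adh <- compute_adherence(bundle$prescriptions, visits = visits)
  dat <- merge(traj, adh[, c("patient_id", paste0("pdc_", seq_len(K)))],
               by = "patient_id")
  dat <- merge(dat, bundle$covariates, by = "patient_id")
  dat$education <- factor(dat$education, levels = sort(unique(dat$education)))
  dat$centre <- factor(dat$centre, levels = sort(unique(dat$centre)))
  dat[stats::complete.cases(dat[, c(paste0("pdc_", seq_len(K)),
                                    paste0("lr_", seq_len(K)))]), ]
}
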