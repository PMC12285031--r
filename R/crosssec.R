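#' Quadratic time-to-follow-up model of LDL-c change
#'
#' Fits the cross-sectional response model: the LDL change ratio
#' `Y = LDL1 / LDL0` against time to the first follow-up measurement with a
#' quadratic term, optionally a group factor (adherence category or
#' genotype) interacting with both time terms, and an adjustment set. Time
#' enters in days and is reported in weeks by downstream summaries.
#'
#' @param data Data frame with the outcome `y_ratio`, the follow-up time in
#'   days, and any group/adjustment columns.
#' @param time Name of the follow-up-time column in days (default
#'   `"t_days"`).
#' @param group Optional name of a factor column (e.g. `pdc1_category`, or
#'   a 0/1/2 additively coded genotype turned into a factor); interacts
#'   with time and time squared.
#' @param adjust Character vector of adjustment covariate names (e.g. sex,
#'   age at first prescription, centre, dose band, education, prevalent
#'   CVD).
#' @return Object of class `ldl_response_fit`: list with the underlying
#'   `lm` fit, `coef_table` (estimate, SE, 95% CI), and metadata.
#' @export
fit_response_model <- function(data, time = "t_days", group = NULL,
                               adjust = NULL) {
  stopifnot("y_ratio" %in% names(data), time %in% names(data))
  d <- data
  d$.t <- d[[time]]
  d$.t2 <- d[[time]]^2
  rhs <- c(".t", ".t2")
  if (!is.null(group)) {
    if (!group %in% names(d)) stop("group column not found: ", group)
    g <- d[[group]]
    if (!is.factor(g)) g <- factor(g)
    if (any(table(g) == 0L)) {
      stop("empty group level: ",
           paste(levels(g)[table(g) == 0L], collapse = ", "))
    }
    d$.grp <- g
    rhs <- c(rhs, ".grp", ".grp:.t", ".grp:.t2")
  }
  if (!is.null(adjust)) rhs <- c(rhs, adjust)
  f <- stats::reformulate(rhs, response = "y_ratio")
  fit <- stats::lm(f, data = d)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  coef_table <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                           se = cf[, 2L], ci_lo = ci[, 1L], ci_hi = ci[, 2L],
                           row.names = NULL)
  structure(list(fit = fit, coef_table = coef_table, time = time,
                 group = group, adjust = adjust),
            class = "ldl_response_fit")
}

#' @export
print.ldl_response_fit <- function(x, ...) {
  cat("LDL-c change response model (quadratic in time)\n")
  print(x$coef_table, digits = 4)
  invisible(x)
}

#' Week of extreme LDL-c response
#'
#' Locates the vertex of the fitted quadratic response curve at the
#' reference group level: `t* = -b_t / (2 b_t2)` days. A positive quadratic
#' coefficient (convex change ratio) means maximal reduction at the vertex.
#' The confidence interval is a parametric bootstrap from the coefficient
#' covariance matrix.
#'
#' @param fit An [fit_response_model()] result, or a named numeric vector
#'   of coefficients containing `(Intercept)`, `.t` and `.t2`.
#' @param n_sim Parametric bootstrap draws (only used for an `lm`-backed
#'   fit).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return List with `convex` (TRUE when an interior minimum of Y exists),
#'   `vertex_days`, `vertex_week`, `fitted_y`, and `ci_week`, `ci_y`
#'   (2-vectors, `NA` for a coefficient-only input). When the quadratic
#'   term is not positive, returns `convex = FALSE` with a `diagnosis`
#'   message instead of a vertex.
#' @export
find_extremum_week <- function(fit, n_sim = 2000L, seed = 1L,
                               conf_level = 0.95) {
  if (inherits(fit, "ldl_response_fit")) {
    co <- stats::coef(fit$fit)
    V <- stats::vcov(fit$fit)
  } else {
    co <- fit
    V <- NULL
  }
  need <- c("(Intercept)", ".t", ".t2")
  if (!all(need %in% names(co))) {
    stop("coefficients must include (Intercept), .t and .t2")
  }
  b0 <- co[["(Intercept)"]]; b1 <- co[[".t"]]; b2 <- co[[".t2"]]
  if (!is.finite(b2) || b2 <= 0) {
    return(list(convex = FALSE,
                diagnosis = "no interior extremum: quadratic coefficient is not positive"))
  }
  vx <- -b1 / (2 * b2)
  fy <- b0 + b1 * vx + b2 * vx^2
  ci_w <- ci_y <- c(NA_real_, NA_real_)
  if (!is.null(V)) {
    set.seed(seed)
    idx <- need
    draws <- MASS::mvrnorm(n_sim, co[idx], V[idx, idx])
    ok <- draws[, ".t2"] > 0
    vxs <- -draws[ok, ".t"] / (2 * draws[ok, ".t2"])
    fys <- draws[ok, "(Intercept)"] + draws[ok, ".t"] * vxs +
      draws[ok, ".t2"] * vxs^2
    alpha <- (1 - conf_level) / 2
    ci_w <- unname(stats::quantile(vxs / 7, c(alpha, 1 - alpha)))
    ci_y <- unname(stats::quantile(fys, c(alpha, 1 - alpha)))
  }
  list(convex = TRUE, vertex_days = vx, vertex_week = vx / 7, fitted_y = fy,
       ci_week = ci_w, ci_y = ci_y)
}

#' Mean LDL-c change by adherence category and follow-up time bin
#'
#' Joins first-year trajectories to adherence categories and summarizes the
#' change ratio per category and per follow-up-time bin, in the style of a
#' binned response plot: n, mean Y, and mean percentage reduction
#' `100 * (1 - mean Y)`.
#'
#' @param trajectories Year-1 trajectory table with `patient_id`, `y_ratio`
#'   and `visit_day_1` (the follow-up day).
#' @param adherence Adherence table with `patient_id` and `pdc1_category`.
#' @param bin_weeks Bin width in weeks (default 1).
#' @param max_weeks Truncate summaries at this many weeks (default 52).
#' @return List with `by_bin` (category x bin rows; empty bins reported
#'   with `n = 0` and `NA` means) and `by_category` (overall per-category
#'   summary).
#' @export
compare_pdc_groups <- function(trajectories, adherence, bin_weeks = 1,
                               max_weeks = 52) {
  d <- merge(trajectories[, c("patient_id", "y_ratio", "visit_day_1")],
             adherence[, c("patient_id", "pdc1_category")], by = "patient_id")
  d <- d[!is.na(d$pdc1_category), , drop = FALSE]
  d$week <- d$visit_day_1 / 7
  d <- d[d$week <= max_weeks, , drop = FALSE]
  d$bin <- floor(d$week / bin_weeks) * bin_weeks
  cats <- levels(d$pdc1_category)
  bins <- seq(0, max_weeks - bin_weeks, by = bin_weeks)
  grid <- expand.grid(pdc1_category = cats, bin_week = bins,
                      stringsAsFactors = FALSE)
  agg <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- d$y_ratio[d$pdc1_category == grid$pdc1_category[i] &
                       d$bin == grid$bin_week[i]]
    my <- if (length(sub)) mean(sub) else NA_real_
    data.frame(pdc1_category = grid$pdc1_category[i],
               bin_week = grid$bin_week[i], n = length(sub), mean_y = my,
               reduction_pct = 100 * (1 - my))
  })
  by_bin <- do.call(rbind, agg)
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    sub <- d$y_ratio[d$pdc1_category == cc]
    my <- if (length(sub)) mean(sub) else NA_real_
    data.frame(pdc1_category = cc, n = length(sub), mean_y = my,
               reduction_pct = 100 * (1 - my))
  }))
  list(by_bin = by_bin, by_category = by_cat)
}
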