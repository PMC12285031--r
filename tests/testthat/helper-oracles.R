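# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own code paths.

# per-day tablet tally: walk every day of the window and accumulate the
# tablets of prescriptions issued that day
pdc_oracle <- function(records, start, end) {
  days <- seq.int(start, end - 1L)
  tally <- numeric(length(days))
  for (i in seq_len(nrow(records))) {
    d <- records$date_day[i]
    if (d >= start && d < end) {
      j <- d - start + 1L
      tally[j] <- tally[j] + records$n_tablets[i]
    }
  }
  100 * sum(tally) / (end - start)
}

rx_table <- function(days, tablets = 28L, id = "P1") {
  n <- length(days)
  data.frame(patient_id = rep_len(id, n), date_day = as.integer(days),
             n_tablets = as.integer(rep_len(tablets, n)),
             drug = rep_len("atorvastatin", n), dose_band = rep_len("medium", n))
}

ldl_table <- function(days, values, id = "P1") {
  data.frame(patient_id = id, date_day = as.integer(days),
             ldl_mmol_l = values)
}

random_rx_case <- function() {
  n <- sample(0:25, 1L)
  rx <- data.frame(date_day = sample(-50:400, n, replace = TRUE),
                   n_tablets = sample(1:60, n, replace = TRUE))
  a <- sample(-30:100, 1L)
  b <- a + sample(1:400, 1L)
  list(rx = rx, start = a, end = b)
}

# weight_set wrapper around externally supplied weights
as_weight_set <- function(w) {
  structure(list(w = w, sw = w, method = "supplied", converged = TRUE,
                 truncation = NULL), class = "weight_set")
}

# a config with no confounding and no adherence feedback: exposures are
# exogenous, so weights should be trivial and naive OLS unbiased
null_confounding_config <- function(n, seed, ...) {
  sim_config(n_patients = n, seed = seed,
             conf_coefs = list(pdc = c(age = 0, female = 0, ldl0 = 0,
                                       education = 0),
                               lr = c(age = 0, female = 0, ldl0 = 0,
                                      education = 0)),
             feedback_coef = 0, ...)
}
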