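# Shared fixtures built in code.

# Minimal patient row for endpoint derivation
make_patient <- function(patient_id = "P1", death_day = NA, last_fu = 400,
                         collection_day = 0, ...) {
  data.frame(patient_id = patient_id, age = 65, sex = "F",
             tumor_type = "NSCLC", race = "Unknown", msi_high = FALSE,
             mtc = 0.5, panel_mb = 1.1,
             tmb = 5, pd1 = 2, pdl1 = 3, top2a = 5, adam12 = 4,
             collection_day = collection_day, death_day = death_day,
             last_followup_day = last_fu, prior_io = FALSE,
             in_discovery = FALSE, in_prior_validation = FALSE,
             stringsAsFactors = FALSE, ...)
}

make_line <- function(patient_id = "P1", line_number = 1, start_day = 0,
                      stop_day = NA, agents = "pembrolizumab") {
  data.frame(patient_id = patient_id, line_number = line_number,
             start_day = start_day, stop_day = stop_day, agents = agents,
             stringsAsFactors = FALSE)
}

# hand-coded Efron partial log-likelihood for a single covariate,
# independent of the fitting path: used as a grid/optimize oracle
efron_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_set <- which(time == t & event == 1)
    r_set <- which(time >= t)
    m <- length(d_set)
    eta_r <- sum(exp(beta * x[r_set]))
    eta_d <- sum(exp(beta * x[d_set]))
    ll <- ll + beta * sum(x[d_set])
    for (j in seq_len(m))
      ll <- ll - log(eta_r - (j - 1) / m * eta_d)
  }
  ll
}

# random tiny survival dataset with ties (integer times) and a binary
# covariate, constrained to be informative for a one-parameter Cox fit
random_tiny_cox_data <- function(max_n = 8) {
  repeat {
    n <- sample(4:max_n, 1)
    d <- data.frame(time = sample(1:5, n, replace = TRUE),
                    event = rbinom(n, 1, 0.7),
                    x = rbinom(n, 1, 0.5))
    if (sum(d$event) >= 2 && length(unique(d$x)) == 2 &&
        length(unique(d$x[d$event == 1])) == 2)
      return(d)
  }
}
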