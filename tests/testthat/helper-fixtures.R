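# small, fast simulation configurations used across tests:
# deterministic crossing of threshold1 after 1000 steps, threshold2 after 2000
fast_single <- function(n = 400, seed = 1, noise_var = 5, ...) {
  wiener_config(n_individuals = n, dt = 2, drift_mean = 1,
                noise_var = noise_var, x0_factor = 4000,
                threshold1 = 2000, threshold2 = 0, seed = seed, ...)
}

fast_two <- function(n = 400, seed = 1, w = 0, ...) {
  wiener_config(n_individuals = n, dt = 2, drift_mean = 1,
                noise_var = 5, x0_factor = 4000,
                threshold1 = 2000, threshold2 = 0,
                architecture = "two_process", coupling_w = w,
                seed = seed, ...)
}

tiny_table <- function(v, w = NA_real_, d, group = "g", batch = "b",
                       v_cens = FALSE, d_cens = FALSE) {
  n <- length(v)
  event_table(data.frame(
    individual_id = sprintf("id%03d", seq_len(n)),
    group = rep_len(group, n), batch = rep_len(batch, n),
    vmc_time = v, vmc_censored = rep_len(v_cens, n),
    wmc_time = rep_len(w, n), wmc_censored = ifelse(is.na(rep_len(w, n)), NA, FALSE),
    death_time = d, death_censored = rep_len(d_cens, n),
    stringsAsFactors = FALSE))
}

# inverse-Gaussian CDF from the package's closed-form survival
ig_cdf <- function(q, mu, lambda) {
  1 - survival_value("inverse_gaussian", c(mu = mu, lambda = lambda), q)
}
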