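# shared fixtures built in code

default_induction <- function() induction_model(XP = 1, t_half_ind = 43, n = 4)

# noise-free ratio series for one site directly from the forward model
noise_free_series <- function(t_half, kacA = 1, XCC = 0.9, B = 0.15,
                              induction = default_induction(),
                              times = cc_timepoints(), site_id = "s1") {
  truth <- list(site_id = site_id, kd_true = log(2) / t_half,
                kacA_true = kacA, XCC_true = XCC, B_true = B, noise_cv = 0)
  simulate_site_ratio_series(truth, induction, times, seed = 1)
}

# tiny deterministic count matrices
toy_counts <- function(vals, times = c(0, 10), ids = c("a", "b")) {
  m <- matrix(vals, nrow = length(ids))
  colnames(m) <- sprintf("t_%g", times)
  dplyr::bind_cols(tibble::tibble(site_id = ids), tibble::as_tibble(m))
}
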