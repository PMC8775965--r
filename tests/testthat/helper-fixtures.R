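# shared fixtures, built in code

quick_protocol <- function(...) acq_protocol(...)

# a clean (noise-free) AIF on the default frame grid
clean_aif <- function(protocol = acq_protocol(), subject_id = "s1") {
  generate_aif(subject_id, protocol, noise_model(aif_variability = 0), seed = 1)
}

# small two-group phenotype table for fast fitting tests
small_groups <- function(n_per_group = 6L) {
  tibble::tibble(
    name = c("hi-perm", "lo-perm"),
    ktrans_logmean = log(c(0.03, 0.003)),
    ktrans_logsd = c(0.3, 0.3),
    vp_mean = c(0.03, 0.01),
    vp_sd = c(0.01, 0.005),
    vp_zero_prob = c(0, 0),
    egfr_conc = c(0, 0),
    n_subjects = c(n_per_group, n_per_group)
  )
}

quick_settings <- function(...) fit_settings(n_starts = 1, maxit = 400, ...)
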