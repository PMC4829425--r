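# Shared fixtures built in code.

default_cal <- function() calibration_set(i_D = 50, i_A = 50, beta_D = 0.30,
                                          beta_A = 0.10, G_F = 2.0)

# Small Monte-Carlo settings for unit tests (acceptance tests use larger).
small_mc <- function(seed = 1L) proximity_mc_settings(n_donors = 2000L,
                                                      n_replicates = 3L,
                                                      seed = seed)

# Generate, quantify and (optionally) proximity-correct a synthetic set in
# one call; without a proximity model E_D = E.
synth_corrected <- function(cfg, model = NULL) {
  sim <- if (cfg$constitutive) generate_constitutive_vesicles(cfg) else
    generate_equilibrium_vesicles(cfg)
  tab <- quantify_vesicles(sim$intensities, cfg$calibration)
  if (is.null(model)) {
    tab$E_prox <- 0
    tab$E_D <- tab$E
  } else {
    tab <- correct_fret(tab, model)
  }
  list(records = tab, truth = sim$truth)
}

# Independent mass-action oracle: solve M + 2 K M^2 = T for the monomer
# concentration numerically and return the dimeric fraction 1 - M/T.
dimeric_fraction_oracle <- function(T, K) {
  vapply(T, function(Ti) {
    if (Ti == 0) return(0)
    M <- uniroot(function(M) M + 2 * K * M^2 - Ti, c(0, Ti),
                 tol = 1e-14)$root
    1 - M / Ti
  }, numeric(1))
}
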