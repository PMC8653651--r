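# Shared fixtures: all synthetic, built in code at test time.

# Reduced-axis dataset with an informative band planted in a known window.
planted_set <- function(seed = 1, n_points = 747, window = c(1150, 1350)) {
  wn <- wavenumber_axis(n_points)
  pp <- planted_profiles(wn, window)
  set <- simulate_spectra(default_design(), target = pp$target,
                          adulterant = pp$adulterant,
                          noise = noise_model(seed = seed), wavenumber = wn)
  list(set = set, window = window,
       win_idx = which(wn >= window[1] & wn <= window[2]))
}

# Small random regression problem.
small_xy <- function(seed = 1, n = 30, p = 50) {
  set.seed(seed)
  list(x = matrix(stats::rnorm(n * p), n, p), y = stats::rnorm(n))
}

# A tiny labelled spectra set for IO and split tests.
tiny_set <- function(seed = 1, n_points = 101) {
  simulate_spectra(mixture_design(c(20, 50, 80), 4, 4, 4),
                   noise = noise_model(seed = seed),
                   wavenumber = wavenumber_axis(n_points))
}
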