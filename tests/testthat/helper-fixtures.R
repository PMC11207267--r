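# Shared fixtures, built in code at test time.

# Trajectory with fully controlled spherical series (defaults: stationary).
make_traj <- function(n = 64, phi = 0.1, theta = 0.2, r = 100, size = 10,
                      label = "other_bird", id = "fx") {
  t <- (seq_len(n) - 1) / 16
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  trajectory(id, t, rep_n(phi), rep_n(theta), rep_n(r), rep_n(size), label)
}

# Small planted two-class Gaussian feature set with 78 named columns.
make_planted <- function(n_rows = 200, n_informative = 5, effect = 3,
                         seed = 42) {
  planted_feature_matrix(n_rows, n_informative, effect, seed)
}

# Normalised feature matrix + binary bird label from a small simulation.
make_stage1_data <- function(n_aero = 30, n_bird = 60, n_raptor = 12,
                             seed = 9) {
  trajs <- simulate_dataset(c(aeroplane = n_aero, other_bird = n_bird,
                              big_raptor = n_raptor), seed = seed)
  fm <- extract_feature_matrix(trajs)
  norm <- suppressWarnings(fit_normalization(fm$X))
  list(X = apply_normalization(norm, fm$X),
       y = as.integer(fm$label != "aeroplane"), label = fm$label,
       trajs = trajs)
}
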