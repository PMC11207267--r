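# Independent straight-line re-computation of all 78 features, written as
# plain loops against the documented definitions; used as the oracle for
# extract_features on an arbitrary fixture.
oracle_features <- function(traj, edges = seq(0, 900, 100)) {
  per <- 32L
  nw <- length(traj$t) %/% per
  th <- traj$theta
  for (i in 2:length(th)) {               # unwrap azimuth
    while (th[i] - th[i - 1] > pi) th[i:length(th)] <- th[i:length(th)] - 2 * pi
    while (th[i] - th[i - 1] < -pi) th[i:length(th)] <- th[i:length(th)] + 2 * pi
  }
  wphi <- wth <- aphi <- ath <- mr <- numeric(nw)
  for (k in seq_len(nw)) {
    i <- ((k - 1) * per + 1):(k * per)
    span <- traj$t[i[per]] - traj$t[i[1]]
    wphi[k] <- (traj$phi[i[per]] - traj$phi[i[1]]) / span
    wth[k] <- (th[i[per]] - th[i[1]]) / span
    s1 <- 0; s2 <- 0
    for (j in 1:(per - 1)) {
      s1 <- s1 + abs(traj$phi[i[j + 1]] - traj$phi[i[j]]) * traj$r[i[j]]
      s2 <- s2 + abs(th[i[j + 1]] - th[i[j]]) * traj$r[i[j]] *
        cos(traj$phi[i[j]])
    }
    aphi[k] <- s1; ath[k] <- s2
    mr[k] <- mean(traj$r[i])
  }
  hist9 <- function(v, lo, hi) {
    counts <- numeric(9)
    for (x in v) {
      b <- floor((x - lo) / ((hi - lo) / 9)) + 1
      counts[min(9, max(1, b))] <- counts[min(9, max(1, b))] + 1
    }
    100 * counts / length(v)
  }
  binavg <- function(v, d) {
    out <- numeric(9)
    for (b in 1:9) {
      sel <- d >= edges[b] & (if (b == 9) d <= edges[10] else d < edges[b + 1])
      if (any(sel)) out[b] <- mean(v[sel])
    }
    out
  }
  c(hist9(wphi, -0.01, 0.01), hist9(wth, -0.03, 0.03),
    binavg(wphi, mr), binavg(wth, mr),
    binavg(traj$phi, traj$r), binavg(traj$size_px, traj$r),
    binavg(aphi, mr), binavg(ath, mr),
    var(wphi), var(wth), var(traj$phi), var(traj$size_px),
    var(aphi), var(ath))
}

test_that("window quantities recover a linear elevation drift exactly", {
  n <- 128
  t <- (seq_len(n) - 1) / 16
  traj <- make_traj(n, phi = 0.005 * t, theta = 0, r = 100)
  ws <- window_quantities(traj)
  expect_equal(nrow(ws$windows), 4)
  expect_equal(ws$windows$w_phi, rep(0.005, 4), tolerance = 1e-12)
  expect_equal(ws$windows$mean_r, rep(100, 4))
})

test_that("arc path length of a single elevation step is |dphi| * r", {
  phi <- c(rep(0, 10), rep(0.01, 22))   # one 0.01-rad step at r = 100 m
  traj <- make_traj(32, phi = phi, theta = 0, r = 100)
  ws <- window_quantities(traj)
  expect_equal(ws$windows$arc_phi, 1.0)
})

test_that("a zero-net sinusoidal window has w_phi ~ 0 but positive arc", {
  t <- (0:31) / 16
  phi <- 0.01 * sin(2 * pi * t * 16 / 31)  # full cycle, endpoints equal
  traj <- make_traj(32, phi = phi, theta = 0, r = 200)
  ws <- window_quantities(traj)
  expect_equal(ws$windows$w_phi, 0, tolerance = 1e-9)
  # numeric sum oracle on the same 32 samples
  expect_equal(ws$windows$arc_phi, sum(abs(diff(phi)) * 200))
  expect_gt(ws$windows$arc_phi, 0)
})

test_that("azimuth quantities are unwrapped across +-pi and scaled by r cos(phi)", {
  n <- 64
  # azimuth drifting through the +-pi seam at 0.02 rad/s
  theta_true <- seq(pi - 0.02, by = 0.02 / 16, length.out = n)
  theta <- ((theta_true + pi) %% (2 * pi)) - pi
  traj <- make_traj(n, phi = 0.5, theta = theta, r = 100)
  ws <- window_quantities(traj)
  expect_equal(ws$windows$w_theta, rep(0.02, 2), tolerance = 1e-9)
  expect_equal(ws$windows$arc_theta,
               rep(sum(rep(0.02 / 16, 31)) * 100 * cos(0.5), 2),
               tolerance = 1e-9)
})

test_that("velocity histograms centre, clip, and stay uniform under uniform input", {
  expect_equal(velocity_histogram(rep(0, 50), -0.01, 0.01),
               c(0, 0, 0, 0, 100, 0, 0, 0, 0))
  expect_equal(velocity_histogram(c(-0.02, 0.02), -0.01, 0.01),
               c(50, 0, 0, 0, 0, 0, 0, 0, 50))
  set.seed(5)
  h <- velocity_histogram(runif(1000, -0.01, 0.01), -0.01, 0.01)
  expect_true(all(abs(h - 100 / 9) < 3))
  expect_equal(sum(h), 100)
  expect_error(velocity_histogram(numeric(0)), "empty")
})

test_that("distance-bin averages match a brute-force group-by oracle", {
  expect_equal(distance_bin_average(rep(7, 5), rep(150, 5)),
               c(0, 7, 0, 0, 0, 0, 0, 0, 0))
  centres <- seq(50, 850, 100)
  expect_equal(distance_bin_average(centres, centres), centres)

  set.seed(8)
  v <- rnorm(200); d <- runif(200, -50, 1000)
  got <- distance_bin_average(v, d)
  edges <- default_distance_edges()
  for (b in 1:9) {
    sel <- d >= edges[b] & (if (b == 9) d <= edges[10] else d < edges[b + 1])
    expect_equal(got[b], if (any(sel)) mean(v[sel]) else 0)
  }
  expect_error(distance_bin_average(1:3, 1:4), "lengths")
})

test_that("extract_features yields the canonical 78-vector with valid blocks", {
  traj <- simulate_track(default_archetypes()$other_bird, 6, seed = 4)
  f <- extract_features(traj)
  expect_length(f, 78)
  expect_identical(names(f), feature_names())
  expect_equal(sum(f[1:9]), 100, tolerance = 1e-9)
  expect_equal(sum(f[10:18]), 100, tolerance = 1e-9)
  expect_true(all(f[grepl("^var_", names(f))] >= 0))
  expect_true(all(f[grepl("^avg_arc", names(f))] >= 0))
  expect_identical(f, extract_features(traj))   # deterministic
})

test_that("a stationary hover gives zero variances and centred histograms", {
  f <- extract_features(make_traj(64))
  expect_true(all(f[grepl("^var_", names(f))] == 0))
  expect_equal(unname(f["hist_wphi_b5"]), 100)
  expect_equal(unname(f["hist_wtheta_b5"]), 100)
})

test_that("every feature matches the hand-coded oracle on a varied fixture", {
  n <- 128
  t <- (seq_len(n) - 1) / 16
  traj <- make_traj(
    n,
    phi = 0.2 + 0.05 * sin(2 * pi * 0.3 * t),
    theta = 0.5 * t / 10 + 0.02 * cos(2 * pi * 0.4 * t),
    r = seq(80, 870, length.out = n),
    size = pmax(1, round(2e5 / seq(80, 870, length.out = n))))
  expect_equal(unname(extract_features(traj)), oracle_features(traj),
               tolerance = 1e-12)
})

test_that("normalisation follows the per-group schemes with train-only statistics", {
  # zscore on {1, 3} gives -1, +1 under the sample sd
  X <- matrix(0, 2, 78, dimnames = list(NULL, feature_names()))
  X[, "var_wphi"] <- c(1, 3)
  X[, "avg_sizepx_d1"] <- c(0, 99)
  nm <- suppressWarnings(fit_normalization(X))
  Xn <- apply_normalization(nm, X)
  expect_equal(unname(Xn[, "var_wphi"]), c(-1, 1) / sqrt(2))

  # size rule: log10(1+x) then min-max using training extremes
  X3 <- matrix(1, 3, 78, dimnames = list(NULL, feature_names()))
  X3[, "avg_sizepx_d1"] <- c(0, 9, 99)
  nm3 <- suppressWarnings(fit_normalization(X3))
  expect_equal(unname(apply_normalization(nm3, X3)[, "avg_sizepx_d1"]),
               c(0, 0.5, 1))

  # histogram columns pass through untouched
  X3[, "hist_wphi_b1"] <- c(10, 20, 70)
  nm3b <- suppressWarnings(fit_normalization(X3))
  expect_equal(unname(apply_normalization(nm3b, X3)[, "hist_wphi_b1"]),
               c(10, 20, 70))
  expect_error(fit_normalization({X3[, "var_sizepx"] <- -1; X3}), "negative")
})

test_that("held-out rows are normalised with statistics from training only", {
  set.seed(31)
  Xtr <- matrix(rexp(20 * 78), 20, 78, dimnames = list(NULL, feature_names()))
  Xte <- matrix(rexp(10 * 78, 0.5), 10, 78,
                dimnames = list(NULL, feature_names()))
  nm <- fit_normalization(Xtr)
  Zte <- apply_normalization(nm, Xte)
  # two-pass oracle from the training matrix
  j <- which(feature_names() == "avg_wphi_d3")
  expect_equal(Zte[, j], (Xte[, j] - mean(Xtr[, j])) / sd(Xtr[, j]))
  js <- which(feature_names() == "var_sizepx")
  l <- log10(1 + Xtr[, js])
  expect_equal(Zte[, js],
               (log10(1 + Xte[, js]) - min(l)) / (max(l) - min(l)))
  # applying to the training matrix itself re-centres the zscore columns
  Ztr <- apply_normalization(nm, Xtr)
  zcols <- grepl("^(avg_(wphi|wtheta|phi|arcphi|arctheta)|var_)",
                 feature_names()) & !grepl("sizepx", feature_names())
  expect_lt(max(abs(colMeans(Ztr[, zcols]))), 1e-9)
  expect_lt(max(abs(apply(Ztr[, zcols], 2, sd) - 1)), 1e-9)
})

test_that("normalisation model survives a JSON round-trip", {
  set.seed(17)
  X <- matrix(rexp(10 * 78), 10, 78, dimnames = list(NULL, feature_names()))
  nm <- fit_normalization(X)
  path <- tempfile(fileext = ".json")
  save_normalization(nm, path)
  nm2 <- load_normalization(path)
  expect_equal(apply_normalization(nm2, X), apply_normalization(nm, X))
})
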