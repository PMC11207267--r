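#' Motion archetype of a simulated object class
#'
#' Describes how one class of flying object moves and appears: speed and
#' position ranges, a path type (`straight` constant-velocity flight,
#' `soaring_circle` horizontal circling with slow drift, `flap_oscillation`
#' straight flight with a vertical wing-beat sinusoid), an apparent size
#' model `size_px = round(size_k * (wingspan / r)^2)` clipped at 1 px, an
#' angular noise level, and a stereo range-quantisation constant
#' (`quant_fB` = focal length x baseline in m*px; ranges are recovered from
#' integer-rounded disparity, so the error grows with r^2 and distant large
#' objects get coarsely mislocalised).
#'
#' @param label Class label, or `NA` for the neutral archetype.
#' @param path `"straight"`, `"soaring_circle"` or `"flap_oscillation"`.
#' @param speed,distance,altitude Two-element ranges: airspeed (m/s),
#'   horizontal distance from the sensor (m), altitude (m).
#' @param circle_radius Soaring circle radius range (m).
#' @param osc_freq Wing-beat frequency (Hz, must stay below the 8 Hz
#'   Nyquist limit of 16 Hz sampling).
#' @param osc_amp Vertical oscillation amplitude (m).
#' @param wingspan Characteristic size (m).
#' @param angle_noise_sd Gaussian noise sd added to `phi` and `theta` (rad).
#' @param size_k Apparent-size constant (px * m^2 / m^2).
#' @param quant_fB Range-quantisation constant (m*px); 0 disables it.
#' @return An object of class `class_archetype`.
#' @export
class_archetype <- function(label, path = c("straight", "soaring_circle",
                                            "flap_oscillation"),
                            speed, distance, altitude,
                            circle_radius = c(20, 50), osc_freq = 0,
                            osc_amp = 0, wingspan = 1,
                            angle_noise_sd = 2e-4, size_k = 1e6,
                            quant_fB = 4000) {
  path <- match.arg(path)
  chk <- function(r) length(r) == 2L && all(r > 0) && r[1] <= r[2]
  if (!chk(speed) || !chk(distance) || !chk(altitude) || !chk(circle_radius))
    stop("archetype ranges must be positive and ordered")
  if (osc_freq >= 8) stop("oscillation frequency must stay below 8 Hz")
  structure(list(label = label, path = path, speed = speed,
                 distance = distance, altitude = altitude,
                 circle_radius = circle_radius, osc_freq = osc_freq,
                 osc_amp = osc_amp, wingspan = wingspan,
                 angle_noise_sd = angle_noise_sd, size_k = size_k,
                 quant_fB = quant_fB),
            class = "class_archetype")
}

#' Default archetypes for the three object classes
#'
#' Aeroplanes fly straight and fast (50–200 m/s) at 800–3000 m with a large
#' apparent size; big raptors soar in 20–50 m circles at 10–20 m/s, 100–600 m
#' out; other (common) birds fly 8–15 m/s with a 3 Hz wing-beat oscillation
#' at 50–400 m. These are engineering choices emulating the qualitative
#' motion patterns of each class, not estimates of any real survey's
#' distributions.
#'
#' @return Named list of three [class_archetype] objects.
#' @export
default_archetypes <- function() {
  list(
    aeroplane = class_archetype("aeroplane", "straight",
                                speed = c(50, 200), distance = c(800, 3000),
                                altitude = c(300, 1000), wingspan = 30),
    big_raptor = class_archetype("big_raptor", "soaring_circle",
                                 speed = c(10, 20), distance = c(100, 600),
                                 altitude = c(30, 250),
                                 circle_radius = c(20, 50), wingspan = 2),
    other_bird = class_archetype("other_bird", "flap_oscillation",
                                 speed = c(8, 15), distance = c(50, 400),
                                 altitude = c(10, 120), osc_freq = 3,
                                 osc_amp = 0.3, wingspan = 0.45))
}

#' Neutral archetype used for the separability mixture
#'
#' A single "generic flyer" whose parameter ranges straddle the three class
#' archetypes. At separability 0 every class is simulated from this
#' archetype, so the classes are indistinguishable by construction.
#'
#' @return A [class_archetype].
#' @export
neutral_archetype <- function() {
  class_archetype(NA_character_, "flap_oscillation", speed = c(10, 60),
                  distance = c(100, 1000), altitude = c(20, 400),
                  osc_freq = 1.5, osc_amp = 0.3, wingspan = 3)
}

#' Simulate one flight trajectory
#'
#' Integrates a Cartesian path at 16 Hz according to the archetype's path
#' type, converts to spherical coordinates, adds angular noise, applies the
#' disparity-rounding range quantisation, and derives the apparent pixel
#' size from the true range. Identical seeds give bit-identical tracks.
#'
#' @param arch A [class_archetype].
#' @param duration Track length in seconds (>= 2).
#' @param seed Integer seed.
#' @param track_id Identifier for the resulting trajectory.
#' @param label Label to assign (defaults to the archetype's).
#' @return A [trajectory].
#' @export
simulate_track <- function(arch, duration = 8, seed = 1L,
                           track_id = "sim", label = arch$label) {
  stopifnot(inherits(arch, "class_archetype"))
  if (duration < 2) stop("duration must be at least 2 s (one window)")
  set.seed(seed)
  dt <- 1 / 16
  n <- floor(duration / dt)
  t <- (seq_len(n) - 1L) * dt
  rho <- runif(1, arch$distance[1], arch$distance[2])
  az <- runif(1, -pi, pi)
  z0 <- runif(1, arch$altitude[1], arch$altitude[2])
  v <- runif(1, arch$speed[1], arch$speed[2])
  p0 <- c(rho * cos(az), rho * sin(az), z0)
  if (arch$path == "soaring_circle") {
    R <- runif(1, arch$circle_radius[1], arch$circle_radius[2])
    om <- v / R
    ph0 <- runif(1, 0, 2 * pi)
    ddir <- runif(1, 0, 2 * pi)
    dh <- runif(1, 0, 2)          # slow horizontal drift of the thermal
    vz <- runif(1, 0.2, 1)        # thermal climb
    x <- p0[1] + R * cos(om * t + ph0) + dh * cos(ddir) * t
    y <- p0[2] + R * sin(om * t + ph0) + dh * sin(ddir) * t
    z <- p0[3] + vz * t
  } else {
    psi <- runif(1, 0, 2 * pi)
    vz <- if (arch$path == "straight") 0 else runif(1, -1, 1)
    x <- p0[1] + v * cos(psi) * t
    y <- p0[2] + v * sin(psi) * t
    z <- p0[3] + vz * t
    if (arch$path == "flap_oscillation" && arch$osc_amp > 0) {
      ph0 <- runif(1, 0, 2 * pi)
      z <- z + arch$osc_amp * sin(2 * pi * arch$osc_freq * t + ph0)
    }
  }
  z <- pmax(z, 1)
  sph <- cartesian_to_spherical(data.frame(x = x, y = y, z = z))
  r_true <- sph$r
  phi <- sph$phi + rnorm(n, 0, arch$angle_noise_sd)
  theta <- sph$theta + rnorm(n, 0, arch$angle_noise_sd)
  phi <- pmin(pi / 2, pmax(-pi / 2, phi))
  theta <- ((theta + pi) %% (2 * pi)) - pi
  r <- if (arch$quant_fB > 0) {
    arch$quant_fB / pmax(1, round(arch$quant_fB / r_true))
  } else r_true
  size_px <- pmax(1, round(arch$size_k * (arch$wingspan / r_true)^2))
  trajectory(track_id, t, phi, theta, r, size_px, label)
}

#' Simulate a labelled synthetic dataset
#'
#' Generates the requested number of tracks per class. Each track's seed is
#' derived from the master seed, so the whole dataset is bit-reproducible.
#' `separability` mixes class archetypes with the [neutral_archetype()]:
#' each track is drawn from its class archetype with probability
#' `separability` and from the neutral archetype otherwise, so 1 gives the
#' full class structure and 0 gives identical distributions for all labels.
#'
#' @param counts Named integer vector with entries `aeroplane`,
#'   `other_bird`, `big_raptor` (any may be 0).
#' @param separability Mixing weight in `[0, 1]`.
#' @param duration_range Track duration range in seconds.
#' @param seed Master seed.
#' @param archetypes List of class archetypes (see [default_archetypes()]).
#' @return List of labelled [trajectory] objects.
#' @export
simulate_dataset <- function(counts = c(aeroplane = 288, other_bird = 604,
                                        big_raptor = 108),
                             separability = 1, duration_range = c(4, 16),
                             seed = 1L,
                             archetypes = default_archetypes()) {
  stopifnot(all(counts >= 0), sum(counts) >= 1,
            separability >= 0, separability <= 1)
  labels <- rep(names(counts), counts)
  n <- length(labels)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  durs <- runif(n, duration_range[1], duration_range[2])
  use_class <- runif(n) < separability
  neutral <- neutral_archetype()
  lapply(seq_len(n), function(i) {
    arch <- if (use_class[i]) archetypes[[labels[i]]] else neutral
    simulate_track(arch, durs[i], seeds[i],
                   track_id = sprintf("sim_%04d", i), label = labels[i])
  })
}

#' Class counts mirroring the reference survey proportions
#'
#' Scales the aeroplane : other-bird : big-raptor shape 3536 : 7423 : 1325
#' (about 1 : 2.1 : 0.37) to a total of `n_total` tracks.
#'
#' @param n_total Total number of tracks.
#' @return Named integer vector of per-class counts.
#' @export
reference_counts <- function(n_total = 1000L) {
  base <- c(aeroplane = 3536, other_bird = 7423, big_raptor = 1325)
  counts <- round(n_total * base / sum(base))
  counts[1] <- n_total - sum(counts[-1])
  counts
}

#' Convert a spherical trajectory to a pixel-level raw track
#'
#' Inverse stereo projection through a [stereo_geometry]; used to exercise
#' the pixel-domain preprocessing on simulated data. Because a single
#' pinhole rig only sees objects in front of it, the world is first rotated
#' in azimuth by `boresight` (default: the circular-mean azimuth of the
#' track, i.e. the camera is aimed at the object). The rotation leaves
#' `phi`, `r` and every azimuth difference — hence every extracted feature —
#' unchanged. A track sweeping more than a half-space around the sensor
#' cannot be seen by one rig and raises an error.
#'
#' @param traj A [trajectory].
#' @param geometry A [stereo_geometry].
#' @param boresight Azimuth of the camera's optical axis in radians.
#' @return A [raw_track].
#' @export
trajectory_to_raw <- function(traj, geometry = stereo_geometry(),
                              boresight = atan2(mean(sin(traj$theta)),
                                                mean(cos(traj$theta)))) {
  cart <- spherical_to_cartesian(data.frame(phi = traj$phi,
                                            theta = traj$theta - boresight,
                                            r = traj$r))
  px <- project_stereo(cart, geometry)
  det <- cbind(data.frame(t = traj$t), px,
               data.frame(size_px = traj$size_px))
  raw_track(traj$track_id, det, traj$label)
}

#' Planted feature matrix for selection benchmarks
#'
#' A 78-column Gaussian matrix in which `n_informative` randomly placed
#' columns are shifted by `effect` standard deviations in class 1; the rest
#' are pure noise. The ground-truth informative set is returned so filter
#' and wrapper selectors can be scored on recovery.
#'
#' @param n_rows Number of rows (split evenly between the classes).
#' @param n_informative Number of informative columns, in `[1, 78]`.
#' @param effect Class shift in sd units.
#' @param seed Integer seed.
#' @return List with `X` (matrix with [feature_names()] columns), `y`
#'   (0/1 vector) and `informative` (sorted column indices).
#' @export
planted_feature_matrix <- function(n_rows = 500L, n_informative = 5L,
                                   effect = 3, seed = 1L) {
  if (n_informative < 1L || n_informative > 78L)
    stop("n_informative must lie in [1, 78]")
  stopifnot(n_rows >= 2L)
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n_rows)
  X <- matrix(rnorm(n_rows * 78L), n_rows, 78L,
              dimnames = list(NULL, feature_names()))
  informative <- sort(sample.int(78L, n_informative))
  X[y == 1L, informative] <- X[y == 1L, informative] + effect
  list(X = X, y = y, informative = informative)
}
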