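#' Canonical names of the 78 track features
#'
#' The feature scheme is built from four physical quantities measured on a
#' spherical trajectory — elevation `phi`, angular velocities `wphi`/`wtheta`
#' over 2-s windows, apparent pixel size `sizepx`, and arc path lengths
#' `arcphi`/`arctheta` per window — arranged as:
#' * 9-bin percentage histograms of each angular velocity (18 values),
#' * averages of six quantities within nine distance intervals (54 values),
#' * one variance per quantity (6 values).
#'
#' @return Character vector of length 78, the fixed column order of every
#'   feature matrix produced by the package.
#' @export
feature_names <- function() {
  c(sprintf("hist_wphi_b%d", 1:9),
    sprintf("hist_wtheta_b%d", 1:9),
    sprintf("avg_wphi_d%d", 1:9),
    sprintf("avg_wtheta_d%d", 1:9),
    sprintf("avg_phi_d%d", 1:9),
    sprintf("avg_sizepx_d%d", 1:9),
    sprintf("avg_arcphi_d%d", 1:9),
    sprintf("avg_arctheta_d%d", 1:9),
    c("var_wphi", "var_wtheta", "var_phi", "var_sizepx",
      "var_arcphi", "var_arctheta"))
}

#' Default distance-interval edges
#'
#' Ten ascending edges defining nine 100-m intervals over 0–900 m. The
#' interval count is fixed by the feature scheme; the edges are
#' configuration (the default spans typical bird detection range and the
#' nearer aeroplane passes).
#'
#' @return Numeric vector of 10 edges in meters.
#' @export
default_distance_edges <- function() seq(0, 900, by = 100)

unwrap_angle <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1] + c(0, cumsum(d))
}

# variance of a possibly length-1 vector (n-1 denominator; 0 when undefined)
safe_var <- function(v) if (length(v) < 2L) 0 else stats::var(v)

#' Per-window angular quantities of a trajectory
#'
#' Cuts the track into consecutive non-overlapping 2-s windows (32 samples at
#' 16 Hz; a trailing partial window is dropped) and computes, per window:
#' * `w_phi`, `w_theta`: net angular rates, (last - first angle) divided by
#'   the window's time span, rad/s (azimuth unwrapped across +-pi first), so
#'   a linearly drifting angle yields its exact rate;
#' * `arc_phi`: metric path travelled in elevation,
#'   `sum(|d phi_i| * r_i)`, meters;
#' * `arc_theta`: metric azimuthal path, `sum(|d theta_i| * r_i * cos(phi_i))`;
#' * `mean_r`: mean range, used to place the window in a distance interval.
#'
#' @param traj A [trajectory].
#' @param window_s Window length in seconds (default 2).
#' @return An object of class `window_series`: list with a `windows`
#'   data.frame (`t_start`, `w_phi`, `w_theta`, `arc_phi`, `arc_theta`,
#'   `mean_r`) and a `samples` data.frame (`phi`, `size_px`, `r`).
#' @export
window_quantities <- function(traj, window_s = 2) {
  stopifnot(inherits(traj, "trajectory"), window_s > 0)
  dt <- stats::median(diff(traj$t))
  per <- max(2L, round(window_s / dt))
  n <- length(traj$t)
  nw <- n %/% per
  if (nw < 1L) stop("track too short: no complete ", window_s, "-s window")
  theta_u <- unwrap_angle(traj$theta)
  win <- data.frame(t_start = numeric(nw), w_phi = numeric(nw),
                    w_theta = numeric(nw), arc_phi = numeric(nw),
                    arc_theta = numeric(nw), mean_r = numeric(nw))
  for (k in seq_len(nw)) {
    i <- ((k - 1L) * per + 1L):(k * per)
    phi <- traj$phi[i]; th <- theta_u[i]; r <- traj$r[i]
    m <- per - 1L
    span <- traj$t[i[per]] - traj$t[i[1L]]
    win$t_start[k] <- traj$t[i[1L]]
    win$w_phi[k] <- (phi[per] - phi[1L]) / span
    win$w_theta[k] <- (th[per] - th[1L]) / span
    win$arc_phi[k] <- sum(abs(diff(phi)) * r[seq_len(m)])
    win$arc_theta[k] <- sum(abs(diff(th)) * r[seq_len(m)] *
                              cos(phi[seq_len(m)]))
    win$mean_r[k] <- mean(r)
  }
  structure(list(windows = win,
                 samples = data.frame(phi = traj$phi, size_px = traj$size_px,
                                      r = traj$r)),
            class = "window_series")
}

#' Clipped percentage histogram of angular velocities
#'
#' Nine equal-width bins over `[lo, hi]`; values outside the range are
#' counted in the first/last bin so the histogram always totals 100%.
#'
#' @param values Numeric vector (rad/s), non-empty.
#' @param lo,hi Histogram range; the scheme uses +-0.01 rad/s for `w_phi` and
#'   +-0.03 rad/s for `w_theta`.
#' @param nbins Number of bins (9).
#' @return Numeric vector of `nbins` percentages summing to 100.
#' @export
velocity_histogram <- function(values, lo = -0.01, hi = 0.01, nbins = 9L) {
  if (!length(values)) stop("empty input to velocity_histogram")
  stopifnot(hi > lo, nbins >= 1L)
  width <- (hi - lo) / nbins
  idx <- floor((values - lo) / width) + 1L
  idx <- pmin(nbins, pmax(1L, idx))
  100 * tabulate(idx, nbins) / length(values)
}

#' Mean of a quantity within each distance interval
#'
#' Intervals are left-closed right-open, the last right-closed. Samples
#' outside the edges are ignored; empty intervals yield 0 (a neutral fill so
#' downstream z-scoring never sees missing values).
#'
#' @param values Numeric vector.
#' @param distances Paired ranges in meters, same length.
#' @param edges 10 ascending edges defining 9 intervals.
#' @return Numeric vector of 9 interval means.
#' @export
distance_bin_average <- function(values, distances,
                                 edges = default_distance_edges()) {
  if (length(values) != length(distances))
    stop("values and distances have different lengths")
  stopifnot(length(edges) == 10L, all(diff(edges) > 0))
  idx <- findInterval(distances, edges, rightmost.closed = TRUE)
  out <- numeric(9L)
  inside <- idx >= 1L & idx <= 9L
  if (any(inside)) {
    s <- vapply(split(values[inside], idx[inside]), mean, numeric(1))
    out[as.integer(names(s))] <- s
  }
  out
}

#' Extract the canonical 78-feature vector from a trajectory
#'
#' Assembles, in the fixed order of [feature_names()]: the two 9-bin angular
#' velocity histograms; distance-binned averages of `w_phi`, `w_theta`,
#' `phi`, `size_px`, `arc_phi`, `arc_theta` (window quantities binned by
#' window mean range, per-sample quantities by sample range); and the six
#' sample variances (n-1 denominator).
#'
#' @param traj A [trajectory].
#' @param edges Distance-interval edges (see [default_distance_edges()]).
#' @param window_s Window length in seconds.
#' @param hist_range_phi,hist_range_theta Histogram ranges in rad/s.
#' @return Named numeric vector of length 78.
#' @export
extract_features <- function(traj, edges = default_distance_edges(),
                             window_s = 2,
                             hist_range_phi = c(-0.01, 0.01),
                             hist_range_theta = c(-0.03, 0.03)) {
  ws <- window_quantities(traj, window_s)
  w <- ws$windows; s <- ws$samples
  out <- c(
    velocity_histogram(w$w_phi, hist_range_phi[1], hist_range_phi[2]),
    velocity_histogram(w$w_theta, hist_range_theta[1], hist_range_theta[2]),
    distance_bin_average(w$w_phi, w$mean_r, edges),
    distance_bin_average(w$w_theta, w$mean_r, edges),
    distance_bin_average(s$phi, s$r, edges),
    distance_bin_average(s$size_px, s$r, edges),
    distance_bin_average(w$arc_phi, w$mean_r, edges),
    distance_bin_average(w$arc_theta, w$mean_r, edges),
    safe_var(w$w_phi), safe_var(w$w_theta), safe_var(s$phi),
    safe_var(s$size_px), safe_var(w$arc_phi), safe_var(w$arc_theta))
  names(out) <- feature_names()
  out
}

#' Feature matrix for a list of trajectories
#'
#' @param trajs List of [trajectory] objects.
#' @param ... Passed to [extract_features()].
#' @return List with `X` (n x 78 matrix, rownames = track ids) and `label`
#'   (factor of track labels).
#' @export
extract_feature_matrix <- function(trajs, ...) {
  X <- t(vapply(trajs, extract_features, numeric(78L), ...))
  rownames(X) <- vapply(trajs, `[[`, character(1), "track_id")
  list(X = X, label = factor(vapply(trajs, `[[`, character(1), "label"),
                             levels = TRACK_LABELS))
}

feature_scheme <- function(features = feature_names()) {
  scheme <- rep("zscore", length(features))
  scheme[grepl("^hist_", features)] <- "none"
  scheme[grepl("sizepx", features)] <- "logminmax"
  scheme
}

#' Fit a per-feature normalisation model
#'
#' Scheme assignment follows the feature scheme: histogram bins are already
#' percentages and stay untouched; every variance and every distance-binned
#' average of the angular quantities is z-scored; the size-derived features
#' (`avg_sizepx_*`, `var_sizepx`) are `log10(1 + x)`-transformed then min-max
#' scaled to `[0, 1]`, since pixel sizes span orders of magnitude. All
#' statistics come from the training rows only; applying the model to new
#' rows may legitimately fall outside `[0, 1]` and is not clipped.
#'
#' @param X Training feature matrix with [feature_names()] columns.
#' @return An object of class `norm_model`.
#' @export
fit_normalization <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  feats <- colnames(X)
  if (is.null(feats)) stop("feature matrix must have column names")
  scheme <- feature_scheme(feats)
  p1 <- numeric(ncol(X)); p2 <- numeric(ncol(X))
  for (j in seq_along(feats)) {
    v <- X[, j]
    if (scheme[j] == "zscore") {
      p1[j] <- mean(v)
      s <- stats::sd(v)
      if (s == 0) {
        warning("constant training column '", feats[j],
                "': sd set to 1", call. = FALSE)
        s <- 1
      }
      p2[j] <- s
    } else if (scheme[j] == "logminmax") {
      if (any(v < 0)) stop("negative size feature '", feats[j], "'")
      l <- log10(1 + v)
      p1[j] <- min(l)
      hi <- max(l)
      if (hi == p1[j]) {
        warning("constant training column '", feats[j],
                "': unit min-max range used", call. = FALSE)
        hi <- p1[j] + 1
      }
      p2[j] <- hi
    }
  }
  structure(list(feature = feats, scheme = scheme, p1 = p1, p2 = p2),
            class = "norm_model")
}

#' Apply a fitted normalisation model
#'
#' @param model A `norm_model` from [fit_normalization()].
#' @param X Feature matrix with the same columns.
#' @return Normalised matrix of the same shape.
#' @export
apply_normalization <- function(model, X) {
  stopifnot(inherits(model, "norm_model"),
            identical(colnames(X), model$feature))
  out <- X
  for (j in seq_along(model$feature)) {
    out[, j] <- switch(model$scheme[j],
      none = X[, j],
      zscore = (X[, j] - model$p1[j]) / model$p2[j],
      logminmax = (log10(1 + X[, j]) - model$p1[j]) /
        (model$p2[j] - model$p1[j]))
  }
  out
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("<norm_model: %d features (%s)>\n", length(x$feature),
              paste(sprintf("%s x%d", names(table(x$scheme)),
                            as.integer(table(x$scheme))), collapse = ", ")))
  invisible(x)
}

#' Save / load a normalisation model as JSON
#'
#' @param model A `norm_model`.
#' @param path File path.
#' @return `path` (save) or the restored `norm_model` (load).
#' @export
save_normalization <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_normalization
#' @export
load_normalization <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(feature = obj$feature, scheme = obj$scheme,
                 p1 = obj$p1, p2 = obj$p2), class = "norm_model")
}
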