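TRACK_LABELS <- c("aeroplane", "big_raptor", "other_bird")
TRACK_COLUMNS <- c("track_id", "t", "x_top", "y_top", "x_bottom", "y_bottom",
                   "size_px", "label")
MIN_TRACK_SAMPLES <- 32L  # one full 2-s window at 16 Hz

#' Stereo rig geometry
#'
#' Describes the simplified vertical-baseline pinhole stereo model used to
#' convert paired pixel detections into metric 3D positions. Real rig
#' calibration (lens distortion, module orientation) is out of scope; the
#' geometry is a plain configuration object.
#'
#' @param focal_px Focal length in pixels, > 0.
#' @param baseline_m Vertical separation of the two cameras in meters, > 0.
#' @return An object of class `stereo_geometry`.
#' @export
stereo_geometry <- function(focal_px = 2000, baseline_m = 2) {
  stopifnot(is.numeric(focal_px), length(focal_px) == 1L, focal_px > 0,
            is.numeric(baseline_m), length(baseline_m) == 1L, baseline_m > 0)
  structure(list(focal_px = focal_px, baseline_m = baseline_m),
            class = "stereo_geometry")
}

#' Raw stereovision track
#'
#' A time-ordered set of paired-camera detections for one object, with an
#' expert label. Timestamps must be strictly increasing and the track must
#' span at least one full 2-s analysis window (32 samples at 16 Hz).
#'
#' @param track_id Track identifier (coerced to character).
#' @param detections `data.frame` with columns `t`, `x_top`, `y_top`,
#'   `x_bottom`, `y_bottom`, `size_px`.
#' @param label One of `"aeroplane"`, `"big_raptor"`, `"other_bird"`.
#' @return An object of class `raw_track`.
#' @export
raw_track <- function(track_id, detections, label) {
  label <- match.arg(label, TRACK_LABELS)
  need <- setdiff(c("t", "x_top", "y_top", "x_bottom", "y_bottom", "size_px"),
                  names(detections))
  if (length(need)) stop("detections missing column(s): ",
                         paste(need, collapse = ", "))
  if (nrow(detections) < MIN_TRACK_SAMPLES)
    stop("track ", track_id, " has fewer than ", MIN_TRACK_SAMPLES,
         " detections")
  if (any(diff(detections$t) <= 0))
    stop("track ", track_id, " has non-monotone timestamps")
  if (any(detections$size_px < 1)) stop("size_px must be >= 1")
  structure(list(track_id = as.character(track_id),
                 detections = as.data.frame(detections), label = label),
            class = "raw_track")
}

#' @export
print.raw_track <- function(x, ...) {
  cat(sprintf("<raw_track %s: %d detections, label=%s, t=[%.3f, %.3f] s>\n",
              x$track_id, nrow(x$detections), x$label,
              min(x$detections$t), max(x$detections$t)))
  invisible(x)
}

#' Spherical flight trajectory
#'
#' One object's track as spherical samples: elevation `phi` (radians,
#' measured from the horizontal plane, in [-pi/2, pi/2]), azimuth `theta`
#' (radians, in (-pi, pi]), range `r` (meters, > 0) and apparent pixel size,
#' at a nominal 16 Hz.
#'
#' @param track_id Identifier.
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param phi,theta,r Spherical coordinate vectors (same length as `t`).
#' @param size_px Integer pixel sizes, >= 1.
#' @param label One of the three class labels.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(track_id, t, phi, theta, r, size_px, label) {
  label <- match.arg(label, TRACK_LABELS)
  n <- length(t)
  stopifnot(length(phi) == n, length(theta) == n, length(r) == n,
            length(size_px) == n)
  if (n < MIN_TRACK_SAMPLES)
    stop("track ", track_id, " shorter than ", MIN_TRACK_SAMPLES, " samples")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (any(r <= 0)) stop("r must be positive")
  if (any(abs(phi) > pi / 2 + 1e-12)) stop("phi outside [-pi/2, pi/2]")
  structure(list(track_id = as.character(track_id), t = as.numeric(t),
                 phi = as.numeric(phi), theta = as.numeric(theta),
                 r = as.numeric(r), size_px = as.numeric(size_px),
                 label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory %s: %d samples, label=%s, r=[%.0f, %.0f] m, %.1f s>\n",
    x$track_id, length(x$t), x$label, min(x$r), max(x$r),
    max(x$t) - min(x$t)))
  invisible(x)
}

#' Read labelled tracks from CSV or JSON
#'
#' CSV dialect: header `track_id,t,x_top,y_top,x_bottom,y_bottom,size_px,label`,
#' comma-separated UTF-8; extra columns are ignored. JSON mirrors it as an
#' array of per-track objects with a `detections` array. Rows are grouped by
#' `track_id` and sorted by time. Tracks with an unknown label, duplicated
#' timestamps, or fewer than 32 detections are dropped with a warning.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A list of [raw_track] objects.
#' @export
read_tracks <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(TRACK_COLUMNS, names(df))
    if (length(missing))
      stop("track CSV missing column(s): ", paste(missing, collapse = ", "))
    rows_by_track <- split(df, df$track_id)
    recs <- lapply(names(rows_by_track), function(id) {
      d <- rows_by_track[[id]]
      list(track_id = id, label = unique(d$label),
           detections = d[c("t", "x_top", "y_top", "x_bottom", "y_bottom",
                            "size_px")])
    })
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    recs <- lapply(recs, function(rec) {
      det <- do.call(rbind, lapply(rec$detections, as.data.frame))
      list(track_id = rec$track_id, label = rec$label, detections = det)
    })
  }
  out <- list()
  for (rec in recs) {
    if (length(rec$label) != 1L || !rec$label %in% TRACK_LABELS) {
      warning("track ", rec$track_id, ": unknown or inconsistent label, ",
              "track excluded", call. = FALSE)
      next
    }
    det <- rec$detections[order(rec$detections$t), , drop = FALSE]
    rownames(det) <- NULL
    if (any(diff(det$t) <= 0)) {
      warning("track ", rec$track_id, ": non-monotone timestamps, ",
              "track rejected", call. = FALSE)
      next
    }
    if (nrow(det) < MIN_TRACK_SAMPLES) {
      warning("track ", rec$track_id, ": fewer than ", MIN_TRACK_SAMPLES,
              " detections, track dropped", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- raw_track(rec$track_id, det, rec$label)
  }
  out
}

#' Write tracks to CSV or JSON
#'
#' Inverse of [read_tracks()]: `read_tracks(write_tracks(x, p), fmt)` is the
#' identity field-for-field.
#'
#' @param tracks List of [raw_track] objects.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- do.call(rbind, lapply(tracks, function(tr) {
      cbind(data.frame(track_id = tr$track_id), tr$detections,
            data.frame(label = tr$label))
    }))
    utils::write.csv(df[TRACK_COLUMNS], path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- lapply(tracks, function(tr) {
      list(track_id = tr$track_id, label = tr$label,
           detections = tr$detections)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Friedman-style supersmoother
#'
#' Denoises a series with running local-linear fits at three spans (fractions
#' of the series length) and picks, at every point, the span whose smoothed
#' leave-one-out absolute residual is smallest. Exact on constant and linear
#' series; adapts to the local signal bandwidth otherwise.
#'
#' @param values Numeric series to smooth (no NAs, length >= 10).
#' @param times Strictly increasing abscissae; defaults to a 16 Hz grid.
#' @param spans Three span fractions, classically (0.05, 0.2, 0.5).
#' @return Numeric vector of smoothed values, same length as `values`.
#' @export
supersmooth <- function(values, times = seq_along(values) / 16,
                        spans = c(0.05, 0.2, 0.5)) {
  n <- length(values)
  if (n < 10L)
    stop("series shorter than 10; smoothing unreliable, pass values through")
  if (anyNA(values) || anyNA(times)) stop("NA in input series")
  stopifnot(length(times) == n, all(diff(times) > 0), length(spans) >= 1L)
  fits <- matrix(NA_real_, n, length(spans))
  aloo <- matrix(NA_real_, n, length(spans))
  for (j in seq_along(spans)) {
    k <- max(2L, ceiling(spans[j] * n))
    f <- running_linear_fit(times, values, k)
    fits[, j] <- f$fit
    aloo[, j] <- abs(f$loo_resid)
  }
  # smooth the |LOO residual| curves with the midrange span before comparing
  hw <- max(1L, floor(0.2 * n / 2))
  for (j in seq_along(spans)) aloo[, j] <- running_mean(aloo[, j], hw)
  pick <- max.col(-aloo, ties.method = "first")
  fits[cbind(seq_len(n), pick)]
}

# Local-linear fit over symmetric (truncated at edges) windows of ~k points,
# with closed-form leave-one-out residuals r/(1 - h_ii).
running_linear_fit <- function(x, y, k) {
  n <- length(x)
  h <- max(1L, k %/% 2L)
  fit <- numeric(n)
  loo <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    xi <- x[lo:hi]; yi <- y[lo:hi]
    m <- length(xi)
    xm <- mean(xi); ym <- mean(yi)
    sxx <- sum((xi - xm)^2)
    if (sxx < .Machine$double.eps) {
      fit[i] <- ym
      hat <- 1 / m
    } else {
      b <- sum((xi - xm) * (yi - ym)) / sxx
      fit[i] <- ym + b * (x[i] - xm)
      hat <- 1 / m + (x[i] - xm)^2 / sxx
    }
    loo[i] <- if (hat >= 1) 0 else (y[i] - fit[i]) / (1 - hat)
  }
  list(fit = fit, loo_resid = loo)
}

running_mean <- function(v, hw) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - hw)
  hi <- pmin(n, seq_len(n) + hw)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Triangulate stereo detections to Cartesian points
#'
#' Vertical-baseline pinhole model: vertical disparity `y_top - y_bottom`
#' gives the depth `focal_px * baseline_m / disparity`; the mean pixel
#' position back-projects to the lateral and vertical offsets. Coordinates:
#' `x` depth along the optical axis, `y` lateral, `z` vertical (meters).
#'
#' @param detections `data.frame` with `x_top`, `y_top`, `x_bottom`,
#'   `y_bottom` (pixels).
#' @param geometry A [stereo_geometry].
#' @return `data.frame` with columns `x`, `y`, `z` in meters.
#' @export
triangulate <- function(detections, geometry) {
  stopifnot(inherits(geometry, "stereo_geometry"))
  disp <- detections$y_top - detections$y_bottom
  if (any(disp == 0)) stop("zero disparity: object at infinity")
  if (any(disp < 0)) stop("negative disparity: inconsistent stereo pair")
  depth <- geometry$focal_px * geometry$baseline_m / disp
  px <- (detections$x_top + detections$x_bottom) / 2
  py <- (detections$y_top + detections$y_bottom) / 2
  data.frame(x = depth, y = depth * px / geometry$focal_px,
             z = depth * py / geometry$focal_px)
}

#' Project Cartesian points back to stereo pixel detections
#'
#' Exact inverse of [triangulate()] under the same pinhole model; used by the
#' simulator to emit pixel-level raw tracks.
#'
#' @param points `data.frame` with `x` (depth, > 0), `y`, `z` in meters.
#' @param geometry A [stereo_geometry].
#' @return `data.frame` with `x_top`, `y_top`, `x_bottom`, `y_bottom`.
#' @export
project_stereo <- function(points, geometry) {
  stopifnot(inherits(geometry, "stereo_geometry"))
  if (any(points$x <= 0)) stop("points must lie in front of the cameras")
  px <- points$y * geometry$focal_px / points$x
  py <- points$z * geometry$focal_px / points$x
  disp <- geometry$focal_px * geometry$baseline_m / points$x
  data.frame(x_top = px, y_top = py + disp / 2,
             x_bottom = px, y_bottom = py - disp / 2)
}

#' Cartesian to spherical coordinates
#'
#' Convention used throughout: `phi` is the elevation above the horizontal
#' (x, y) plane (`asin(z / r)`), `theta` the azimuth (`atan2(y, x)`), `r` the
#' Euclidean range. At the poles (`x = y = 0`) the azimuth is undefined and
#' set to 0.
#'
#' @param points `data.frame` with `x`, `y`, `z`.
#' @return `data.frame` with `phi`, `theta`, `r`.
#' @export
cartesian_to_spherical <- function(points) {
  r <- sqrt(points$x^2 + points$y^2 + points$z^2)
  if (any(r == 0)) stop("zero vector has no spherical representation")
  theta <- atan2(points$y, points$x)
  theta[points$x == 0 & points$y == 0] <- 0
  data.frame(phi = asin(pmin(1, pmax(-1, points$z / r))), theta = theta, r = r)
}

#' Spherical to Cartesian coordinates
#'
#' Inverse of [cartesian_to_spherical()] (round-trip exact to 1e-9).
#'
#' @param points `data.frame` with `phi`, `theta`, `r`.
#' @return `data.frame` with `x`, `y`, `z`.
#' @export
spherical_to_cartesian <- function(points) {
  stopifnot(all(points$r > 0))
  data.frame(x = points$r * cos(points$phi) * cos(points$theta),
             y = points$r * cos(points$phi) * sin(points$theta),
             z = points$r * sin(points$phi))
}

#' Convert a raw stereo track to a spherical trajectory
#'
#' The four pixel series are denoised with [supersmooth()] first, then
#' triangulated and converted to spherical coordinates, mirroring the
#' preprocessing order of the acquisition pipeline.
#'
#' @param track A [raw_track].
#' @param geometry A [stereo_geometry].
#' @param spans Supersmoother spans, or `NULL` to skip smoothing.
#' @return A [trajectory].
#' @export
raw_to_trajectory <- function(track, geometry, spans = c(0.05, 0.2, 0.5)) {
  stopifnot(inherits(track, "raw_track"))
  det <- track$detections
  if (!is.null(spans)) {
    for (col in c("x_top", "y_top", "x_bottom", "y_bottom"))
      det[[col]] <- supersmooth(det[[col]], det$t, spans)
  }
  sph <- cartesian_to_spherical(triangulate(det, geometry))
  trajectory(track$track_id, det$t, sph$phi, sph$theta, sph$r, det$size_px,
             track$label)
}
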