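# Toy-scale minimum-norm least-squares (MNLS) source estimation: leadfields,
# inverse operators, sensor-array repositioning and ROI source waveforms.

new_leadfield <- function(gain, sensors, locations) {
  gain <- as.matrix(gain)
  if (any(!is.finite(gain))) stop_config("leadfield entries must be finite")
  if (length(sensors) != nrow(gain)) stop_config("sensor names do not match gain rows")
  if (nrow(locations) != ncol(gain)) stop_config("source locations do not match gain columns")
  structure(list(gain = gain, sensors = sensors, locations = locations),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield> ", nrow(x$gain), " sensors x ", ncol(x$gain),
      " sources\n", sep = "")
  invisible(x)
}

#' Build a toy leadfield
#'
#' Small synthetic forward models standing in for an anatomical leadfield:
#' `identity` (square, one sensor per source), `random_full_rank` (Gaussian
#' gain matrix, redrawn until rank equals `min(n_sensors, n_sources)`), or
#' `ring_geometry` (sensors on an outer ring, fixed-orientation scalar
#' sources on an inner ring, gain decaying with sensor-source distance --
#' the geometry used for the localization benchmarks).
#'
#' @param n_sensors,n_sources dimensions (>= 1).
#' @param mode one of `"random_full_rank"`, `"ring_geometry"`, `"identity"`.
#' @param seed integer seed; output is deterministic given the seed.
#' @param rotation angular offset (radians) of the sensor ring in
#'   `ring_geometry` mode; nonzero values emulate an individually displaced
#'   sensor array relative to the canonical one.
#' @return A `leadfield` with `gain` (sensors x sources), sensor names and
#'   3D source locations in mm (arbitrary head frame).
#' @export
make_toy_leadfield <- function(n_sensors, n_sources,
                               mode = c("random_full_rank", "ring_geometry",
                                        "identity"),
                               seed = 1L, rotation = 0) {
  mode <- match.arg(mode)
  check_number(n_sensors, "n_sensors", lower = 1)
  check_number(n_sources, "n_sources", lower = 1)
  sensors <- sprintf("S%02d", seq_len(n_sensors))
  ring <- function(n, radius, rot = 0) {
    phi <- 2 * pi * (seq_len(n) - 1L) / n + rot
    cbind(x = radius * cos(phi), y = radius * sin(phi), z = 0)
  }
  with_seed(seed, {
    if (mode == "identity") {
      if (n_sensors != n_sources) {
        stop_config("identity mode requires n_sensors == n_sources")
      }
      return(new_leadfield(diag(n_sensors), sensors, ring(n_sources, 70)))
    }
    if (mode == "random_full_rank") {
      r_target <- min(n_sensors, n_sources)
      repeat {
        gain <- matrix(stats::rnorm(n_sensors * n_sources),
                       n_sensors, n_sources)
        if (qr(gain)$rank == r_target) break
      }
      return(new_leadfield(gain, sensors, ring(n_sources, 70)))
    }
    # ring geometry: distance-decaying gains
    sens_loc <- ring(n_sensors, 110, rotation)
    src_loc <- ring(n_sources, 70)
    d <- outer(seq_len(n_sensors), seq_len(n_sources), function(i, j) {
      sqrt(rowSums((sens_loc[i, , drop = FALSE] - src_loc[j, , drop = FALSE])^2))
    })
    new_leadfield(1 / (1 + (d / 40)^2), sensors, src_loc)
  })
}

#' Default Tikhonov regularization for a leadfield
#'
#' `trace(L L') / n_sensors * 0.01`, a mild fraction of the mean sensor
#' power of the forward model.
#'
#' @param L a `leadfield`.
#' @return The default lambda.
#' @export
default_lambda <- function(L) {
  sum(L$gain^2) / nrow(L$gain) * 0.01
}

#' Minimum-norm least-squares inverse operator
#'
#' `W = L' (L L' + lambda I)^-1` (sources x sensors).  With `lambda = 0`
#' and data in the range of `L`, `W x` is the minimum-Euclidean-norm exact
#' solution of `L s = x`; for `lambda > 0` it is the Tikhonov-regularized
#' estimate, converging to the Moore-Penrose pseudo-inverse solution as
#' `lambda` approaches 0.
#'
#' @param L a `leadfield`.
#' @param lambda nonnegative regularization parameter; use
#'   [default_lambda()] for a standard choice.
#' @return The inverse operator matrix (sources x sensors).
#' @export
mnls_operator <- function(L, lambda = default_lambda(L)) {
  check_number(lambda, "lambda", lower = 0)
  G <- L$gain
  A <- tcrossprod(G)
  diag(A) <- diag(A) + lambda
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv) || rcond(A) < 1e-14) {
    stop_config("L L' is (near-)singular; use lambda > 0 to regularize")
  }
  crossprod(G, Ainv)
}

#' Apply an inverse operator to sensor data
#'
#' @param W inverse operator (sources x sensors), see [mnls_operator()].
#' @param sensor_data matrix sensors x samples (e.g. a grand-average
#'   waveform), or a `waveform`.
#' @param time_ms optional time axis carried through to the estimate.
#' @param lambda regularization recorded in the estimate (metadata only).
#' @return A `source_estimate` with `amplitudes` (sources x samples).
#' @export
apply_inverse <- function(W, sensor_data, time_ms = NULL, lambda = NA_real_) {
  if (inherits(sensor_data, "waveform")) {
    time_ms <- sensor_data$time_ms
    sensor_data <- sensor_data$data
  }
  sensor_data <- as.matrix(sensor_data)
  if (ncol(W) != nrow(sensor_data)) {
    stop_config("sensor dimension mismatch: operator has ", ncol(W),
                " sensors, data has ", nrow(sensor_data))
  }
  structure(list(amplitudes = W %*% sensor_data,
                 time_ms = time_ms %||% seq_len(ncol(sensor_data)),
                 lambda = lambda),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("<source_estimate> ", nrow(x$amplitudes), " sources x ",
      ncol(x$amplitudes), " samples\n", sep = "")
  invisible(x)
}

#' Reposition sensor data onto a canonical array
#'
#' Two-step transform used to align individual sensor geometries with a
#' canonical one: project the individual data into source space with the
#' MNLS inverse of the individual leadfield, then forward-project with the
#' canonical leadfield: `x_canon = L_canon W_ind x_ind`.
#'
#' @param x_ind individual sensor data (sensors x samples).
#' @param L_ind,L_canon individual and canonical `leadfield`s sharing the
#'   same source space.
#' @param lambda regularization for the inversion of `L_ind`.
#' @return Canonical-array data (sensors x samples).
#' @export
reposition_sensors <- function(x_ind, L_ind, L_canon,
                               lambda = default_lambda(L_ind)) {
  if (ncol(L_ind$gain) != ncol(L_canon$gain)) {
    stop_config("leadfields do not share a source space")
  }
  W <- mnls_operator(L_ind, lambda)
  L_canon$gain %*% (W %*% as.matrix(x_ind))
}

#' Define a region of interest over source indices
#'
#' @param label ROI name.
#' @param indices member source indices (non-empty).
#' @param n_sources optional total source count for validation.
#' @return A list of class `source_roi`.
#' @export
source_roi <- function(label, indices, n_sources = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L || anyNA(indices) || any(indices < 1L)) {
    stop_config("ROI must contain valid, non-empty source indices")
  }
  if (!is.null(n_sources) && any(indices > n_sources)) {
    stop_config("ROI indices exceed the number of sources")
  }
  structure(list(label = label, indices = indices), class = "source_roi")
}

#' ROIs around source-strength maxima
#'
#' Groups sources whose mean absolute amplitude exceeds a fraction of the
#' global maximum into contiguous-index ROIs (a simple stand-in for drawing
#' ROIs around source maxima above a threshold).
#'
#' @param est a `source_estimate`.
#' @param threshold fraction of the maximum mean |amplitude| in (0, 1).
#' @return List of `source_roi`s.
#' @export
rois_from_maxima <- function(est, threshold = 0.5) {
  check_number(threshold, "threshold", lower = 1e-9, upper = 1 - 1e-9)
  strength <- rowMeans(abs(est$amplitudes))
  keep <- which(strength >= threshold * max(strength))
  if (length(keep) == 0L) return(list())
  grp <- cumsum(c(1L, diff(keep) != 1L))
  lapply(split(keep, grp), function(ix) {
    source_roi(sprintf("roi_%d", ix[1]), ix)
  })
}

#' Source-strength time course of an ROI
#'
#' Mean absolute estimated current across the ROI members, per sample
#' (source strength as magnitude; sources are fixed-orientation scalars in
#' the toy model).
#'
#' @param est a `source_estimate`.
#' @param roi a `source_roi`.
#' @return Numeric vector, one value per sample.
#' @export
roi_waveform <- function(est, roi) {
  if (!inherits(roi, "source_roi")) stop_config("'roi' must be a source_roi")
  if (any(roi$indices > nrow(est$amplitudes))) {
    stop_config("ROI indices exceed the estimate's source space")
  }
  colMeans(abs(est$amplitudes[roi$indices, , drop = FALSE]))
}
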