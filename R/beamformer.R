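#' Scalar minimum-variance beamformer weights
#'
#' Computes one spatial filter per source from broadband-filtered sensor
#' data: with `C` the sample covariance of the 0.5--48 Hz band-passed
#' sensor signals, regularized as `C + lambda * mean(diag(C)) * I`, the
#' weights for lead column `l` are `w = C^-1 l / (l' C^-1 l)`, the
#' minimum-variance solution under the unit-gain constraint `w'l = 1`.
#'
#' @param sensor_data Sensors x samples matrix (or a sensor-space
#'   `meg_recording`).
#' @param leads A `meg_leadfield` (see [simulate_forward()]) or a plain
#'   sensors x regions lead matrix.
#' @param fs Sampling frequency in Hz (required when `sensor_data` is a
#'   plain matrix).
#' @param regularization Diagonal-loading fraction `lambda` of the mean
#'   sensor variance (default 0.05).
#' @param cov_band Band over which the covariance is estimated, default
#'   `c(0.5, 48)` Hz.
#' @return Object of class `meg_beamformer`: `weights` (regions x sensors),
#'   `regularization`, `cov_band`.  Every row satisfies
#'   `weights[r, ] %*% lead[, r] == 1` to numerical precision.
#' @export
beamformer_weights <- function(sensor_data, leads, fs = NULL,
                               regularization = 0.05, cov_band = c(0.5, 48)) {
  if (inherits(sensor_data, "meg_recording")) {
    fs <- sensor_data$fs
    sensor_data <- sensor_data$data
  }
  if (is.null(fs)) abort("fs is required")
  L <- if (inherits(leads, "meg_leadfield")) leads$lead_matrix else leads
  S <- nrow(L)
  stopifnot(nrow(sensor_data) == S)
  if (ncol(sensor_data) <= S) abort("need more samples than sensors for the covariance")
  if (any(colSums(abs(L)) == 0)) abort("lead field contains an all-zero column")

  xb <- bandpass_fir(sensor_data, cov_band[1L], cov_band[2L], fs)
  C <- cov(t(xb))
  out <- weights_from_covariance(C, L, regularization)
  out$cov_band <- cov_band
  out
}

#' @rdname beamformer_weights
#' @param C Sensor covariance matrix (sensors x sensors).
#' @export
weights_from_covariance <- function(C, leads, regularization = 0.05) {
  L <- if (inherits(leads, "meg_leadfield")) leads$lead_matrix else leads
  S <- nrow(L)
  stopifnot(nrow(C) == S, ncol(C) == S)
  if (any(colSums(abs(L)) == 0)) abort("lead field contains an all-zero column")
  C_reg <- C + regularization * mean(diag(C)) * diag(S)
  Ci_L <- tryCatch(
    solve(C_reg, L),
    error = function(e) {
      abort(paste0(
        "regularized covariance is singular (", conditionMessage(e),
        "); increase `regularization`"
      ))
    }
  )
  denom <- colSums(L * Ci_L)
  W <- t(Ci_L) / denom
  structure(
    list(weights = W, regularization = regularization, cov_band = NULL),
    class = "meg_beamformer"
  )
}

#' Project sensor data to source space
#'
#' Applies the beamformer's spatial filters row-wise:
#' `source[r, ] = weights[r, ] %*% sensor_data`.
#'
#' @param sensor_data Sensors x samples matrix or sensor-space
#'   `meg_recording`.
#' @param weights A `meg_beamformer` from [beamformer_weights()].
#' @param roi_names Source names (default `R001`, ...).
#' @param fs Sampling frequency (taken from the recording when given one).
#' @param subject_id Identifier carried into the output.
#' @return A source-space `meg_recording`.
#' @export
reconstruct_sources <- function(sensor_data, weights, roi_names = NULL,
                                fs = NULL, subject_id = "subject") {
  stopifnot(inherits(weights, "meg_beamformer"))
  if (inherits(sensor_data, "meg_recording")) {
    fs <- sensor_data$fs
    subject_id <- sensor_data$subject_id
    sensor_data <- sensor_data$data
  }
  W <- weights$weights
  if (ncol(W) != nrow(sensor_data)) abort("sensor count does not match the weights")
  roi_names <- roi_names %||% sprintf("R%03d", seq_len(nrow(W)))
  structure(
    list(subject_id = subject_id, fs = fs, roi_names = roi_names,
         data = W %*% sensor_data),
    class = "meg_recording"
  )
}
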