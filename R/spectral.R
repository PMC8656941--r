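#' One-sided periodogram power spectral density
#'
#' Raw (rectangular-window) periodogram of each region's signal, returned as
#' a one-sided density so that the rectangle-rule sum of `power * df` over
#' all positive-frequency bins equals the signal's mean square (Parseval).
#'
#' @param epoch Numeric matrix (regions x samples) or vector.
#' @param fs Sampling frequency in Hz.
#' @return An object of class `meg_psd`: list with `freqs` (Hz, length
#'   `floor(n/2) + 1`, resolution `fs/n`) and `power` (regions x freqs,
#'   units^2/Hz).
#' @export
periodogram_psd <- function(epoch, fs) {
  x <- as_matrix_ts(epoch)
  if (!all(is.finite(x))) abort("epoch contains non-finite values")
  n <- ncol(x)
  X <- stats::mvfft(t(x))
  P <- Mod(X)^2 / (n * fs)
  half <- floor(n / 2) + 1L
  P <- P[seq_len(half), , drop = FALSE]
  # double the strictly one-sided bins (not DC; not Nyquist when n is even)
  dbl <- 2:(if (n %% 2 == 0) half - 1L else half)
  P[dbl, ] <- 2 * P[dbl, ]
  structure(
    list(freqs = (seq_len(half) - 1L) * fs / n, power = t(P), fs = fs),
    class = "meg_psd"
  )
}

# frequency-bin membership: bands own their upper edge (shared edge bin goes
# to the lower band); the first band also owns its lower edge so the six
# bands exactly tile the 0.5-48 Hz analysis range bin-by-bin
band_bin_index <- function(freqs, scheme) {
  idx <- rep(NA_integer_, length(freqs))
  for (i in seq_len(nrow(scheme))) {
    lo <- scheme$f_lo[i]
    hi <- scheme$f_hi[i]
    inb <- if (i == 1L) freqs >= lo & freqs <= hi else freqs > lo & freqs <= hi
    idx[inb] <- i
  }
  idx
}

#' Relative band power from a PSD
#'
#' Integrates the PSD over each band of the scheme (rectangle rule over the
#' bins belonging to the band) and normalizes by the total power over the
#' full scheme range.  Because every analysis-range bin belongs to exactly
#' one band, each region's relative powers sum to one exactly.
#'
#' @param p A `meg_psd` object from [periodogram_psd()].
#' @param scheme Band scheme tibble, default [band_scheme()].
#' @return List with `rbp` (regions x bands matrix, rows summing to 1),
#'   `total_power` (regions vector, units^2, integral over the scheme
#'   range) and `band` names.  Regions with zero total power get `NA` rows
#'   and a warning.
#' @export
relative_band_power <- function(p, scheme = band_scheme()) {
  stopifnot(inherits(p, "meg_psd"))
  validate_band_scheme(scheme)
  df <- p$freqs[2L] - p$freqs[1L]
  idx <- band_bin_index(p$freqs, scheme)
  nb <- nrow(scheme)
  band_power <- vapply(seq_len(nb), function(b) {
    cols <- which(idx == b)
    rowSums(p$power[, cols, drop = FALSE]) * df
  }, numeric(nrow(p$power)))
  band_power <- matrix(band_power, nrow = nrow(p$power))
  total <- rowSums(band_power)
  rbp <- band_power / total
  if (any(total <= 0)) {
    warn("zero total power in at least one region; RBP undefined there")
    rbp[total <= 0, ] <- NA_real_
  }
  colnames(rbp) <- scheme$band
  list(rbp = rbp, total_power = total, band = scheme$band)
}

#' Individual peak frequency of the occipital-average PSD
#'
#' The frequency at which the PSD, averaged over the occipital regions (and
#' over epochs when several PSDs are supplied), attains its maximum within
#' the search range (default 4--13 Hz).
#'
#' @param psds A `meg_psd` or list of `meg_psd` objects sharing a frequency
#'   grid.
#' @param occipital_idx Integer indices of occipital regions.
#' @param f_range Search range in Hz, default `c(4, 13)`.
#' @return Peak frequency in Hz.  If the maximum sits on a boundary of the
#'   search range (monotone spectrum) a warning is raised.
#' @export
individual_peak_frequency <- function(psds, occipital_idx, f_range = c(4, 13)) {
  if (inherits(psds, "meg_psd")) psds <- list(psds)
  stopifnot(length(occipital_idx) >= 1L)
  avg <- Reduce(`+`, lapply(psds, function(p) {
    colMeans(p$power[occipital_idx, , drop = FALSE])
  })) / length(psds)
  freqs <- psds[[1L]]$freqs
  inr <- which(freqs >= f_range[1L] & freqs <= f_range[2L])
  k <- inr[which.max(avg[inr])]
  if (k == inr[1L] || k == inr[length(inr)]) {
    warn("peak frequency lies on the boundary of the search range")
  }
  freqs[k]
}

#' Subject-level spectral profile from selected epochs
#'
#' Computes per-epoch periodogram PSDs, relative band powers and total
#' power, averages them across the selected epochs, and determines the
#' individual peak frequency (IPF) from the epoch-averaged occipital PSD.
#'
#' @param eset A selected `meg_epochs` object (see [select_epochs()]); any
#'   epoch set works, but the intended input carries exactly the selected
#'   epochs.
#' @param occipital_idx Integer indices of occipital regions.
#' @param scheme Band scheme, default [band_scheme()].
#' @return Object of class `meg_spectral`: `subject_id`, `rbp` (regions x
#'   bands, rows sum to 1), `total_power`, `ipf` (Hz), `roi_names`, `band`.
#' @seealso [tidy.meg_spectral()] for a long-format tibble.
#' @export
spectral_profile <- function(eset, occipital_idx, scheme = band_scheme()) {
  stopifnot(inherits(eset, "meg_epochs"), length(eset$epochs) >= 1L)
  psds <- lapply(eset$epochs, periodogram_psd, fs = eset$fs)
  rbps <- lapply(psds, relative_band_power, scheme = scheme)
  rbp <- Reduce(`+`, lapply(rbps, `[[`, "rbp")) / length(rbps)
  total <- Reduce(`+`, lapply(rbps, `[[`, "total_power")) / length(rbps)
  ipf <- individual_peak_frequency(psds, occipital_idx)
  structure(
    list(
      subject_id = eset$subject_id, rbp = rbp, total_power = total,
      ipf = ipf, roi_names = eset$roi_names, band = scheme$band
    ),
    class = "meg_spectral"
  )
}

#' Whole-brain spectral feature table for a set of subjects
#'
#' Collapses subject spectral profiles to one row per subject: the six
#' whole-brain (region-averaged) relative band powers plus the IPF.  This is
#' the brain-feature block used by group statistics and PLSC.
#'
#' @param profiles List of `meg_spectral` objects.
#' @return Tibble with columns `subject_id`, one `<band>_rbp` per band, and
#'   `ipf`.
#' @export
spectral_feature_table <- function(profiles) {
  purrr::map_dfr(profiles, function(p) {
    out <- tibble::tibble(subject_id = p$subject_id)
    wb <- colMeans(p$rbp)
    for (b in p$band) out[[paste0(b, "_rbp")]] <- wb[[b]]
    out$ipf <- p$ipf
    out
  })
}
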