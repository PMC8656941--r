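#' Segment a recording into fixed-length epochs
#'
#' Cuts a source recording into consecutive, non-overlapping epochs starting
#' at sample 1; the trailing remainder is discarded.  Robust per-region
#' location and scale (median and MAD over the whole recording) are computed
#' here and carried along for amplitude quality scoring.
#'
#' @param rec A `meg_recording` (see [simulate_sources()] or
#'   [reconstruct_sources()]).
#' @param epoch_len Epoch length in samples; the default 16384 corresponds
#'   to 13.1 s at 1250 Hz.
#' @return An object of class `meg_epochs`: `subject_id`, `fs`,
#'   `epoch_len`, `roi_names`, `epochs` (list of regions x epoch_len
#'   matrices), `start_indices` (1-based sample offsets), robust `center`
#'   and `scale`, and an empty `quality` slot.
#' @export
segment_epochs <- function(rec, epoch_len = 16384L) {
  stopifnot(inherits(rec, "meg_recording"))
  nT <- ncol(rec$data)
  if (nT < epoch_len) abort("recording shorter than one epoch")
  n_ep <- floor(nT / epoch_len)
  starts <- (seq_len(n_ep) - 1L) * epoch_len + 1L
  epochs <- lapply(starts, function(s) {
    rec$data[, s:(s + epoch_len - 1L), drop = FALSE]
  })
  rs <- robust_center_scale(rec$data)
  structure(
    list(
      subject_id = rec$subject_id, fs = rec$fs, epoch_len = as.integer(epoch_len),
      roi_names = rec$roi_names, epochs = epochs, start_indices = starts,
      center = rs$center, scale = rs$scale, quality = NULL, selected = FALSE
    ),
    class = "meg_epochs"
  )
}

#' Score the quality of one epoch
#'
#' Three quality markers per epoch: the peak absolute amplitude in robust-z
#' units (artifact indicator), the epoch's occipital peak frequency in the
#' 4--13 Hz range, and the occipital-average alpha1 relative power
#' (drowsiness indicators).
#'
#' @param epoch Regions x samples matrix.
#' @param fs Sampling frequency in Hz.
#' @param occipital_idx Integer indices of occipital regions.
#' @param center,scale Per-region robust location and scale (median, MAD of
#'   the whole recording) used for the z-amplitude; defaults to the epoch's
#'   own statistics when not supplied.
#' @param scheme Band scheme, default [band_scheme()].
#' @return One-row tibble: `max_abs_z`, `epoch_ipf`, `alpha1_occ_rbp`.  A
#'   zero-variance region yields `max_abs_z = Inf` so the epoch is rejected
#'   on amplitude.
#' @export
score_epoch <- function(epoch, fs, occipital_idx, center = NULL, scale = NULL,
                        scheme = band_scheme()) {
  stopifnot(length(occipital_idx) >= 1L)
  epoch <- as_matrix_ts(epoch)
  if (is.null(center) || is.null(scale)) {
    rs <- robust_center_scale(epoch)
    center <- center %||% rs$center
    scale <- scale %||% rs$scale
  }
  if (any(scale <= 0)) {
    max_abs_z <- Inf
  } else {
    max_abs_z <- max(abs((epoch - center) / scale))
  }
  p <- periodogram_psd(epoch, fs)
  ipf <- suppressWarnings(individual_peak_frequency(p, occipital_idx))
  rb <- relative_band_power(p, scheme)
  a1 <- mean(rb$rbp[occipital_idx, "alpha1"])
  tibble::tibble(max_abs_z = max_abs_z, epoch_ipf = ipf, alpha1_occ_rbp = a1)
}

#' Score every candidate epoch of an epoch set
#'
#' Applies [score_epoch()] to each epoch using the recording-level robust
#' statistics stored in the set, and applies the three rejection rules:
#' amplitude (`|z|` above `z_thresh` robust units), epoch-IPF outlier
#' (outside median +/- 3 MAD of the candidate epochs' IPFs) and low
#' occipital alpha1 power (below the within-subject 25th percentile).  When
#' an epoch trips several rules the recorded reason follows the priority
#' amplitude > ipf_outlier > low_alpha.
#'
#' @param eset A `meg_epochs` object from [segment_epochs()].
#' @param occipital_idx Integer indices of occipital regions.
#' @param z_thresh Robust-z amplitude rejection threshold (default 6).
#' @param ipf_mads IPF outlier half-width in MADs (default 3).
#' @param alpha_quantile Low-alpha rejection quantile (default 0.25).
#' @param scheme Band scheme.
#' @return The epoch set with a `quality` tibble: one row per candidate with
#'   the three scores, `rejected` and `reason` in
#'   `c("amplitude", "ipf_outlier", "low_alpha", "none")`.
#' @export
score_epochs <- function(eset, occipital_idx, z_thresh = 6, ipf_mads = 3,
                         alpha_quantile = 0.25, scheme = band_scheme()) {
  stopifnot(inherits(eset, "meg_epochs"))
  q <- purrr::map_dfr(eset$epochs, score_epoch,
    fs = eset$fs, occipital_idx = occipital_idx,
    center = eset$center, scale = eset$scale, scheme = scheme
  )
  q$epoch <- seq_len(nrow(q))
  q$start_index <- eset$start_indices

  ipf_med <- median(q$epoch_ipf)
  ipf_mad <- mad(q$epoch_ipf)
  alpha_cut <- quantile(q$alpha1_occ_rbp, alpha_quantile, names = FALSE)

  amp <- q$max_abs_z > z_thresh
  ipf_out <- abs(q$epoch_ipf - ipf_med) > ipf_mads * ipf_mad & ipf_mad > 0
  low_a <- q$alpha1_occ_rbp < alpha_cut

  q$reason <- dplyr::case_when(
    amp ~ "amplitude",
    ipf_out ~ "ipf_outlier",
    low_a ~ "low_alpha",
    TRUE ~ "none"
  )
  q$rejected <- q$reason != "none"
  eset$quality <- dplyr::relocate(q, "epoch", "start_index")
  eset
}

#' Select the best epochs of a scored set
#'
#' Among non-rejected candidates, epochs are ranked by the sum of the ranks
#' of their epoch IPF and occipital alpha1 power (equal weight, higher is
#' better) and the top `n_select` are kept, preferring earlier start indices
#' on ties; the returned set is in chronological order.
#'
#' @param eset A scored `meg_epochs` object (see [score_epochs()]).
#' @param n_select Number of epochs to keep (default 8).
#' @return The epoch set restricted to the selected epochs (`selected =
#'   TRUE`, quality table subset accordingly).  If fewer than `n_select`
#'   candidates survive rejection, an error of class
#'   `restmeg_subject_exclusion` is thrown, mirroring cohort-level subject
#'   exclusion for low-quality recordings.
#' @export
select_epochs <- function(eset, n_select = 8L) {
  stopifnot(inherits(eset, "meg_epochs"))
  if (is.null(eset$quality)) abort("epoch set must be scored first; see score_epochs()")
  q <- eset$quality
  surv <- q[!q$rejected, , drop = FALSE]
  if (nrow(surv) < n_select) {
    abort(
      sprintf(
        "subject %s excluded: only %d of %d epochs survive quality rejection (need %d)",
        eset$subject_id, nrow(surv), nrow(q), n_select
      ),
      class = "restmeg_subject_exclusion"
    )
  }
  score <- rank(surv$epoch_ipf) + rank(surv$alpha1_occ_rbp)
  ord <- order(-score, surv$start_index)
  keep <- sort(surv$epoch[ord[seq_len(n_select)]])

  eset$epochs <- eset$epochs[keep]
  eset$start_indices <- eset$start_indices[keep]
  eset$quality <- q[match(keep, q$epoch), , drop = FALSE]
  eset$selected <- TRUE
  eset
}
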