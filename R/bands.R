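#' Canonical six-band frequency scheme
#'
#' Returns the band scheme used throughout the package: delta (0.5--4 Hz),
#' theta (4--8 Hz), alpha1 (8--10 Hz), alpha2 (10--13 Hz), beta (13--30 Hz)
#' and gamma (30--48 Hz).  The bands are contiguous, non-overlapping and tile
#' the full analysis range 0.5--48 Hz exactly, so relative band powers sum
#' to one by construction.
#'
#' @return A tibble with columns `band` (ordered factor levels in spectral
#'   order), `f_lo` and `f_hi` in Hz.
#' @export
#' @examples
#' band_scheme()
band_scheme <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 10, 13, 30),
    f_hi = c(4, 8, 10, 13, 30, 48)
  )
}

#' Validate a band scheme
#'
#' Checks that a band table is contiguous, non-overlapping and tiles the
#' closed interval given by its first `f_lo` and last `f_hi`.
#'
#' @param scheme A tibble/data frame with columns `band`, `f_lo`, `f_hi`.
#' @return The scheme, invisibly, if valid; otherwise an error.
#' @export
validate_band_scheme <- function(scheme) {
  stopifnot(all(c("band", "f_lo", "f_hi") %in% names(scheme)))
  if (any(scheme$f_hi <= scheme$f_lo)) {
    abort("invalid band scheme: each band needs f_lo < f_hi")
  }
  if (nrow(scheme) > 1L) {
    gaps <- scheme$f_lo[-1L] - scheme$f_hi[-nrow(scheme)]
    if (any(abs(gaps) > 1e-9)) {
      abort("invalid band scheme: bands must be contiguous and non-overlapping")
    }
  }
  if (anyDuplicated(scheme$band)) abort("invalid band scheme: duplicated band names")
  invisible(scheme)
}

band_edges <- function(scheme, band) {
  i <- match(band, scheme$band)
  if (is.na(i)) abort(paste0("unknown band: ", band))
  c(scheme$f_lo[i], scheme$f_hi[i])
}
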