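#' Orthogonalize one signal with respect to another
#'
#' Removes from `y` its zero-lag projection onto `x`:
#' `y - (<y, x> / <x, x>) x`.  The result has zero inner product with `x`,
#' which removes instantaneous (leakage) coupling before envelope
#' correlation.
#'
#' @param x Reference signal (non-zero variance).
#' @param y Signal to correct.
#' @return The corrected signal, with attribute `degenerate = TRUE` when the
#'   residual variance falls below `1e-12 * var(y)` (a pure-leakage pair).
#' @export
orthogonalize <- function(x, y) {
  sx <- sum(x * x)
  if (sx == 0) abort("reference signal has zero variance")
  r <- y - (sum(x * y) / sx) * x
  attr(r, "degenerate") <- stats::var(r) < 1e-12 * stats::var(y)
  r
}

#' Corrected amplitude envelope correlation of one signal pair
#'
#' The AECc of two band-limited signals: each signal is orthogonalized with
#' respect to the other (removing the zero-lag component), amplitude
#' envelopes are taken as the magnitude of the analytic signal, and the two
#' directed Pearson envelope correlations are averaged.  A degenerate
#' direction (collinear pair) contributes 0: pure instantaneous leakage
#' carries no corrected connectivity.
#'
#' @param x,y Band-passed signals of equal length.
#' @param edge_discard Number of samples dropped from each end of the
#'   envelopes before correlating (two-pass filter transients); default 0.
#' @return AECc value in `[-1, 1]`.
#' @export
aecc_pair <- function(x, y, edge_discard = 0L) {
  stopifnot(length(x) == length(y))
  keep <- (edge_discard + 1L):(length(x) - edge_discard)
  one_dir <- function(ref, oth) {
    o <- orthogonalize(ref, oth)
    if (isTRUE(attr(o, "degenerate"))) return(0)
    e_ref <- amplitude_envelope(ref)[keep]
    e_oth <- amplitude_envelope(o)[keep]
    if (sd(e_ref) <= 1e-10 * mean(e_ref) || sd(e_oth) <= 1e-10 * mean(e_oth)) {
      warn("constant envelope: correlation undefined, scored 0")
      return(0)
    }
    cor(e_ref, e_oth)
  }
  (one_dir(x, y) + one_dir(y, x)) / 2
}

#' Uncorrected amplitude envelope correlation
#'
#' Plain Pearson correlation of the two amplitude envelopes without
#' orthogonalization; inflated by instantaneous leakage and provided as the
#' reference against which the corrected measure ([aecc_pair()]) is
#' assessed.
#'
#' @inheritParams aecc_pair
#' @return AEC value in `[-1, 1]`.
#' @export
aec_pair <- function(x, y, edge_discard = 0L) {
  stopifnot(length(x) == length(y))
  keep <- (edge_discard + 1L):(length(x) - edge_discard)
  ex <- amplitude_envelope(x)[keep]
  ey <- amplitude_envelope(y)[keep]
  if (sd(ex) <= 1e-10 * mean(ex) || sd(ey) <= 1e-10 * mean(ey)) {
    warn("constant envelope: correlation undefined, scored 0")
    return(0)
  }
  cor(ex, ey)
}

# all-pairs AECc of one band-passed epoch, exploiting linearity of the
# analytic signal: env(y - b x) = |A_y - b A_x| with A precomputed per
# region, so no per-pair FFT is needed
aecc_epoch <- function(xb, keep) {
  R <- nrow(xb)
  A <- analytic_signal(xb)
  E <- Mod(A)[, keep, drop = FALSE]
  Ec <- E - rowMeans(E)
  En <- sqrt(rowSums(Ec^2))
  ss <- rowSums(xb^2)
  vref <- rowSums((xb - rowMeans(xb))^2)
  D <- matrix(0, R, R) # D[i, j] = cor(env_i, env(j orthogonalized wrt i))
  for (i in seq_len(R)) {
    if (ss[i] == 0) next
    beta <- drop(xb %*% xb[i, ]) / ss[i]
    Res <- Mod(A - outer(beta, A[i, ]))[, keep, drop = FALSE]
    # degenerate residuals (pure leakage) contribute 0
    res_full <- rowSums((xb - outer(beta, xb[i, ]))^2)
    degen <- res_full < 1e-12 * vref | vref == 0
    Rc <- Res - rowMeans(Res)
    Rn <- sqrt(rowSums(Rc^2))
    num <- drop(Rc %*% Ec[i, ])
    cvec <- num / (Rn * En[i])
    cvec[degen | !is.finite(cvec)] <- 0
    D[i, ] <- cvec
  }
  D
}

#' Band-specific AECc connectivity matrix of an epoch set
#'
#' For every epoch, all ordered region pairs are orthogonalized (per epoch,
#' in both directions), Hilbert envelopes are correlated, the directed
#' matrix is symmetrized by averaging its upper and lower triangles, and the
#' per-epoch matrices are averaged.
#'
#' @param eset A (selected) `meg_epochs` object.
#' @param band Band name from the scheme, or a numeric `c(f_lo, f_hi)`.
#' @param scheme Band scheme, default [band_scheme()].
#' @param order FIR order (default as in [bandpass_fir()]); the first and
#'   last `order` envelope samples of each epoch are discarded before
#'   correlating.
#' @return Object of class `meg_connectivity`: `band`, `matrix` (regions x
#'   regions, symmetric, zero diagonal, entries in `[-1, 1]`),
#'   `n_epochs_averaged`, `roi_names`.  Constant regions give zero
#'   rows/columns with a warning.
#' @export
connectivity_matrix <- function(eset, band, scheme = band_scheme(), order = NULL) {
  stopifnot(inherits(eset, "meg_epochs"), length(eset$epochs) >= 1L)
  edges <- if (is.character(band)) band_edges(scheme, band) else band
  band_name <- if (is.character(band)) band else paste0(band, collapse = "-")
  nT <- ncol(eset$epochs[[1L]])
  R <- nrow(eset$epochs[[1L]])
  acc <- matrix(0, R, R)
  any_const <- FALSE
  for (ep in eset$epochs) {
    xb <- bandpass_fir(ep, edges[1L], edges[2L], eset$fs, order = order)
    ord <- attr(xb, "fir_order")
    keep <- (ord + 1L):(nT - ord)
    if (any(apply(ep, 1L, sd) == 0)) any_const <- TRUE
    D <- aecc_epoch(xb, keep)
    acc <- acc + (D + t(D)) / 2
  }
  m <- acc / length(eset$epochs)
  diag(m) <- 0
  if (any_const) warn("constant region(s): their connectivity rows/columns are 0")
  structure(
    list(
      band = band_name, matrix = m,
      n_epochs_averaged = length(eset$epochs), roi_names = eset$roi_names
    ),
    class = "meg_connectivity"
  )
}

#' Whole-brain average and nodal strength of a connectivity matrix
#'
#' @param m A `meg_connectivity` object (or plain symmetric matrix).
#' @return List of class `meg_connectivity_summary`: `whole_brain` (mean of
#'   the upper-triangle entries) and `nodal_strength`, a tibble with one row
#'   per region (off-diagonal row sums).
#' @export
connectivity_summary <- function(m) {
  mat <- if (inherits(m, "meg_connectivity")) m$matrix else m
  roi <- if (inherits(m, "meg_connectivity")) {
    m$roi_names %||% sprintf("R%03d", seq_len(nrow(mat)))
  } else {
    rownames(mat) %||% sprintf("R%03d", seq_len(nrow(mat)))
  }
  structure(
    list(
      band = if (inherits(m, "meg_connectivity")) m$band else NA_character_,
      whole_brain = mean(mat[upper.tri(mat)]),
      nodal_strength = tibble::tibble(
        roi = roi, strength = rowSums(mat) - diag(mat)
      )
    ),
    class = "meg_connectivity_summary"
  )
}
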