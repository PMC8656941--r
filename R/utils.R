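#' @importFrom rlang abort warn .data
#' @importFrom stats cor cov fft mad median pf pt quantile rnorm runif rbinom
#'   sd var lm anova resid approx setNames complete.cases p.adjust
#' @importFrom utils head tail
NULL

# Fan a single pipeline seed out to per-stage streams.  Offsets are fixed and
# documented so a stage re-run in isolation sees the same stream as inside
# run_pipeline().  Result stays well inside 32-bit integer range.
fan_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    simulate = 1L, forward = 2L, cohort = 3L, beamform = 4L, epochs = 5L,
    spectral = 6L, connectivity = 7L, stats = 8L, plsc_perm = 9L,
    plsc_boot = 10L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown stage: ", stage))
  as.integer((abs(seed) %% 2000003L) * 1000L + offsets[[stage]])
}

# robust per-region location/scale used by epoch quality scoring
robust_center_scale <- function(data) {
  ctr <- apply(data, 1L, median)
  scl <- apply(data, 1L, mad)
  list(center = ctr, scale = scl)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_matrix_ts <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}
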