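#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a subject spectral profile
#'
#' @param x A `meg_spectral` object.
#' @param ... Unused.
#' @return Long tibble: `subject_id`, `roi`, `band`, `rbp`, `total_power`,
#'   `ipf`.
#' @export
tidy.meg_spectral <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    roi = rep(x$roi_names, times = length(x$band)),
    band = rep(x$band, each = length(x$roi_names)),
    rbp = as.vector(x$rbp),
    total_power = rep(x$total_power, times = length(x$band)),
    ipf = x$ipf
  )
}

#' Tidy a connectivity matrix into an edge list
#'
#' @param x A `meg_connectivity` object.
#' @param ... Unused.
#' @return Tibble of the upper-triangle edges: `band`, `from`, `to`,
#'   `aecc`.
#' @export
tidy.meg_connectivity <- function(x, ...) {
  ut <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    band = x$band,
    from = x$roi_names[ut[, 1L]],
    to = x$roi_names[ut[, 2L]],
    aecc = x$matrix[ut]
  )
}

#' Tidy a Spearman correlation grid
#'
#' @param x A `meg_spearman` object.
#' @param ... Unused.
#' @return Tibble of unique variable pairs: `var1`, `var2`, `rho`, `p`,
#'   `n`, `significant` (FDR).
#' @export
tidy.meg_spearman <- function(x, ...) {
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$variables[ut[, 1L]],
    var2 = x$variables[ut[, 2L]],
    rho = x$rho[ut],
    p = x$p[ut],
    n = x$n[ut],
    significant = x$fdr_mask[ut]
  )
}

#' Tidy PLSC loadings
#'
#' @param x A `meg_plsc` object.
#' @param ... Unused.
#' @return Tibble with one row per variable and component: `block`
#'   (`brain`/`cognitive`), `variable`, `component`, `salience`, `loading`,
#'   and, after [plsc_bootstrap()], `boot_z` and `reliable`.
#' @export
tidy.meg_plsc <- function(x, ...) {
  nc <- length(x$singular_values)
  one_block <- function(block, names, sal, load, bz, rel) {
    out <- tibble::tibble(
      block = block,
      variable = rep(names, times = nc),
      component = rep(seq_len(nc), each = length(names)),
      salience = as.vector(sal),
      loading = as.vector(load)
    )
    if (!is.null(bz)) {
      out$boot_z <- as.vector(bz)
      out$reliable <- as.vector(rel)
    }
    out
  }
  dplyr::bind_rows(
    one_block("brain", x$x_names, x$saliences_x, x$loadings_x,
              x$boot_z_x, x$reliable_x),
    one_block("cognitive", x$y_names, x$saliences_y, x$loadings_y,
              x$boot_z_y, x$reliable_y)
  )
}

#' Component-level PLSC summary
#'
#' @param x A `meg_plsc` object.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`,
#'   `singular_value`, `r_squared`, and, after [plsc_permutation()], `p`,
#'   `p_fdr`, `significant`.
#' @export
glance.meg_plsc <- function(x, ...) {
  out <- tibble::tibble(
    component = seq_along(x$singular_values),
    singular_value = x$singular_values,
    r_squared = x$r_squared
  )
  if (!is.null(x$perm_p)) {
    out$p <- x$perm_p
    out$p_fdr <- x$perm_p_fdr
    out$significant <- x$significant
  }
  out
}

#' @export
print.meg_plsc <- function(x, ...) {
  cat(sprintf(
    "PLSC fit: %d x %d vs %d x %d, %d components\n",
    x$n, length(x$x_names), x$n, length(x$y_names),
    length(x$singular_values)
  ))
  print(glance(x))
  invisible(x)
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf(
    "MEG recording '%s': %d regions x %d samples at %g Hz (%.1f s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' @export
print.meg_epochs <- function(x, ...) {
  cat(sprintf(
    "Epoch set '%s': %d epochs of %d samples (%s)\n",
    x$subject_id, length(x$epochs), x$epoch_len,
    if (isTRUE(x$selected)) "selected" else "candidates"
  ))
  invisible(x)
}
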