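#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_line
#'   geom_point geom_hline scale_fill_gradient2 facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a subject's band power profile
#'
#' Region-averaged relative band power per band, with the subject's peak
#' frequency in the title.
#'
#' @param object A `meg_spectral` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meg_spectral <- function(object, ...) {
  df <- tibble::tibble(
    band = factor(object$band, levels = object$band),
    rbp = colMeans(object$rbp)
  )
  ggplot(df, aes(x = .data$band, y = .data$rbp)) +
    geom_col(fill = "steelblue") +
    labs(
      title = sprintf("%s - whole-brain relative band power (IPF %.1f Hz)",
                      object$subject_id, object$ipf),
      x = NULL, y = "relative band power"
    ) +
    theme_minimal()
}

#' Heatmap of a connectivity matrix
#'
#' @param object A `meg_connectivity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meg_connectivity <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::rename(df, from = "to", to = "from")
  # symmetric display
  full <- dplyr::bind_rows(df, df2[names(df)])
  ggplot(full, aes(x = .data$from, y = .data$to, fill = .data$aecc)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1) * max(abs(full$aecc))) +
    labs(title = sprintf("AECc, %s band", object$band), x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Loading plot for a PLSC component
#'
#' Brain and cognitive loadings side by side; after [plsc_bootstrap()],
#' reliable loadings (|bootstrap z| above threshold) are highlighted.
#'
#' @param object A `meg_plsc` object.
#' @param component Component to show (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meg_plsc <- function(object, component = 1L, ...) {
  df <- dplyr::filter(tidy(object), .data$component == !!component)
  df$variable <- factor(df$variable, levels = unique(df$variable))
  if (!"reliable" %in% names(df)) df$reliable <- NA
  p <- ggplot(df, aes(x = .data$variable, y = .data$loading,
                      fill = .data$reliable)) +
    geom_col() +
    facet_wrap(~block, scales = "free_x") +
    labs(
      title = sprintf("PLSC component %d loadings", component),
      x = NULL, y = "loading"
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  p
}

#' Correlation-grid plot with FDR marks
#'
#' @param object A `meg_spearman` object.
#' @param ... Unused.
#' @return A ggplot object; significant cells (FDR) are starred.
#' @export
autoplot.meg_spearman <- function(object, ...) {
  df <- tidy(object)
  df$label <- sprintf("%.2f%s", df$rho, ifelse(df$significant, "*", ""))
  ggplot(df, aes(x = .data$var1, y = .data$var2, fill = .data$rho)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "rho") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
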