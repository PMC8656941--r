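#' Covariate-adjusted group comparison (ANCOVA / nested GLM F-test)
#'
#' Tests a binary group effect on one feature within a general linear model:
#' the full model `y ~ group + covariates` is compared with the reduced
#' model `y ~ covariates` by the nested-model F statistic on 1 and
#' `n - k - 2` degrees of freedom.  The accompanying effect size is Cohen's
#' d between the groups' residual distributions after regressing out the
#' covariates only (see [cohens_d_residual()]).
#'
#' @param data Data frame with the response, group and covariate columns.
#' @param response Name of the response column.
#' @param group Name of the binary group column (factor or character with
#'   exactly two levels, both non-empty).
#' @param covariates Character vector of covariate column names (may be
#'   empty).  Non-numeric covariates (e.g. gender) enter as indicator
#'   variables.
#' @return One-row tibble: `feature`, `F`, `df1`, `df2`, `p`, `cohens_d`,
#'   `d_contrast` (which group minus which).  Rows with missing values in
#'   any used column are dropped.
#' @export
ancova_group_test <- function(data, response, group, covariates = character()) {
  used <- c(response, group, covariates)
  stopifnot(all(used %in% names(data)))
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  d[[group]] <- droplevels(factor(d[[group]]))
  lv <- levels(d[[group]])
  if (length(lv) != 2L) abort("group must have exactly two non-empty levels")
  k <- length(covariates)
  if (nrow(d) <= k + 2L) abort("too few complete observations for the model")

  rhs_red <- if (k) paste(covariates, collapse = " + ") else "1"
  f_full <- stats::reformulate(c(group, covariates), response)
  f_red <- stats::as.formula(paste(response, "~", rhs_red))
  fit_full <- lm(f_full, data = d)
  if (fit_full$rank < ncol(stats::model.matrix(fit_full))) {
    abort("rank-deficient design: group and covariates are collinear")
  }
  fit_red <- lm(f_red, data = d)
  an <- anova(fit_red, fit_full)
  Fv <- an$F[2L]
  p <- an$`Pr(>F)`[2L]
  dres <- cohens_d_residual(d, response, group, covariates)

  tibble::tibble(
    feature = response, F = Fv, df1 = an$Df[2L], df2 = an$Res.Df[2L],
    p = p, cohens_d = dres,
    d_contrast = paste(lv[1L], "-", lv[2L]),
    n = nrow(d)
  )
}

#' Cohen's d between covariate-adjusted residual distributions
#'
#' Residuals of the covariate-only model are split by group and compared as
#' `(mean_A - mean_B) / s_pooled`, with the pooled standard deviation
#' weighted by `n_A - 1` and `n_B - 1`.  The sign convention is first group
#' level minus second (alphabetical for character groups); the contrast is
#' reported by [ancova_group_test()].
#'
#' @inheritParams ancova_group_test
#' @return Signed Cohen's d.
#' @export
cohens_d_residual <- function(data, response, group, covariates = character()) {
  used <- c(response, group, covariates)
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  g <- droplevels(factor(d[[group]]))
  if (nlevels(g) != 2L) abort("group must have exactly two non-empty levels")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  res <- resid(lm(stats::as.formula(paste(response, "~", rhs)), data = d))
  a <- res[g == levels(g)[1L]]
  b <- res[g == levels(g)[2L]]
  sp <- sqrt(((length(a) - 1L) * var(a) + (length(b) - 1L) * var(b)) /
    (length(a) + length(b) - 2L))
  if (sp <= 1e-10 * max(abs(d[[response]]), 1)) {
    abort("zero pooled standard deviation")
  }
  (mean(a) - mean(b)) / sp
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`: with sorted p-values `p(1) <= ... <=
#' p(m)`, all hypotheses up to the largest `k` with `p(k) <= k q / m` are
#' rejected.  Adjusted p-values come from [stats::p.adjust()] with method
#' `"BH"`.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical, in input order) and `p_adj`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) abort("empty p-value vector")
  stopifnot(all(pvals > 0 & pvals <= 1, na.rm = TRUE))
  m <- length(pvals)
  ord <- order(pvals)
  ps <- pvals[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  reject <- logical(m)
  if (is.finite(k)) reject[ord[seq_len(k)]] <- TRUE
  reject[is.na(pvals)] <- NA
  list(reject = reject, p_adj = p.adjust(pvals, method = "BH"))
}

#' Feature-wise group comparison with FDR control
#'
#' Runs [ancova_group_test()] over a set of feature columns and controls the
#' false discovery rate across them with [bh_fdr()].
#'
#' @inheritParams ancova_group_test
#' @param features Character vector of feature column names.
#' @param q FDR level (default 0.05).
#' @return Tibble with one row per feature: the ANCOVA columns plus `p_adj`
#'   and `significant`.
#' @export
group_compare <- function(data, features, group, covariates = character(),
                          q = 0.05) {
  res <- purrr::map_dfr(
    features, ancova_group_test,
    data = data, group = group, covariates = covariates
  )
  fdr <- bh_fdr(res$p, q)
  res$p_adj <- fdr$p_adj
  res$significant <- fdr$reject
  res
}

#' Spearman rank-correlation grid with FDR control
#'
#' Pairwise Spearman correlations (average ranks; midranks for ties) over
#' the selected columns with pairwise deletion of missing values; p-values
#' from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`; FDR
#' control across the unique off-diagonal pairs.
#'
#' @param data Data frame.
#' @param vars Columns to correlate (default: all numeric columns).
#' @param q FDR level (default 0.05).
#' @param min_pairs Minimum complete pairs per cell (default 4); cells with
#'   fewer are `NA`.
#' @return Object of class `meg_spearman`: `variables`, matrices `rho`,
#'   `p`, `n`, and logical `fdr_mask`.  Constant variables yield `NA` cells
#'   with a warning.
#' @export
spearman_grid <- function(data, vars = NULL, q = 0.05, min_pairs = 4L) {
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1L))]
  x <- as.matrix(data[vars])
  m <- length(vars)
  rho <- p <- nmat <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(p) <- 0
  const_seen <- FALSE
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ok <- stats::complete.cases(x[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < min_pairs) next
      xi <- x[ok, i]
      xj <- x[ok, j]
      if (sd(xi) == 0 || sd(xj) == 0) {
        const_seen <- TRUE
        next
      }
      r <- cor(xi, xj, method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      pij <- if (abs(r) >= 1) 0 else {
        tv <- r * sqrt((n - 2) / (1 - r^2))
        2 * pt(-abs(tv), df = n - 2)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  if (const_seen) warn("constant variable(s): undefined correlation cells set to NA")
  up <- upper.tri(p)
  mask <- matrix(FALSE, m, m, dimnames = dimnames(p))
  pv <- p[up]
  if (any(is.finite(pv))) {
    fin <- which(is.finite(pv))
    rej <- bh_fdr(pmax(pv[fin], .Machine$double.xmin), q)$reject
    tmp <- logical(length(pv))
    tmp[fin] <- rej
    mask[up] <- tmp
    mask <- mask | t(mask)
  }
  structure(
    list(variables = vars, rho = rho, p = p, n = nmat, fdr_mask = mask, q = q),
    class = "meg_spearman"
  )
}

#' Majority-vote assignment of regions to resting-state networks
#'
#' Assigns each region to the resting-state network with the largest label
#' count; ties are broken by the fixed network order VIS < SM < DA < VA <
#' FP < DMN < LIM and flagged.
#'
#' @param label_counts Regions x networks matrix or data frame of
#'   non-negative counts (a `roi` column is used for names if present).
#' @param networks Network order used for columns and tie-breaking.
#' @return Tibble of class `meg_rsn_map`: `roi`, `network` (factor in fixed
#'   order), `tie`.
#' @export
rsn_majority_vote <- function(label_counts,
                              networks = c("VIS", "SM", "DA", "VA", "FP", "DMN", "LIM")) {
  roi <- NULL
  if (is.data.frame(label_counts)) {
    if ("roi" %in% names(label_counts)) {
      roi <- label_counts$roi
      label_counts <- label_counts[setdiff(names(label_counts), "roi")]
    }
    label_counts <- as.matrix(label_counts)
  }
  stopifnot(all(colnames(label_counts) %in% networks))
  if (any(label_counts < 0)) abort("label counts must be non-negative")
  if (any(rowSums(label_counts) == 0)) abort("region with all-zero label counts")
  roi <- roi %||% rownames(label_counts) %||%
    sprintf("R%03d", seq_len(nrow(label_counts)))
  cnt <- label_counts[, intersect(networks, colnames(label_counts)), drop = FALSE]
  win <- unname(apply(cnt, 1L, function(r) colnames(cnt)[which.max(r)]))
  tie <- unname(apply(cnt, 1L, function(r) sum(r == max(r)) > 1L))
  structure(
    tibble::tibble(roi = roi, network = factor(win, levels = networks), tie = tie),
    class = c("meg_rsn_map", "tbl_df", "tbl", "data.frame")
  )
}

#' Percentage effect-size contribution per resting-state network
#'
#' Among the regions with a significant group difference, sums the absolute
#' effect sizes within each network and normalizes by the sum over all
#' significant regions, in percent.  Percentages sum to 100 whenever any
#' region is significant.
#'
#' @param d Numeric vector of per-region effect sizes (Cohen's d).
#' @param significant Logical vector marking regions that survive FDR.
#' @param map A `meg_rsn_map` (or tibble with `roi`, `network`) aligned with
#'   `d`.
#' @return Tibble with `network` and `contribution_pct` (all networks
#'   present; zeros and a warning when no region is significant).
#' @export
rsn_effect_contribution <- function(d, significant, map) {
  stopifnot(length(d) == length(significant), length(d) == nrow(map))
  networks <- levels(map$network) %||% unique(as.character(map$network))
  sig_d <- abs(d) * (significant %in% TRUE)
  tot <- sum(sig_d)
  if (tot == 0) {
    warn("no significant region: all contributions are zero")
    pct <- setNames(numeric(length(networks)), networks)
  } else {
    sums <- tapply(sig_d, factor(as.character(map$network), levels = networks), sum)
    sums[is.na(sums)] <- 0
    pct <- 100 * sums / tot
  }
  tibble::tibble(network = factor(networks, levels = networks),
                 contribution_pct = as.numeric(pct))
}

#' Composite cognitive-activity questionnaire scores
#'
#' From item-level responses (integers 1--5, one per activity and age),
#' computes the current cognitive activity score cCAQ (mean over activities
#' at current age) and the past score pCAQ (mean over activities and the
#' four past ages 6, 12, 18 and 40 years).  Missing items are excluded from
#' the means and counted.
#'
#' @param responses Data frame containing CAQ item columns named
#'   `caq_p06_a*`, `caq_p12_a*`, `caq_p18_a*`, `caq_p40_a*` (past ages) and
#'   `caq_cur_a*` (current age), as produced by [simulate_cohort()], plus
#'   optionally `subject_id`.
#' @return Tibble: `subject_id` (if present), `cCAQ`, `pCAQ`, `n_current`,
#'   `n_past` (non-missing item counts).  A composite with no observed item
#'   is `NA`.
#' @export
caq_scores <- function(responses) {
  cur_cols <- grep("^caq_cur_", names(responses), value = TRUE)
  past_cols <- grep("^caq_p(06|12|18|40)_", names(responses), value = TRUE)
  if (!length(cur_cols) || !length(past_cols)) {
    abort("no CAQ item columns found (expected caq_cur_* and caq_p06/p12/p18/p40_*)")
  }
  vals <- as.matrix(responses[c(cur_cols, past_cols)])
  if (any(vals < 1 | vals > 5, na.rm = TRUE)) {
    abort("CAQ responses must be integers on the 1-5 frequency scale")
  }
  cur <- as.matrix(responses[cur_cols])
  pst <- as.matrix(responses[past_cols])
  out <- tibble::tibble(
    cCAQ = rowMeans(cur, na.rm = TRUE),
    pCAQ = rowMeans(pst, na.rm = TRUE),
    n_current = rowSums(!is.na(cur)),
    n_past = rowSums(!is.na(pst))
  )
  out$cCAQ[out$n_current == 0L] <- NA_real_
  out$pCAQ[out$n_past == 0L] <- NA_real_
  if ("subject_id" %in% names(responses)) {
    out <- dplyr::bind_cols(
      tibble::tibble(subject_id = responses$subject_id), out
    )
  }
  out
}
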