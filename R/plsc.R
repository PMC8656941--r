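#' k-nearest-neighbour imputation of a numeric table
#'
#' Fills each missing cell with the mean of the same variable over the k
#' nearest subjects, where distance is the Euclidean distance over the
#' z-scored, mutually observed variables of the two subjects and neighbours
#' are restricted to subjects observing the target variable.  Distance ties
#' are broken by row order, making the result deterministic.
#'
#' @param data Data frame; only numeric columns are imputed (others pass
#'   through).
#' @param k Number of neighbours (default 4).
#' @return The completed data frame (same class and column order).
#' @export
impute_knn <- function(data, k = 4L) {
  num <- vapply(data, is.numeric, logical(1L))
  x <- as.matrix(data[num])
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of subjects")
  if (!anyNA(x)) return(data)
  if (any(colSums(!is.na(x)) == 0L)) {
    abort("variable missing for all subjects cannot be imputed")
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    abort("subject with no observed variable cannot be imputed")
  }
  mu <- colMeans(x, na.rm = TRUE)
  sg <- apply(x, 2L, sd, na.rm = TRUE)
  sg[sg == 0 | is.na(sg)] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sg, "/")

  filled <- x
  for (i in which(rowSums(is.na(x)) > 0L)) {
    d2 <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      shared <- which(!is.na(z[i, ]) & !is.na(z[j, ]))
      if (!length(shared)) return(Inf)
      sum((z[i, shared] - z[j, shared])^2)
    }, numeric(1L))
    for (v in which(is.na(x[i, ]))) {
      cand <- which(!is.na(x[, v]) & is.finite(d2))
      if (!length(cand)) next
      nb <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
      filled[i, v] <- mean(x[nb, v])
    }
  }
  data[num] <- tibble::as_tibble(filled)
  data
}

#' Partial least squares correlation of two variable blocks
#'
#' Columns of both blocks are z-scored, the cross-block correlation matrix
#' `Rxy = X' Y / (n - 1)` is decomposed by SVD `Rxy = U S V'`, giving
#' paired, block-wise orthonormal brain and cognitive saliences that
#' maximize cross-block covariance.  Latent scores are the projections of
#' the standardized blocks onto the saliences; loadings are the Pearson
#' correlations between the original columns and their own block's latent
#' scores; per component, `r_squared` is the squared correlation between
#' the two latent score vectors.
#'
#' @param x,y Data frames or matrices (subjects x variables) without
#'   missing values (see [impute_knn()]); every column must have positive
#'   variance.
#' @return Object of class `meg_plsc`: `singular_values`, `saliences_x`,
#'   `saliences_y`, `scores_x`, `scores_y`, `loadings_x`, `loadings_y`,
#'   `r_squared`, names and standardization records; `min(p, q)`
#'   components.
#' @seealso [plsc_permutation()], [plsc_bootstrap()], [tidy.meg_plsc()],
#'   [glance.meg_plsc()].
#' @export
plsc <- function(x, y) {
  X <- as.matrix(as.data.frame(x))
  Y <- as.matrix(as.data.frame(y))
  if (nrow(X) != nrow(Y)) abort("blocks must have the same number of subjects")
  n <- nrow(X)
  if (n <= 2L) abort("need more than two subjects")
  if (anyNA(X) || anyNA(Y)) abort("blocks contain missing values; impute first")
  zx <- scale(X)
  zy <- scale(Y)
  if (any(attr(zx, "scaled:scale") == 0) || any(attr(zy, "scaled:scale") == 0)) {
    abort("zero-variance column in one of the blocks")
  }
  Rxy <- crossprod(zx, zy) / (n - 1)
  sv <- svd(Rxy)
  nc <- min(ncol(X), ncol(Y))
  U <- sv$u[, seq_len(nc), drop = FALSE]
  V <- sv$v[, seq_len(nc), drop = FALSE]
  Lx <- zx %*% U
  Ly <- zy %*% V
  structure(
    list(
      singular_values = sv$d[seq_len(nc)],
      saliences_x = U, saliences_y = V,
      scores_x = Lx, scores_y = Ly,
      loadings_x = cor(X, Lx), loadings_y = cor(Y, Ly),
      r_squared = vapply(seq_len(nc), function(c) cor(Lx[, c], Ly[, c])^2,
                         numeric(1L)),
      x_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
      y_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
      center_x = attr(zx, "scaled:center"), scale_x = attr(zx, "scaled:scale"),
      center_y = attr(zy, "scaled:center"), scale_y = attr(zy, "scaled:scale"),
      n = n, x = X, y = Y
    ),
    class = "meg_plsc"
  )
}

#' Permutation test of PLSC components
#'
#' Rows of the cognitive block are permuted, the decomposition is
#' recomputed, and each component's p-value is the exceedance probability
#' of its rank-matched singular value:
#' `p_c = (1 + #\{s*_c >= s_c\}) / (1 + n_perm)`, FDR-corrected across
#' components with [bh_fdr()].
#'
#' @param fit A `meg_plsc` object.
#' @param n_perm Number of permutations (default 1000; at least 100).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed.
#' @return The fit, augmented with `perm_p`, `perm_p_fdr`, `significant`
#'   and `n_perm`.
#' @export
plsc_permutation <- function(fit, n_perm = 1000L, q = 0.05, seed = 1L) {
  stopifnot(inherits(fit, "meg_plsc"))
  if (n_perm < 100L) abort("n_perm must be at least 100")
  set.seed(fan_seed(seed, "plsc_perm"))
  zx <- scale(fit$x)
  zy <- scale(fit$y)
  n <- fit$n
  nc <- length(fit$singular_values)
  exceed <- numeric(nc)
  for (b in seq_len(n_perm)) {
    d <- svd(crossprod(zx, zy[sample.int(n), , drop = FALSE]) / (n - 1),
             nu = 0, nv = 0)$d[seq_len(nc)]
    exceed <- exceed + (d >= fit$singular_values)
  }
  fit$perm_p <- (1 + exceed) / (1 + n_perm)
  fdr <- bh_fdr(fit$perm_p, q)
  fit$perm_p_fdr <- fdr$p_adj
  fit$significant <- fdr$reject
  fit$n_perm <- n_perm
  fit
}

# align a resampled decomposition to the reference: greedy match on the
# summed absolute inner products of the stacked saliences, then sign-flip
align_components <- function(U, V, U0, V0) {
  S <- abs(crossprod(rbind(U, V), rbind(U0, V0)))
  nc <- ncol(U0)
  ord <- integer(nc)
  used <- logical(nrow(S))
  for (c0 in order(-apply(S, 2L, max))) {
    j <- which.max(ifelse(used, -Inf, S[, c0]))
    ord[c0] <- j
    used[j] <- TRUE
  }
  sgn <- vapply(seq_len(nc), function(c0) {
    s <- sum(U[, ord[c0]] * U0[, c0]) + sum(V[, ord[c0]] * V0[, c0])
    if (s < 0) -1 else 1
  }, numeric(1L))
  list(order = ord, sign = sgn)
}

#' Bootstrap reliability of PLSC loadings
#'
#' Subjects are resampled with replacement (paired rows of both blocks), the
#' decomposition is recomputed, components are aligned to the original fit
#' by maximal absolute salience inner product (with sign matching), and the
#' bootstrap standard score of every loading is the original loading
#' divided by its bootstrap standard deviation (bootstrap-ratio
#' convention).  Loadings with `|z| > z_thresh` are flagged reliable.
#' Degenerate resamples (constant column) are skipped and counted.
#'
#' @param fit A `meg_plsc` object.
#' @param n_boot Number of resamples (default 500; at least 100).
#' @param z_thresh Reliability threshold on `|z|` (default 3).
#' @param z_cap Cap on `|z|` for zero-bootstrap-variance loadings
#'   (default 100).
#' @param seed Integer seed.
#' @return The fit, augmented with `boot_z_x`, `boot_z_y` (variables x
#'   components), `reliable_x`, `reliable_y`, `n_boot_used`.
#' @export
plsc_bootstrap <- function(fit, n_boot = 500L, z_thresh = 3, z_cap = 100,
                           seed = 1L) {
  stopifnot(inherits(fit, "meg_plsc"))
  if (n_boot < 100L) abort("n_boot must be at least 100")
  set.seed(fan_seed(seed, "plsc_boot"))
  n <- fit$n
  nc <- length(fit$singular_values)
  bx <- array(NA_real_, c(ncol(fit$x), nc, n_boot))
  by <- array(NA_real_, c(ncol(fit$y), nc, n_boot))
  used <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    Xb <- fit$x[idx, , drop = FALSE]
    Yb <- fit$y[idx, , drop = FALSE]
    if (any(apply(Xb, 2L, sd) == 0) || any(apply(Yb, 2L, sd) == 0)) next
    fb <- plsc(Xb, Yb)
    al <- align_components(fb$saliences_x, fb$saliences_y,
                           fit$saliences_x, fit$saliences_y)
    used <- used + 1L
    bx[, , b] <- sweep(fb$loadings_x[, al$order, drop = FALSE], 2L, al$sign, "*")
    by[, , b] <- sweep(fb$loadings_y[, al$order, drop = FALSE], 2L, al$sign, "*")
  }
  if (used < n_boot) {
    warn(sprintf("%d degenerate resample(s) skipped", n_boot - used))
  }
  sd_x <- apply(bx, c(1L, 2L), sd, na.rm = TRUE)
  sd_y <- apply(by, c(1L, 2L), sd, na.rm = TRUE)
  zx <- fit$loadings_x / sd_x
  zy <- fit$loadings_y / sd_y
  clamp <- function(z) {
    z[!is.finite(z)] <- sign(z[!is.finite(z)]) * z_cap
    z[is.na(z)] <- 0
    pmin(pmax(z, -z_cap), z_cap)
  }
  fit$boot_z_x <- clamp(zx)
  fit$boot_z_y <- clamp(zy)
  fit$reliable_x <- abs(fit$boot_z_x) > z_thresh
  fit$reliable_y <- abs(fit$boot_z_y) > z_thresh
  fit$n_boot_used <- used
  fit$z_thresh <- z_thresh
  fit
}
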