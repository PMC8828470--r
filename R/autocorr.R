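#' Spatial autocorrelation per gene (Moran's I / Geary's C)
#'
#' Global spatial autocorrelation of each gene over a spatial weights graph:
#'
#' Moran's I
#' \deqn{I = \frac{n}{W} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' Geary's C
#' \deqn{C = \frac{(n-1) \sum_{ij} w_{ij} (x_i - x_j)^2}{2 W \sum_i z_i^2}}
#'
#' with \eqn{z_i = x_i - \bar x}, weights \eqn{w_{ij}} the (optionally
#' row-standardized) connectivity and \eqn{W = \sum w_{ij}}. P-values are
#' one-sided toward spatial clustering (large I / small C) by default, from
#' either a label permutation test with the +1 correction or the analytic
#' normality approximation (`E[I] = -1/(n-1)`, `E[C] = 1`); genes are
#' Benjamini-Hochberg adjusted jointly. Zero-variance genes are reported as
#' `NaN` with `degenerate = TRUE`.
#'
#' @param dataset A [spatial_dataset].
#' @param graph A [spatial_graph].
#' @param mode `"moran"` or `"geary"`.
#' @param genes Optional character vector of genes (default: all).
#' @param n_perms Number of permutations; `0` switches to the analytic
#'   normality p-value.
#' @param seed Permutation seed (required when `n_perms > 0`).
#' @param row_standardize Row-standardize the weights (default `TRUE`, the
#'   conventional scaling putting I on about `[-1, 1]`).
#' @param two_sided Two-sided p-values instead of the one-sided clustering
#'   alternative.
#' @return An `autocorr_result` tibble: `gene`, `statistic`, `expected_null`,
#'   `pvalue`, `pvalue_adj`, `method`, `degenerate`.
#' @export
spatial_autocorr <- function(dataset, graph, mode = c("moran", "geary"),
                             genes = NULL, n_perms = 1000, seed = NULL,
                             row_standardize = TRUE, two_sided = FALSE) {
  mode <- match.arg(mode)
  if (n_perms > 0 && is.null(seed)) {
    abort("Permutation test needs a seed.", class = "spomics_error")
  }
  genes <- genes %||% dataset$var_ids
  missing <- setdiff(genes, dataset$var_ids)
  if (length(missing)) abort(paste0("Unknown genes: ", paste(head(missing, 5), collapse = ", ")),
                             class = "spomics_error")
  W <- graph$connectivity
  if (!length(W@x)) abort("Graph has no edges.", class = "spomics_error")
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    W <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% W
  }
  Wsum <- sum(W)
  n <- nrow(W)
  tr <- Matrix::mat2triplet(W)
  X <- as.matrix(dataset$X[, genes, drop = FALSE])

  stat_of <- function(xv) {
    z <- xv - mean(xv)
    ss <- sum(z^2)
    if (ss == 0) return(NaN)
    if (mode == "moran") {
      (n / Wsum) * sum(z * as.numeric(W %*% z)) / ss
    } else {
      (n - 1) * sum(tr$x * (xv[tr$i] - xv[tr$j])^2) / (2 * Wsum * ss)
    }
  }
  obs <- unname(apply(X, 2L, stat_of))
  degenerate <- !is.finite(obs)
  e0 <- if (mode == "moran") -1 / (n - 1) else 1

  pv <- rep(NaN, length(genes))
  if (n_perms > 0) {
    method <- "permutation"
    pv[!degenerate] <- with_seed(seed, vapply(which(!degenerate), function(g) {
      xv <- X[, g]
      ps <- vapply(seq_len(n_perms), function(p) stat_of(sample(xv)), numeric(1))
      extreme <- if (two_sided) abs(ps - e0) >= abs(obs[g] - e0)
      else if (mode == "moran") ps >= obs[g] else ps <= obs[g]
      (1 + sum(extreme)) / (1 + n_perms)
    }, numeric(1)))
  } else {
    method <- "analytic"
    v <- analytic_variance(W, n, mode)
    zscore <- (obs - e0) / sqrt(v)
    pv <- if (two_sided) 2 * pnorm(abs(zscore), lower.tail = FALSE)
    else if (mode == "moran") pnorm(zscore, lower.tail = FALSE)
    else pnorm(zscore)
    pv[degenerate] <- NaN
  }
  padj <- rep(NaN, length(genes))
  padj[!degenerate] <- p.adjust(pv[!degenerate], method = "BH")
  tbl <- tibble(gene = genes, statistic = obs, expected_null = e0,
                pvalue = pv, pvalue_adj = padj, method = method,
                degenerate = degenerate)
  new_spomics_tbl(tbl, "autocorr_result",
                  list(mode = mode, n_perms = as.integer(n_perms),
                       seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                       row_standardized = row_standardize,
                       two_sided = two_sided))
}

# Normality-approximation variances (the standard moments; see any spatial
# statistics text). S1 = 1/2 sum (w_ij + w_ji)^2, S2 = sum_i (w_i. + w_.i)^2.
analytic_variance <- function(W, n, mode) {
  Wg <- methods::as(W, "generalMatrix")
  S0 <- sum(Wg)
  Wt <- Matrix::t(Wg)
  S1 <- sum((Wg + Wt)@x^2) / 2
  S2 <- sum((Matrix::rowSums(Wg) + Matrix::colSums(Wg))^2)
  if (mode == "moran") {
    (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - (1 / (n - 1))^2
  } else {
    ((2 * S1 + S2) * (n - 1) - 4 * S0^2) / (2 * (n + 1) * S0^2)
  }
}
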