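#' Read a ligand-receptor interaction table
#'
#' CSV with columns `source`, `target`; multi-subunit complexes are encoded
#' as underscore-joined gene lists (`"L1_L2"`). Duplicate rows are dropped;
#' subunit order is preserved.
#'
#' @param path CSV path.
#' @return An `interaction_table` tibble: `source`, `target` (the original
#'   strings) plus list-columns `source_genes`, `target_genes`.
#' @export
read_interactions <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("source", "target") %in% names(df))) {
    abort("Interaction CSV must have columns source, target.", class = "spomics_schema_error")
  }
  interaction_table(df$source, df$target)
}

#' @rdname read_interactions
#' @param source,target Character vectors of (underscore-joined) complex
#'   specifications.
#' @export
interaction_table <- function(source, target) {
  df <- tibble(source = as.character(source), target = as.character(target))
  df <- dplyr::distinct(df)
  df$source_genes <- strsplit(df$source, "_", fixed = TRUE)
  df$target_genes <- strsplit(df$target, "_", fixed = TRUE)
  bad <- vapply(c(df$source_genes, df$target_genes),
                function(g) length(g) == 0 || any(!nzchar(g)), logical(1))
  if (any(bad)) abort("Empty gene name inside a complex specification.", class = "spomics_schema_error")
  class(df) <- c("interaction_table", class(df))
  df
}

#' Permutation ligand-receptor test across cluster pairs
#'
#' CellphoneDB-style test: for every interaction (ligand complex, receptor
#' complex) and ordered cluster pair (sender, receiver), the statistic is the
#' mean of (mean ligand-complex expression over sender cells, mean
#' receptor-complex expression over receiver cells). Complex expression per
#' cell is the minimum (default) or mean over subunits. The null distribution
#' comes from `n_perms` uniform label shuffles; `p = (1 + #[m_perm >= m_obs])
#' / (1 + n_perms)`. Pairs where either complex is expressed (> 0) in fewer
#' than `expr_frac_threshold` of its cluster's cells keep their mean but get
#' `p = NaN`; Benjamini-Hochberg adjustment runs over the tested
#' (non-`NaN`) hypotheses. Expression is used as-is; log-normalized input is
#' recommended.
#'
#' @param dataset A [spatial_dataset].
#' @param label_key Categorical column with at least 2 clusters.
#' @param interactions An `interaction_table` (see [read_interactions()]).
#' @param n_perms Number of label permutations.
#' @param seed Permutation seed (identical seed gives bit-identical output).
#' @param complex_policy `"min"` or `"mean"` subunit reduction.
#' @param expr_frac_threshold Minimum expressing-cell fraction per cluster.
#' @return A `ligrec_result` tibble: `source`, `target`, `cluster_1`
#'   (sender), `cluster_2` (receiver), `mean`, `pvalue`, `pvalue_adj`.
#' @export
ligrec_test <- function(dataset, label_key, interactions, n_perms = 1000,
                        seed, complex_policy = c("min", "mean"),
                        expr_frac_threshold = 0.1) {
  complex_policy <- match.arg(complex_policy)
  labels <- get_labels(dataset, label_key)
  lev <- levels(labels)
  k <- length(lev)
  if (k < 2) abort("ligrec_test needs at least 2 clusters.", class = "spomics_error")
  if (!inherits(interactions, "interaction_table")) {
    abort("`interactions` must be an interaction_table.", class = "spomics_error")
  }
  present <- vapply(seq_len(nrow(interactions)), function(r) {
    all(c(interactions$source_genes[[r]], interactions$target_genes[[r]]) %in%
          dataset$var_ids)
  }, logical(1))
  if (any(!present)) {
    warn(sprintf("%d interaction(s) with genes absent from the dataset dropped.",
                 sum(!present)))
  }
  ia <- interactions[present, ]
  if (!nrow(ia)) abort("No interaction left after gene filtering.", class = "spomics_error")
  X <- as.matrix(dataset$X)
  reduce <- function(gene_sets) {
    vapply(gene_sets, function(gs) {
      sub <- X[, gs, drop = FALSE]
      if (complex_policy == "min") {
        apply(sub, 1L, min)
      } else {
        rowMeans(sub)
      }
    }, numeric(nrow(X)))
  }
  Vlig <- reduce(ia$source_genes)  # n_cells x n_interactions
  Vrec <- reduce(ia$target_genes)
  nI <- nrow(ia)
  n <- nrow(X)

  cluster_means <- function(li) {
    G <- Matrix::sparseMatrix(i = seq_len(n), j = li, x = 1, dims = c(n, k))
    sizes <- Matrix::colSums(G)
    Gn <- Matrix::Diagonal(x = ifelse(sizes > 0, 1 / sizes, 0)) %*% Matrix::t(G)
    list(lig = as.matrix(Gn %*% Vlig), rec = as.matrix(Gn %*% Vrec))
  }
  li <- as.integer(labels)
  mo <- cluster_means(li)
  # observed statistic: array [sender, receiver, interaction]
  stat_of <- function(cm) {
    outer_s <- array(0, c(k, k, nI))
    for (it in seq_len(nI)) {
      outer_s[, , it] <- (matrix(cm$lig[, it], k, k) +
                            matrix(cm$rec[, it], k, k, byrow = TRUE)) / 2
    }
    outer_s
  }
  m_obs <- stat_of(mo)
  ge_count <- array(0L, c(k, k, nI))
  with_seed(seed, for (p in seq_len(n_perms)) {
    mp <- stat_of(cluster_means(sample(li)))
    ge_count <- ge_count + (mp >= m_obs)
  })
  pmat <- (1 + ge_count) / (1 + n_perms)

  frac_expr <- function(V) {
    G <- Matrix::sparseMatrix(i = seq_len(n), j = li, x = 1, dims = c(n, k))
    sizes <- Matrix::colSums(G)
    as.matrix(Matrix::Diagonal(x = 1 / sizes) %*% Matrix::t(G) %*% (V > 0))
  }
  flig <- frac_expr(Vlig)  # k x nI
  frec <- frac_expr(Vrec)
  for (it in seq_len(nI)) {
    bad_s <- flig[, it] < expr_frac_threshold
    bad_r <- frec[, it] < expr_frac_threshold
    pmat[bad_s, , it] <- NaN
    pmat[, bad_r, it] <- NaN
  }

  grid <- expand.grid(sender = seq_len(k), receiver = seq_len(k),
                      interaction = seq_len(nI))
  tbl <- tibble(
    source = ia$source[grid$interaction],
    target = ia$target[grid$interaction],
    cluster_1 = lev[grid$sender],
    cluster_2 = lev[grid$receiver],
    mean = m_obs[cbind(grid$sender, grid$receiver, grid$interaction)],
    pvalue = pmat[cbind(grid$sender, grid$receiver, grid$interaction)]
  )
  tbl$pvalue_adj <- NaN
  tested <- !is.nan(tbl$pvalue)
  tbl$pvalue_adj[tested] <- p.adjust(tbl$pvalue[tested], method = "BH")
  new_spomics_tbl(tbl, "ligrec_result",
                  list(n_perms = as.integer(n_perms), seed = as.integer(seed),
                       complex_policy = complex_policy,
                       expr_frac_threshold = expr_frac_threshold,
                       clusters = lev))
}
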