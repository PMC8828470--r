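#' Build a spatial dataset
#'
#' The hub object every statistic in spomics reads from: an observation by
#' gene expression matrix, per-observation spatial coordinates, categorical
#' labels, spatial graphs and auxiliary per-observation matrices (e.g. image
#' features). Observation order is canonical: the order of `coords` rows; all
#' other inputs are aligned to it by `obs_id`.
#'
#' @param X Numeric matrix (dense or `Matrix` sparse), observations in rows,
#'   genes in columns. Row/column names, when present, must agree with
#'   `obs_ids` / `var_ids`.
#' @param coords Data frame or matrix with columns `x`, `y` (extra columns
#'   beyond the first two coordinate columns are ignored). One row per
#'   observation; coordinates share a single length unit.
#' @param obs_ids Character vector of unique observation identifiers.
#' @param var_ids Character vector of unique gene identifiers.
#' @param labels Optional data frame of categorical columns (one value per
#'   observation) merged into the per-observation table.
#' @return An object of class `spatial_dataset`: a list with elements `X`,
#'   `obs` (tibble: `obs_id`, `x`, `y`, label columns), `var_ids`, `graphs`
#'   (named list of [spatial_graph] objects) and `obsm` (named list of
#'   per-observation matrices).
#' @examples
#' d <- spatial_dataset(matrix(rpois(20, 3), 5, 4), cbind(x = runif(5), y = runif(5)))
#' d
#' @export
spatial_dataset <- function(X, coords, obs_ids = NULL, var_ids = NULL,
                            labels = NULL) {
  X <- as_expr_matrix(X)
  coords <- as.data.frame(coords)
  if (ncol(coords) < 2) abort("`coords` needs at least x and y columns.", class = "spomics_error")
  xy <- coords[, intersect(c("x", "y"), names(coords))]
  if (ncol(xy) < 2) xy <- coords[, 1:2]
  xy <- data.frame(x = as.numeric(xy[[1]]), y = as.numeric(xy[[2]]))
  n <- nrow(X)
  if (nrow(xy) != n) {
    abort(sprintf("coords has %d rows but X has %d observations.", nrow(xy), n),
          class = "spomics_align_error")
  }
  if (!all(is.finite(xy$x)) || !all(is.finite(xy$y))) {
    abort("Coordinates must be finite numbers.", class = "spomics_parse_error")
  }
  obs_ids <- as.character(obs_ids %||% rownames(X) %||% paste0("obs", seq_len(n)))
  if (anyDuplicated(obs_ids)) {
    abort(paste0("Duplicated obs ids: ",
                 paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", ")),
          class = "spomics_align_error")
  }
  var_ids <- as.character(var_ids %||% colnames(X) %||% paste0("gene", seq_len(ncol(X))))
  if (anyDuplicated(var_ids)) abort("Gene ids must be unique.", class = "spomics_align_error")
  dimnames(X) <- list(obs_ids, var_ids)
  obs <- tibble(obs_id = obs_ids, x = xy$x, y = xy$y)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != n) abort("Label table row count differs from n_obs.", class = "spomics_align_error")
    for (nm in names(labels)) obs[[nm]] <- as.factor(labels[[nm]])
  }
  structure(
    list(X = X, obs = obs, var_ids = var_ids, graphs = list(), obsm = list()),
    class = "spatial_dataset"
  )
}

as_expr_matrix <- function(X) {
  if (inherits(X, "sparseMatrix")) return(methods::as(X, "CsparseMatrix"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) abort("`X` must be a numeric matrix.", class = "spomics_error")
  X
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d obs x %d genes\n", n_obs(x), length(x$var_ids)))
  labs <- label_keys(x)
  if (length(labs)) cat("labels:", paste(labs, collapse = ", "), "\n")
  if (length(x$graphs)) cat("graphs:", paste(names(x$graphs), collapse = ", "), "\n")
  if (length(x$obsm)) cat("obsm:", paste(names(x$obsm), collapse = ", "), "\n")
  invisible(x)
}

n_obs <- function(dataset) nrow(dataset$obs)

coords_matrix <- function(dataset) {
  m <- cbind(x = dataset$obs$x, y = dataset$obs$y)
  rownames(m) <- dataset$obs$obs_id
  m
}

label_keys <- function(dataset) {
  nm <- names(dataset$obs)
  nm[vapply(dataset$obs, is.factor, logical(1))]
}

get_labels <- function(dataset, label_key) {
  if (!label_key %in% names(dataset$obs)) {
    abort(sprintf("No label column '%s' in dataset.", label_key), class = "spomics_error")
  }
  v <- dataset$obs[[label_key]]
  if (!is.factor(v)) v <- factor(v)
  droplevels(v)
}

#' Read a spatial dataset from files
#'
#' Reads an expression matrix (MatrixMarket `.mtx` with `genes.tsv` /
#' `barcodes.tsv` sidecars, or a CSV with a header row of gene ids and a
#' first column of observation ids), a coordinates CSV (`obs_id,x,y`) and
#' optionally one or more label CSVs (`obs_id` plus one column per label
#' key). All tables are aligned to the coordinate-file observation order.
#'
#' @param expr_path Path to the expression matrix (`.mtx` or `.csv`). For MTX,
#'   sidecar files `<dir>/genes.tsv` and `<dir>/barcodes.tsv` (one id per
#'   line) name the columns and rows; the matrix is obs x gene.
#' @param coords_path Path to the coordinates CSV with columns `obs_id,x,y`
#'   (a third coordinate column, if present, is ignored).
#' @param labels_path Optional path (or vector of paths) to label CSVs.
#' @return A [spatial_dataset].
#' @export
read_dataset <- function(expr_path, coords_path, labels_path = NULL) {
  expr <- read_expression(expr_path)
  coords <- read.csv(coords_path, check.names = FALSE)
  need <- c("obs_id", "x", "y")
  if (!all(need %in% names(coords))) {
    abort("Coordinates CSV must have columns obs_id, x, y.", class = "spomics_parse_error")
  }
  if (!is.numeric(coords$x) || !is.numeric(coords$y)) {
    abort("Non-numeric coordinate values.", class = "spomics_parse_error")
  }
  coords$obs_id <- as.character(coords$obs_id)
  align <- match(coords$obs_id, rownames(expr))
  check_alignment(coords$obs_id, rownames(expr), "expression matrix")
  check_alignment(rownames(expr), coords$obs_id, "coordinates file")
  X <- expr[align, , drop = FALSE]
  labels <- NULL
  for (lp in labels_path %||% character()) {
    lab <- read.csv(lp, check.names = FALSE, colClasses = "character")
    if (!"obs_id" %in% names(lab)) {
      abort("Label CSV must have an obs_id column.", class = "spomics_parse_error")
    }
    check_alignment(coords$obs_id, lab$obs_id, basename(lp))
    lab <- lab[match(coords$obs_id, lab$obs_id), setdiff(names(lab), "obs_id"), drop = FALSE]
    labels <- if (is.null(labels)) lab else cbind(labels, lab)
  }
  spatial_dataset(X, coords[c("x", "y")], obs_ids = coords$obs_id,
                  var_ids = colnames(expr), labels = labels)
}

check_alignment <- function(wanted, present, what) {
  missing <- setdiff(wanted, present)
  if (length(missing)) {
    abort(sprintf("Obs ids missing from %s: %s", what,
                  paste(head(missing, 5), collapse = ", ")),
          class = "spomics_align_error")
  }
}

read_expression <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    # writeMM may have used a symmetric/pattern variant; normalize to general
    X <- methods::as(methods::as(Matrix::readMM(path) * 1, "generalMatrix"),
                     "CsparseMatrix")
    dir <- dirname(path)
    genes <- readLines(file.path(dir, "genes.tsv"))
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
    barcodes <- vapply(strsplit(barcodes, "\t"), `[[`, character(1), 1L)
    if (nrow(X) != length(barcodes) || ncol(X) != length(genes)) {
      abort("MTX dimensions do not match sidecar files.", class = "spomics_parse_error")
    }
    dimnames(X) <- list(barcodes, genes)
    X
  } else {
    df <- read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) abort("Non-numeric expression values.", class = "spomics_parse_error")
    rownames(m) <- ids
    m
  }
}

#' Write a result table to CSV
#'
#' Serializes any spomics result tibble (or plain data frame) to CSV with
#' full double precision; undefined p-values are written as empty cells so a
#' round-trip reproduces `NaN`/`NA` rather than zeros.
#'
#' @param result A result tibble.
#' @param path Output CSV path.
#' @param header Optional character vector of comment lines (written prefixed
#'   with `#`) carrying provenance.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, header = NULL) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("Cannot open '%s' for writing.", path), class = "spomics_io_error")
  })
  on.exit(close(con))
  for (h in header %||% character()) writeLines(paste0("# ", h), con)
  df <- as.data.frame(result)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf_trim(df[[j]])
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# %.15g keeps >= 12 significant digits on round-trip; NA/NaN become empty.
sprintf_trim <- function(x) {
  out <- sprintf("%.15g", x)
  out[!is.finite(x) & !is.na(x)] <- as.character(x[!is.finite(x) & !is.na(x)])
  out[is.na(x)] <- NA_character_
  out
}

#' Read a result table written by [write_result()]
#'
#' @param path CSV path (leading `#` comment lines are skipped).
#' @return A tibble.
#' @export
read_result <- function(path) {
  as_tibble(read.csv(path, comment.char = "#", check.names = FALSE))
}

#' Attach a graph or label to a dataset
#'
#' @param dataset A [spatial_dataset].
#' @param graph A [spatial_graph] to store under `key`.
#' @param key Name under which to store the graph.
#' @return The modified dataset.
#' @export
set_graph <- function(dataset, graph, key = "spatial") {
  stopifnot(inherits(dataset, "spatial_dataset"), inherits(graph, "spatial_graph"))
  validate_spatial_graph(graph, n_obs(dataset))
  dataset$graphs[[key]] <- graph
  dataset
}
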