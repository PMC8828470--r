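#' Per-spot image features
#'
#' Extracts features from the per-observation image crop (see
#' [generate_spot_crops()]) and returns an observation x feature tibble,
#' also attached to `dataset$obsm[[key]]`. Available extractors:
#'
#' * `summary`: per channel mean, standard deviation and quantiles
#'   (default 0.9, 0.5, 0.1).
#' * `histogram`: per channel bin counts of the crop's value histogram
#'   (default 10 bins over the value range, `[0, 1]` for float layers).
#' * `texture`: gray-level co-occurrence matrix (GLCM) properties per
#'   channel. Pixels are quantized to 256 gray levels; pair counts are
#'   accumulated at offset distance 1 for angles 0, 45, 90 and 135 degrees,
#'   symmetrized and normalized to a probability distribution `C`; the
#'   properties contrast `sum C_pq (p-q)^2`, dissimilarity `sum C_pq |p-q|`,
#'   homogeneity `sum C_pq / (1 + (p-q)^2)`, angular second moment
#'   `sum C_pq^2` and correlation
#'   `sum C_pq (p - mu_p)(q - mu_q) / sqrt(sigma_p^2 sigma_q^2)` are averaged
#'   over the four angles. Zero-variance crops get correlation 1 (limit
#'   convention). Float layers need an explicit `texture_range`.
#' * `segmentation`: statistics of segmented objects assigned to the spot by
#'   centroid-in-crop: object count, mean and sd of object pixel areas, and
#'   mean intensity per channel of `layer` over the objects' pixels.
#'   Requires `label_layer`.
#'
#' Columns are named `<feature>_<layer>_ch<channel>_<statistic>` in a
#' deterministic order; extraction is independent per observation, so rows
#' only depend on the observation itself.
#'
#' @param dataset A [spatial_dataset] with pixel-unit coordinates.
#' @param img An [image_store()].
#' @param geometry A [spot_geometry()].
#' @param features Character subset of
#'   `c("summary", "histogram", "texture", "segmentation")`, or a named list
#'   of custom functions `crop -> named numeric`.
#' @param layer Intensity layer to extract from.
#' @param params Named list of extractor parameters: `quantiles`, `bins`,
#'   `texture_range`, `label_layer`, `glcm_levels`.
#' @param key Name under which the matrix is stored in `dataset$obsm`.
#' @return The updated dataset; the feature tibble is in
#'   `dataset$obsm[[key]]` (class `feature_matrix`, first column `obs_id`).
#' @export
calculate_features <- function(dataset, img, geometry,
                               features = "summary", layer = "image",
                               params = list(), key = "img_features") {
  known <- c("summary", "histogram", "texture", "segmentation")
  if (is.character(features)) {
    bad <- setdiff(features, known)
    if (length(bad)) abort(paste0("Unknown features: ", paste(bad, collapse = ", ")),
                           class = "spomics_error")
  }
  crops <- generate_spot_crops(img, dataset, geometry, layer)
  seg_info <- NULL
  if (is.character(features) && "segmentation" %in% features) {
    if (is.null(params$label_layer)) {
      abort("Segmentation features need params$label_layer.", class = "spomics_error")
    }
    seg_info <- segmentation_objects(get_layer(img, params$label_layer)[, , 1],
                                     get_layer(img, layer))
  }
  rows <- purrr::map(crops, function(cr) {
    vals <- c(obs_id = cr$obs_id)
    out <- list()
    if (is.list(features)) {
      for (nm in names(features)) {
        v <- features[[nm]](cr$crop)
        names(v) <- paste0(nm, "_", layer, "_", names(v))
        out <- c(out, as.list(v))
      }
    } else {
      if ("summary" %in% features) out <- c(out, feat_summary(cr$crop, layer, params))
      if ("histogram" %in% features) out <- c(out, feat_histogram(cr$crop, layer, params))
      if ("texture" %in% features) out <- c(out, feat_texture(cr$crop, layer, params))
      if ("segmentation" %in% features) {
        out <- c(out, feat_segmentation(cr, seg_info, geometry, layer, params))
      }
    }
    tibble(obs_id = cr$obs_id, !!!out)
  })
  feat <- dplyr::bind_rows(rows)
  class(feat) <- c("feature_matrix", class(feat))
  dataset$obsm[[key]] <- feat
  dataset
}

feat_summary <- function(crop, layer, params) {
  qs <- params$quantiles %||% c(0.9, 0.5, 0.1)
  out <- list()
  for (ch in seq_len(dim(crop)[3])) {
    v <- as.numeric(crop[, , ch])
    base <- paste0("summary_", layer, "_ch", ch - 1L)
    out[[paste0(base, "_mean")]] <- mean(v)
    out[[paste0(base, "_sd")]] <- sd(v)
    for (q in qs) out[[paste0(base, "_q", format(q))]] <- unname(quantile(v, q, type = 7))
  }
  out
}

feat_histogram <- function(crop, layer, params) {
  bins <- params$bins %||% 10L
  rng <- params$hist_range %||% c(0, 1)
  out <- list()
  for (ch in seq_len(dim(crop)[3])) {
    v <- as.numeric(crop[, , ch])
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    cut_idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), bins)
    counts <- tabulate(cut_idx, nbins = bins)
    base <- paste0("histogram_", layer, "_ch", ch - 1L)
    for (b in seq_len(bins)) out[[paste0(base, "_bin", b - 1L)]] <- counts[b]
  }
  out
}

feat_texture <- function(crop, layer, params) {
  levels <- params$glcm_levels %||% 256L
  rng <- params$texture_range
  is_int <- all(crop == round(crop)) && max(crop) > 1
  if (is.null(rng)) {
    if (is_int) rng <- c(0, 255)
    else if (max(crop) <= 1 && min(crop) >= 0) rng <- c(0, 1)
    else abort("Float layer outside [0,1]: texture needs explicit params$texture_range.",
               class = "spomics_error")
  }
  out <- list()
  for (ch in seq_len(dim(crop)[3])) {
    m <- crop[, , ch]
    q <- pmin(pmax(floor((m - rng[1]) / (rng[2] - rng[1] + 1e-12) * levels), 0), levels - 1L)
    props <- sapply(glcm_offsets(), function(off) glcm_properties(q, off, levels))
    base <- paste0("texture_", layer, "_ch", ch - 1L)
    for (p in rownames(props)) out[[paste0(base, "_", p)]] <- mean(props[p, ])
  }
  out
}

glcm_offsets <- function() {
  # distance 1 at 0, 45, 90, 135 degrees in (drow, dcol) image convention
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

# Symmetrized, normalized GLCM properties from the pair list: moments of the
# pair values give contrast/dissimilarity/homogeneity/correlation directly;
# ASM needs the cell probabilities.
glcm_properties <- function(q, off, levels) {
  h <- nrow(q); w <- ncol(q)
  r0 <- max(1L, 1L - off[1]); r1 <- min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(w, w - off[2])
  empty <- c(contrast = NaN, dissimilarity = NaN, homogeneity = NaN,
             asm = NaN, correlation = NaN)
  if (r0 > r1 || c0 > c1) return(empty)
  p <- as.numeric(q[r0:r1, c0:c1])
  qq <- as.numeric(q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2])])
  # symmetrize: count both (p,q) and (q,p)
  a <- c(p, qq); b <- c(qq, p)
  npair <- length(a)
  d <- a - b
  mu <- mean(a)
  s2 <- mean((a - mu)^2)
  corr <- if (s2 == 0) 1 else mean((a - mu) * (b - mu)) / s2
  code <- a * levels + b
  probs <- tabulate(match(code, unique(code)), nbins = length(unique(code))) / npair
  c(contrast = mean(d^2),
    dissimilarity = mean(abs(d)),
    homogeneity = mean(1 / (1 + d^2)),
    asm = sum(probs^2),
    correlation = corr)
}

segmentation_objects <- function(label_mat, intensity) {
  ids <- sort(unique(label_mat[label_mat > 0]))
  if (!length(ids)) {
    return(list(ids = integer(0),
                centroid_row = numeric(0), centroid_col = numeric(0),
                area = numeric(0), mean_int = NULL))
  }
  idx <- which(label_mat > 0, arr.ind = TRUE)
  lab <- label_mat[idx]
  f <- factor(lab, levels = ids)
  area <- as.numeric(table(f))
  centroid_row <- tapply(idx[, 1], f, mean) - 1  # 0-based pixel centres
  centroid_col <- tapply(idx[, 2], f, mean) - 1
  nc <- dim(intensity)[3]
  mean_int <- sapply(seq_len(nc), function(ch) {
    v <- intensity[, , ch][idx]
    as.numeric(tapply(v, f, mean))
  })
  mean_int <- matrix(mean_int, nrow = length(ids))
  list(ids = ids, centroid_row = as.numeric(centroid_row),
       centroid_col = as.numeric(centroid_col), area = area,
       mean_int = mean_int)
}

feat_segmentation <- function(cr, seg, geometry, layer, params) {
  side <- geometry$side
  inside <- seg$centroid_row >= cr$row0 & seg$centroid_row < cr$row0 + side &
    seg$centroid_col >= cr$col0 & seg$centroid_col < cr$col0 + side
  base <- paste0("segmentation_", params$label_layer)
  out <- list()
  n <- sum(inside)
  out[[paste0(base, "_count")]] <- n
  out[[paste0(base, "_area_mean")]] <- if (n) mean(seg$area[inside]) else 0
  out[[paste0(base, "_area_sd")]] <- if (n > 1) sd(seg$area[inside]) else 0
  if (!is.null(seg$mean_int)) {
    for (ch in seq_len(ncol(seg$mean_int))) {
      out[[paste0(base, "_", layer, "_ch", ch - 1L, "_mean_intensity")]] <-
        if (n) mean(seg$mean_int[inside, ch]) else 0
    }
  }
  out
}
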