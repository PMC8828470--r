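#' In-memory tissue image container
#'
#' Named pixel layers sharing one (height, width) frame, stored channels-last
#' as `height x width x channels` arrays. Spot coordinates relate to pixel
#' arrays through the convention that `x` indexes columns and `y` rows, with
#' origin top-left and 0-based pixel positions. Segmentation layers hold
#' non-negative integer labels with 0 = background.
#'
#' @param ... Named arrays (2-D arrays are promoted to one channel).
#' @return An `image_store` object.
#' @examples
#' img <- image_store(he = array(runif(64 * 64 * 3), c(64, 64, 3)))
#' img
#' @export
image_store <- function(...) {
  layers <- list(...)
  store <- structure(list(layers = list()), class = "image_store")
  for (nm in names(layers)) store <- add_layer(store, layers[[nm]], nm)
  store
}

#' @rdname image_store
#' @param img An `image_store`.
#' @param pixels Array to add (height x width x channels, or 2-D).
#' @param layer Layer name.
#' @export
add_layer <- function(img, pixels, layer) {
  if (length(dim(pixels)) == 2L) pixels <- array(pixels, c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) abort("Pixel arrays must be 2-D or 3-D (h, w, c).", class = "spomics_error")
  shp <- dim(pixels)[1:2]
  for (other in img$layers) {
    if (!all(dim(other)[1:2] == shp)) {
      abort("Layer spatial shape differs from existing layers.", class = "spomics_error")
    }
  }
  img$layers[[layer]] <- pixels
  img
}

#' @export
print.image_store <- function(x, ...) {
  cat("<image_store>\n")
  for (nm in names(x$layers)) {
    d <- dim(x$layers[[nm]])
    cat(sprintf("  %s: %d x %d x %d\n", nm, d[1], d[2], d[3]))
  }
  invisible(x)
}

get_layer <- function(img, layer) {
  if (!layer %in% names(img$layers)) {
    abort(sprintf("No layer '%s' in image store.", layer), class = "spomics_error")
  }
  img$layers[[layer]]
}

#' Load a TIFF or PNG image into an image store
#'
#' @param img An existing [image_store()] (or `NULL` to start one).
#' @param path Path to a PNG or TIFF file; grayscale images are promoted to
#'   one channel.
#' @param layer Layer name for the loaded image.
#' @return The updated `image_store`.
#' @export
load_image <- function(img = NULL, path, layer = "image") {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (is.null(img)) img <- image_store()
  add_layer(img, px, layer)
}

#' Write a layer to TIFF or PNG
#'
#' Label layers are written as 16-bit TIFF (labels divided by 65535);
#' intensity layers are clipped to `[0, 1]`.
#'
#' @param img An [image_store()].
#' @param layer Layer name.
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, layer, path) {
  px <- get_layer(img, layer)
  if (dim(px)[3] == 1L) px <- px[, , 1]
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(pmin(pmax(px, 0), 1), path)
  } else {
    is_label <- all(px == round(px)) && max(px) > 1
    if (is_label) {
      tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
    } else {
      tiff::writeTIFF(pmin(pmax(px, 0), 1), path)
    }
  }
  invisible(path)
}

#' Process an image layer (grayscale, Gaussian smoothing, custom)
#'
#' `"gray"` converts a 3-channel layer to luminance with weights
#' (0.2125, 0.7154, 0.0721). `"smooth"` applies a separable Gaussian kernel
#' (truncated at radius `round(4 * sigma)`, reflect padding) per channel. A
#' function can be passed for custom pure pixel-array transforms. When
#' `tile_size` is set the transform runs on overlapping tiles whose cores
#' partition the image; for smoothing this equals whole-image processing
#' exactly when `overlap >= 4 * sigma`.
#'
#' @param img An [image_store()].
#' @param layer Input layer name.
#' @param method `"gray"`, `"smooth"`, or a function `array -> array`.
#' @param sigma Gaussian standard deviation in pixels (smooth).
#' @param tile_size Optional tile core side in pixels.
#' @param overlap Tile margin in pixels (default `ceiling(4 * sigma)` for
#'   smoothing, 0 otherwise).
#' @param new_layer Output layer name (default `<layer>_<method>`).
#' @return The updated `image_store`.
#' @export
process_image <- function(img, layer, method = "gray", sigma = 2,
                          tile_size = NULL, overlap = NULL, new_layer = NULL) {
  px <- get_layer(img, layer)
  if (is.function(method)) {
    fun <- method
    tag <- "custom"
    overlap <- overlap %||% 0L
  } else {
    tag <- match.arg(method, c("gray", "smooth"))
    if (tag == "gray") {
      if (dim(px)[3] != 3L) abort("Grayscale conversion needs exactly 3 channels.", class = "spomics_error")
      fun <- function(a) {
        g <- a[, , 1] * 0.2125 + a[, , 2] * 0.7154 + a[, , 3] * 0.0721
        array(g, c(dim(a)[1:2], 1L))
      }
      overlap <- overlap %||% 0L
    } else {
      fun <- function(a) gaussian_smooth(a, sigma)
      overlap <- overlap %||% ceiling(4 * sigma)
    }
  }
  out <- if (is.null(tile_size)) fun(px) else tile_apply(px, fun, tile_size, overlap)
  if (length(dim(out)) == 2L) out <- array(out, c(dim(out), 1L))
  add_layer(img, out, new_layer %||% paste0(layer, "_", tag))
}

# Separable Gaussian convolution, reflect padding, kernel radius round(4*sigma).
gaussian_smooth <- function(a, sigma) {
  r <- max(1L, as.integer(round(4 * sigma)))
  k <- exp(-(( -r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- a
  for (ch in seq_len(dim(a)[3])) {
    m <- a[, , ch]
    m <- conv_reflect(m, k)        # along rows (vertical)
    m <- t(conv_reflect(t(m), k))  # along columns (horizontal)
    out[, , ch] <- m
  }
  out
}

conv_reflect <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  if (r > n) abort("Kernel radius exceeds image size.", class = "spomics_error")
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (o in seq_along(k)) {
    out <- out + k[o] * pad[(o - 1) + seq_len(n), , drop = FALSE]
  }
  out
}

# Run `fun` over overlapping tiles whose cores partition the image; each tile
# is the core extended by `overlap` pixels (clipped at image borders), and
# only the core of the result is kept.
tile_apply <- function(px, fun, tile_size, overlap) {
  h <- dim(px)[1]; w <- dim(px)[2]
  probe <- fun(px[seq_len(min(h, tile_size + 2 * overlap)),
                  seq_len(min(w, tile_size + 2 * overlap)), , drop = FALSE])
  n_ch <- if (length(dim(probe)) == 3L) dim(probe)[3] else 1L
  out <- array(0, c(h, w, n_ch))
  for (r0 in seq(1L, h, by = tile_size)) {
    for (c0 in seq(1L, w, by = tile_size)) {
      r1 <- min(r0 + tile_size - 1L, h)
      c1 <- min(c0 + tile_size - 1L, w)
      er0 <- max(1L, r0 - overlap); er1 <- min(h, r1 + overlap)
      ec0 <- max(1L, c0 - overlap); ec1 <- min(w, c1 + overlap)
      res <- fun(px[er0:er1, ec0:ec1, , drop = FALSE])
      if (length(dim(res)) == 2L) res <- array(res, c(dim(res), 1L))
      core_r <- (r0 - er0 + 1L):(r0 - er0 + (r1 - r0 + 1L))
      core_c <- (c0 - ec0 + 1L):(c0 - ec0 + (c1 - c0 + 1L))
      out[r0:r1, c0:c1, ] <- res[core_r, core_c, , drop = FALSE]
    }
  }
  out
}

#' Watershed segmentation of a single-channel layer
#'
#' Thresholds the layer (Otsu by default), computes the Euclidean distance
#' transform of the foreground and floods it by watershed, so touching or
#' slightly overlapping objects separated by distinct distance-transform
#' peaks (at least `min_peak_distance` apart) receive distinct labels.
#' Labels are consecutive integers from 1; 0 is background.
#'
#' @param img An [image_store()].
#' @param layer Single-channel input layer (run
#'   `process_image(method = "gray")` first for RGB).
#' @param invert Segment pixels below the threshold instead of above.
#' @param threshold `"otsu"` or a numeric threshold in layer units.
#' @param min_peak_distance Minimum separation of watershed seed peaks
#'   (pixels).
#' @param new_layer Output label-layer name.
#' @return The updated `image_store` with an integer label layer.
#' @export
segment_watershed <- function(img, layer, invert = FALSE, threshold = "otsu",
                              min_peak_distance = 5, new_layer = "segmented") {
  px <- get_layer(img, layer)
  if (dim(px)[3] != 1L) abort("Watershed needs a single-channel layer.", class = "spomics_error")
  m <- px[, , 1]
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(t(m)), range = range(m))
  } else {
    threshold
  }
  fg <- if (invert) m < thr else m > thr
  if (!any(fg)) {
    warn("Empty foreground: 0 objects.")
    lab <- array(0L, c(dim(m), 1L))
    return(add_layer(img, lab, new_layer))
  }
  # EBImage works on (x, y) arrays; transpose in and out.
  dm <- EBImage::distmap(EBImage::Image(t(fg) * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = as.integer(min_peak_distance))
  lab <- t(EBImage::imageData(ws))
  ids <- sort(unique(lab[lab > 0]))
  relab <- integer(max(ids) + 1L)
  relab[ids + 1L] <- seq_along(ids)
  lab[lab > 0] <- relab[lab[lab > 0] + 1L]
  add_layer(img, array(as.integer(lab), c(dim(m), 1L)), new_layer)
}

#' Spot crop geometry
#'
#' @param diameter Spot diameter in pixels.
#' @param spot_scale Multiplier on the diameter (crop side =
#'   `round(diameter * spot_scale * scale)`).
#' @param scale Resize factor applied to the geometry.
#' @return A `spot_geometry` object.
#' @export
spot_geometry <- function(diameter, spot_scale = 1, scale = 1) {
  side <- max(1L, as.integer(round(diameter * spot_scale * scale)))
  structure(list(diameter = diameter, spot_scale = spot_scale, scale = scale,
                 side = side), class = "spot_geometry")
}

#' Square crops around each spot centre
#'
#' Crops are `side x side` pixel blocks centred at each observation's
#' (x, y) position (x = column, y = row, 0-based); portions outside the
#' image are zero-padded and flagged. Order follows the observation order.
#'
#' @param img An [image_store()].
#' @param dataset A [spatial_dataset] whose coordinates are in pixel units
#'   of the image.
#' @param geometry A [spot_geometry()].
#' @param layer Layer to crop.
#' @return A list with one element per observation: `obs_id`, `crop`
#'   (side x side x channels array), `padded` flag.
#' @export
generate_spot_crops <- function(img, dataset, geometry, layer = "image") {
  px <- get_layer(img, layer)
  h <- dim(px)[1]; w <- dim(px)[2]; nc <- dim(px)[3]
  side <- geometry$side
  half <- (side - 1L) %/% 2L
  purrr::map(seq_len(n_obs(dataset)), function(i) {
    col0 <- as.integer(round(dataset$obs$x[i])) - half  # 0-based origin
    row0 <- as.integer(round(dataset$obs$y[i])) - half
    rows <- row0 + 0:(side - 1L)
    cols <- col0 + 0:(side - 1L)
    inside_r <- rows >= 0 & rows < h
    inside_c <- cols >= 0 & cols < w
    crop <- array(0, c(side, side, nc))
    if (any(inside_r) && any(inside_c)) {
      crop[which(inside_r), which(inside_c), ] <-
        px[rows[inside_r] + 1L, cols[inside_c] + 1L, , drop = FALSE]
    }
    list(obs_id = dataset$obs$obs_id[i], crop = crop,
         padded = !all(inside_r) || !all(inside_c),
         row0 = row0, col0 = col0)
  })
}
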