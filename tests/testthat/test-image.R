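test_that("layers share one frame; grayscale follows luminance weights", {
  img <- image_store(rgb = array(0, c(16, 16, 3)))
  expect_error(add_layer(img, array(0, c(8, 8, 1)), "bad"), class = "spomics_error")

  red <- array(0, c(8, 8, 3)); red[, , 1] <- 1
  img <- image_store(rgb = red)
  img <- process_image(img, "rgb", "gray")
  expect_equal(img$layers$rgb_gray[1, 1, 1], 0.2125)
  expect_error(process_image(img, "rgb_gray", "gray"), class = "spomics_error")
})

test_that("smoothing preserves constants and tiling matches whole-image", {
  img <- image_store(flat = array(0.42, c(32, 32, 1)))
  img <- process_image(img, "flat", "smooth", sigma = 2)
  expect_equal(img$layers$flat_smooth, img$layers$flat, tolerance = 1e-12)

  set.seed(61)
  noisy <- array(runif(96 * 96 * 2), c(96, 96, 2))
  img2 <- image_store(x = noisy)
  whole <- process_image(img2, "x", "smooth", sigma = 1.5, new_layer = "w")
  tiled <- process_image(img2, "x", "smooth", sigma = 1.5, tile_size = 32,
                         overlap = ceiling(4 * 1.5), new_layer = "t")
  expect_equal(tiled$layers$t, whole$layers$w, tolerance = 1e-6)

  # custom transforms tile exactly when pixel-local
  sq <- function(a) a^2
  t2 <- process_image(img2, "x", sq, tile_size = 40, new_layer = "sq")
  expect_equal(t2$layers$sq, noisy^2, tolerance = 1e-12)
})

test_that("png/tiff round trip through load_image", {
  skip_if_not_installed("png")
  path <- withr::local_tempfile(fileext = ".png")
  set.seed(62)
  a <- array(runif(24 * 20 * 3), c(24, 20, 3))
  png::writePNG(a, path)
  img <- load_image(NULL, path, "he")
  expect_equal(dim(img$layers$he), c(24, 20, 3))
  expect_equal(img$layers$he, a, tolerance = 1 / 255)
  # grayscale promotion to one channel
  g <- matrix(runif(12 * 12), 12)
  png::writePNG(g, path)
  expect_equal(dim(load_image(NULL, path, "g")$layers$g), c(12, 12, 1))
})

test_that("watershed counts blobs and splits touching disks", {
  img <- image_store(black = array(0, c(32, 32, 1)))
  expect_warning(imgs <- segment_watershed(img, "black"), "Empty foreground")
  expect_equal(max(imgs$layers$segmented), 0)

  sim <- simulate_blob_image(n_blobs = 5, radius = 8, size = c(128, 128),
                             noise_sd = 0, seed = 63)
  seg <- segment_watershed(sim$img, "image", threshold = 0.5)
  expect_equal(max(seg$layers$segmented), 5)
  lab <- seg$layers$segmented[, , 1]
  expect_true(all(lab >= 0))
  expect_setequal(unique(lab[lab > 0]), 1:5)

  # two disks overlapping by less than a radius still separate
  m <- matrix(0, 64, 64)
  cols <- matrix(rep(0:63, each = 64), 64); rows <- t(cols)
  m[(cols - 24)^2 + (rows - 32)^2 <= 100] <- 1
  m[(cols - 38)^2 + (rows - 32)^2 <= 100] <- 1
  two <- segment_watershed(image_store(pair = array(m, c(64, 64, 1))),
                           "pair", threshold = 0.5)
  expect_equal(max(two$layers$segmented), 2)
})

test_that("spot crops honour the slicing contract and padding flags", {
  px <- array(seq_len(11 * 11) / 121, c(11, 11, 1))
  img <- image_store(image = px)
  d <- make_dataset(cbind(x = c(5, 0), y = c(5, 0)))  # centre and corner
  crops <- generate_spot_crops(img, d, spot_geometry(5), "image")
  expect_length(crops, 2)
  expect_equal(crops[[1]]$crop[, , 1], px[4:8, 4:8, 1])
  expect_false(crops[[1]]$padded)
  expect_true(crops[[2]]$padded)
  expect_equal(crops[[2]]$crop[1:2, 1:2, 1], matrix(0, 2, 2))  # zero pad
  expect_equal(crops[[2]]$crop[3:5, 3:5, 1], px[1:3, 1:3, 1])
})

test_that("GLCM texture properties: constants exact, gradient matches oracle", {
  flat <- array(0.5, c(9, 9, 1))
  img <- image_store(image = flat)
  d <- make_dataset(cbind(x = 4, y = 4))
  d <- calculate_features(d, img, spot_geometry(9), "texture")
  f <- d$obsm$img_features
  expect_equal(f$texture_image_ch0_contrast, 0)
  expect_equal(f$texture_image_ch0_dissimilarity, 0)
  expect_equal(f$texture_image_ch0_homogeneity, 1)
  expect_equal(f$texture_image_ch0_asm, 1)
  expect_equal(f$texture_image_ch0_correlation, 1)

  # horizontal gradient crop vs brute-force dense GLCM at offset (0, 1)
  side <- 7
  grad <- array(rep((0:(side - 1)) / (side - 1), each = side), c(side, side, 1))
  q <- floor(grad[, , 1] * 0.999999 * 256)
  C <- matrix(0, 256, 256)
  for (r in 1:side) for (cc in 1:(side - 1)) {
    p1 <- q[r, cc] + 1; p2 <- q[r, cc + 1] + 1
    C[p1, p2] <- C[p1, p2] + 1
    C[p2, p1] <- C[p2, p1] + 1
  }
  C <- C / sum(C)
  pq <- which(C > 0, arr.ind = TRUE) - 1
  w <- C[C > 0]
  mu <- sum(w * pq[, 1]); s2 <- sum(w * (pq[, 1] - mu)^2)
  oracle <- c(
    contrast = sum(w * (pq[, 1] - pq[, 2])^2),
    dissimilarity = sum(w * abs(pq[, 1] - pq[, 2])),
    homogeneity = sum(w / (1 + (pq[, 1] - pq[, 2])^2)),
    asm = sum(w^2),
    correlation = sum(w * (pq[, 1] - mu) * (pq[, 2] - mu)) / s2)
  got <- spomics:::glcm_properties(q, c(0L, 1L), 256L)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("texture on out-of-range float layers demands an explicit range", {
  img <- image_store(image = array(rnorm(81), c(9, 9, 1)))
  d <- make_dataset(cbind(x = 4, y = 4))
  expect_error(calculate_features(d, img, spot_geometry(9), "texture"),
               class = "spomics_error")
  d2 <- calculate_features(d, img, spot_geometry(9), "texture",
                           params = list(texture_range = c(-4, 4)))
  expect_true(is.finite(d2$obsm$img_features$texture_image_ch0_contrast))
})

test_that("painted-spot summary means are exact and order-equivariant", {
  px <- array(0, c(30, 30, 1))
  centres <- cbind(x = c(5, 15, 25), y = c(5, 15, 25))
  vals <- c(0.2, 0.5, 0.9)
  for (i in 1:3) {
    rows <- (centres[i, "y"] - 2):(centres[i, "y"] + 2) + 1
    px[rows, (centres[i, "x"] - 2):(centres[i, "x"] + 2) + 1, 1] <- vals[i]
  }
  img <- image_store(image = px)
  d <- make_dataset(centres)
  d <- calculate_features(d, img, spot_geometry(5), c("summary", "histogram"))
  f <- d$obsm$img_features
  expect_equal(f$summary_image_ch0_mean, vals)
  expect_equal(f$summary_image_ch0_sd, c(0, 0, 0))
  expect_equal(f$summary_image_ch0_q0.5, vals)
  expect_equal(rowSums(as.matrix(f[, grep("histogram", names(f))])),
               rep(25, 3))  # bin counts sum to crop size

  # permuting observations permutes rows accordingly
  dperm <- make_dataset(centres[c(3, 1, 2), ])
  fperm <- calculate_features(dperm, img, spot_geometry(5), "summary")$obsm$img_features
  expect_equal(fperm$summary_image_ch0_mean, vals[c(3, 1, 2)])
})

test_that("segmentation features count centroid-assigned objects", {
  sim <- simulate_blob_image(n_blobs = 4, radius = 6, size = c(96, 96),
                             noise_sd = 0, seed = 64)
  img <- segment_watershed(sim$img, "image", threshold = 0.5)
  d <- make_dataset(cbind(x = sim$centers$x, y = sim$centers$y))
  d <- calculate_features(d, img, spot_geometry(18), "segmentation",
                          params = list(label_layer = "segmented"))
  f <- d$obsm$img_features
  expect_equal(f$segmentation_segmented_count, rep(1, 4))
  area <- pi * 6^2
  expect_true(all(abs(f$segmentation_segmented_area_mean - area) < 15))
  expect_true(all(f$segmentation_segmented_image_ch0_mean_intensity == 1))
  expect_error(calculate_features(d, img, spot_geometry(18), "segmentation"),
               class = "spomics_error")
})
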