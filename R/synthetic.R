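#' Specify label and expression models for simulations
#'
#' Helpers building the model specifications consumed by
#' [simulate_points()].
#'
#' @param model Label model: `"random"` (i.i.d. categorical with optional
#'   `proportions`) or `"spatial_block"` (k contiguous vertical bands of
#'   equal point count).
#' @param k Number of clusters.
#' @param proportions Optional cluster proportions (random model).
#' @return A list specification.
#' @export
label_spec <- function(model = c("random", "spatial_block"), k = 2,
                       proportions = NULL) {
  model <- match.arg(model)
  list(model = model, k = k, proportions = proportions)
}

#' @rdname label_spec
#' @param n_genes Number of genes.
#' @param sd Noise standard deviation (all models; genes are
#'   `|N(mu, sd)|`-distributed around a baseline of 1, keeping expression
#'   non-negative).
#' @param spatial_genes Names (or count) of genes with a planted spatial
#'   block effect.
#' @param effect_size Additive elevation of planted genes inside the block
#'   (or of ligand/receptor genes inside their clusters).
#' @param ligrec_pairs Optional data frame (`ligand`, `receptor`, `sender`,
#'   `receiver`) of planted ligand-receptor pairs: the ligand gene is
#'   elevated in the sender cluster and the receptor in the receiver.
#' @export
expression_spec <- function(n_genes = 20, sd = 1, spatial_genes = NULL,
                            effect_size = 3, ligrec_pairs = NULL) {
  list(n_genes = n_genes, sd = sd, spatial_genes = spatial_genes,
       effect_size = effect_size, ligrec_pairs = ligrec_pairs)
}

#' Simulate a spatial point-pattern dataset
#'
#' Seeded generator for every input shape the statistics in this package
#' consume: coordinates (homogeneous Poisson, Thomas-style clustered, or
#' hexagonal/square lattice), categorical labels (random or spatial block)
#' and an expression matrix (non-negative noise, optionally with planted
#' spatially structured genes or planted ligand-receptor pairs). Identical
#' specifications and seed give identical datasets.
#'
#' @param n_points Number of points (ignored for lattices, which use
#'   `nx * ny`).
#' @param window Bounding box `c(xmin, xmax, ymin, ymax)`.
#' @param pattern `"poisson"`, `"clustered"` or `"lattice"`.
#' @param n_parents,offspring_sd Thomas-process parameters (clustered):
#'   each point is attached to one of `n_parents` uniform parents and
#'   displaced by isotropic Gaussian noise with sd `offspring_sd`.
#' @param lattice_type,pitch,nx,ny Lattice parameters: `"hex"` (triangular)
#'   or `"square"`, centre spacing `pitch`, `nx` columns by `ny` rows.
#' @param labels A [label_spec()] or `NULL` for no labels (label key
#'   `"cluster"`).
#' @param expression An [expression_spec()] or `NULL` for a minimal
#'   two-gene noise matrix.
#' @param seed Mandatory seed.
#' @return A [spatial_dataset].
#' @export
simulate_points <- function(n_points = 100,
                            window = c(0, 1, 0, 1),
                            pattern = c("poisson", "clustered", "lattice"),
                            n_parents = 5, offspring_sd = 0.03,
                            lattice_type = c("hex", "square"),
                            pitch = 1, nx = 10, ny = 10,
                            labels = label_spec("random", k = 2),
                            expression = expression_spec(),
                            seed) {
  pattern <- match.arg(pattern)
  lattice_type <- match.arg(lattice_type)
  with_seed(seed, {
    coords <- switch(pattern,
      poisson = cbind(x = runif(n_points, window[1], window[2]),
                      y = runif(n_points, window[3], window[4])),
      clustered = {
        px <- runif(n_parents, window[1], window[2])
        py <- runif(n_parents, window[3], window[4])
        par <- sample.int(n_parents, n_points, replace = TRUE)
        cbind(x = px[par] + rnorm(n_points, 0, offspring_sd),
              y = py[par] + rnorm(n_points, 0, offspring_sd))
      },
      lattice = lattice_coords(lattice_type, pitch, nx, ny))
    n <- nrow(coords)
    lab <- NULL
    if (!is.null(labels)) {
      lab <- data.frame(cluster = switch(labels$model,
        random = {
          pr <- labels$proportions %||% rep(1 / labels$k, labels$k)
          factor(sample(paste0("c", seq_len(labels$k)), n, replace = TRUE, prob = pr),
                 levels = paste0("c", seq_len(labels$k)))
        },
        spatial_block = {
          band <- ceiling(rank(coords[, "x"], ties.method = "first") / (n / labels$k))
          factor(paste0("c", pmin(band, labels$k)),
                 levels = paste0("c", seq_len(labels$k)))
        }))
    }
    X <- NULL
    if (!is.null(expression)) {
      ng <- expression$n_genes
      X <- abs(matrix(rnorm(n * ng, mean = 1, sd = expression$sd), n, ng))
      colnames(X) <- paste0("gene", seq_len(ng))
      sg <- expression$spatial_genes
      if (!is.null(sg)) {
        if (is.numeric(sg)) sg <- colnames(X)[seq_len(sg)]
        in_block <- coords[, "x"] <= median(coords[, "x"])
        X[in_block, sg] <- X[in_block, sg] + expression$effect_size
      }
      lr <- expression$ligrec_pairs
      if (!is.null(lr) && !is.null(lab)) {
        for (r in seq_len(nrow(lr))) {
          X[lab$cluster == lr$sender[r], lr$ligand[r]] <-
            X[lab$cluster == lr$sender[r], lr$ligand[r]] + expression$effect_size
          X[lab$cluster == lr$receiver[r], lr$receptor[r]] <-
            X[lab$cluster == lr$receiver[r], lr$receptor[r]] + expression$effect_size
        }
      }
    } else {
      X <- matrix(1, n, 2, dimnames = list(NULL, c("gene1", "gene2")))
    }
    spatial_dataset(X, coords, labels = lab)
  })
}

lattice_coords <- function(type, pitch, nx, ny) {
  if (type == "square") {
    g <- expand.grid(col = seq_len(nx) - 1L, row = seq_len(ny) - 1L)
    cbind(x = g$col * pitch, y = g$row * pitch)
  } else {
    g <- expand.grid(col = seq_len(nx) - 1L, row = seq_len(ny) - 1L)
    cbind(x = g$col * pitch + (g$row %% 2) * pitch / 2,
          y = g$row * pitch * sqrt(3) / 2)
  }
}

#' Simulate a blob image with known object centres
#'
#' Draws `n_blobs` non-overlapping bright disks (rejection sampling on the
#' centres; error after 10000 failed placements) on a dark background and
#' adds Gaussian pixel noise, returning both the image and the ground-truth
#' centres for segmentation tests.
#'
#' @param n_blobs Number of disks.
#' @param radius Disk radius in pixels.
#' @param size Image size `c(height, width)`.
#' @param intensity Disk intensity (background is 0; values clipped to
#'   `[0, 1]` after noise).
#' @param noise_sd Gaussian pixel noise sd.
#' @param seed Mandatory seed.
#' @param margin Minimum centre separation factor (centres at least
#'   `margin * 2 * radius` apart and `radius + 1` from the border).
#' @return A list: `img` (an [image_store()] with layer `"image"`),
#'   `centers` (tibble `x`, `y` in 0-based pixel coordinates).
#' @export
simulate_blob_image <- function(n_blobs = 5, radius = 8, size = c(128, 128),
                                intensity = 1, noise_sd = 0.05, seed,
                                margin = 1.25) {
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    fails <- 0L
    while (nrow(centers) < n_blobs) {
      cand <- c(runif(1, radius + 1, w - radius - 2), runif(1, radius + 1, h - radius - 2))
      ok <- !nrow(centers) ||
        all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
              margin * 2 * radius)
      if (ok) {
        centers <- rbind(centers, cand)
      } else {
        fails <- fails + 1L
        if (fails > 10000L) abort("Cannot place blobs without overlap; reduce n_blobs or radius.",
                                  class = "spomics_error")
      }
    }
    m <- matrix(0, h, w)
    if (n_blobs > 0) {
      cols <- matrix(rep(0:(w - 1), each = h), h, w)
      rows <- matrix(rep(0:(h - 1), times = w), h, w)
      for (b in seq_len(n_blobs)) {
        m[(cols - centers[b, 1])^2 + (rows - centers[b, 2])^2 <= radius^2] <- intensity
      }
    }
    if (noise_sd > 0) m <- m + matrix(rnorm(h * w, 0, noise_sd), h, w)
    m <- pmin(pmax(m, 0), 1)
    list(img = image_store(image = array(m, c(h, w, 1L))),
         centers = tibble(x = centers[, 1], y = centers[, 2]))
  })
}
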