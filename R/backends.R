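# Image -> feature-view backends. The pipeline treats backbones as frozen
# feature extractors: extraction is deterministic, with no augmentation or
# dropout. The deterministic "toy" backend computes closed-form image
# statistics so the package runs end-to-end without any network weights;
# the deep backends (CNN global-average-pool view, transformer pre-softmax
# head view) are declared interfaces that require an external runtime and
# weights, which this package does not bundle.

#' Describe a feature-extraction backend
#'
#' @param name One of `"toy"` (deterministic image statistics; no weights),
#'   `"cnn_pool"` (frozen CNN, global-average-pool layer; 1536-dim), or
#'   `"vit_head"` (frozen vision transformer, pre-softmax 1000-unit head).
#' @param weights_source Registry id or file path of pretrained weights;
#'   must be absent for the toy backend.
#' @param input_size Input side length in pixels the backend resizes to
#'   (bilinear interpolation). Ignored by the toy backend, which consumes
#'   images at native resolution.
#' @param output_dim Reported feature dimension; `NA` for the toy backend
#'   until the first image fixes the channel count.
#' @return An object of class `backend_spec`.
#' @export
backend_spec <- function(name = c("toy", "cnn_pool", "vit_head"),
                         weights_source = NULL,
                         input_size = NULL, output_dim = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    toy = list(input_size = NA_integer_, output_dim = NA_integer_),
    cnn_pool = list(input_size = 299L, output_dim = 1536L),
    vit_head = list(input_size = 224L, output_dim = 1000L)
  )
  if (name == "toy" && !is.null(weights_source)) {
    stop_config("the toy backend takes no weights_source")
  }
  structure(list(
    name = name,
    weights_source = weights_source,
    input_size = if (is.null(input_size)) defaults$input_size else as.integer(input_size),
    output_dim = if (is.null(output_dim)) defaults$output_dim else as.integer(output_dim)
  ), class = "backend_spec")
}

#' Extract a feature view from the images of a manifest
#'
#' Produces one feature row per manifest sample, in manifest order (row
#' alignment is positional and tagged by sample id). Extraction is fully
#' deterministic: two runs on the same images produce identical matrices.
#'
#' Only the `toy` backend is runnable here: for each image it computes
#' per-channel means and variances plus 4x4 block means of the luminance
#' channel (18 features for grayscale, 22 for RGB). The deep backends
#' (`cnn_pool`, `vit_head`) require an external deep-learning runtime and
#' pretrained weights and raise a configuration error ("backend
#' unavailable"), which is distinct from a data error such as an unreadable
#' image.
#'
#' @param manifest Manifest `data.frame` with readable `image_path`s.
#' @param spec A [backend_spec()]; default is the toy backend.
#' @param view_name Name for the resulting view; defaults to the backend name.
#' @return A [feature_view()] aligned with the manifest.
#' @export
extract_features <- function(manifest, spec = backend_spec("toy"),
                             view_name = NULL) {
  stopifnot(inherits(spec, "backend_spec"))
  if (spec$name != "toy") {
    stop_config("backend unavailable: '", spec$name,
                "' requires an external deep-learning runtime and pretrained ",
                "weights, which this package does not bundle; use the 'toy' ",
                "backend or supply precomputed feature views")
  }
  if (nrow(manifest) == 0) stop_input("empty manifest")
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$image_path[i]
    if (is.na(p) || !nzchar(p) || !file.exists(p)) {
      stop_input("unreadable image for sample_id '", manifest$sample_id[i],
                 "': ", ifelse(is.na(p) || !nzchar(p), "<no image_path>", p))
    }
    img <- tryCatch(png::readPNG(p), error = function(e) {
      stop_input("unreadable image for sample_id '", manifest$sample_id[i],
                 "': ", conditionMessage(e))
    })
    rows[[i]] <- toy_image_features(img)
  }
  dims <- unique(vapply(rows, length, integer(1)))
  if (length(dims) != 1) {
    stop_input("images have inconsistent channel counts; feature dimensions: ",
               paste(dims, collapse = ", "))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- toy_feature_names(ncol(mat))
  if (is.null(view_name)) view_name <- spec$name
  feature_view(view_name, manifest$sample_id, mat)
}

# Per-channel means and variances plus coarse 4x4 block means of luminance.
# Variance uses the population formula so a constant image gives exactly 0.
toy_image_features <- function(img) {
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  nc <- min(dim(img)[3], 3L)  # ignore alpha
  img <- img[, , seq_len(nc), drop = FALSE]
  ch_mean <- apply(img, 3, mean)
  ch_var <- apply(img, 3, function(x) mean((x - mean(x))^2))
  lum <- if (nc == 3) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img[, , 1]
  }
  blocks <- block_means(lum, 4L)
  c(ch_mean, ch_var, as.vector(t(blocks)))
}

toy_feature_names <- function(d) {
  nc <- (d - 16L) / 2L
  c(paste0("mean_c", seq_len(nc)), paste0("var_c", seq_len(nc)),
    paste0("block_", rep(seq_len(4), each = 4), "_", rep(seq_len(4), 4)))
}

# Mean of each cell of a k x k partition of the matrix (row/column index
# blocks by floor division; no interpolation).
block_means <- function(mat, k) {
  ri <- pmin(k, 1L + ((seq_len(nrow(mat)) - 1L) * k) %/% nrow(mat))
  ci <- pmin(k, 1L + ((seq_len(ncol(mat)) - 1L) * k) %/% ncol(mat))
  out <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      out[a, b] <- mean(mat[ri == a, ci == b])
    }
  }
  out
}

#' Write a small textured test PNG
#'
#' Utility for exercising the I/O and toy-backend paths in examples and
#' tests: writes a `size` x `size` grayscale PNG with seeded uniform noise,
#' or a constant image when `constant` is given.
#'
#' @param path Output path.
#' @param size Side length in pixels.
#' @param seed Integer seed for the texture.
#' @param constant Optional gray level in `[0, 1]`; overrides the texture.
#' @return `path`, invisibly.
#' @export
write_test_png <- function(path, size = 32, seed = 1, constant = NULL) {
  img <- if (is.null(constant)) {
    set.seed(seed)
    matrix(stats::runif(size * size), size, size)
  } else {
    matrix(constant, size, size)
  }
  png::writePNG(img, path)
  invisible(path)
}
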