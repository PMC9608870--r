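#' Rasterize projected vertex values onto a square pixel grid
#'
#' Partitions the Mollweide square \eqn{[-\sqrt2, \sqrt2]^2} into
#' `grid_size` x `grid_size` equal pixels and assigns each vertex to exactly
#' one pixel. Bins are half-open `[lo, hi)` with the last bin closed on both
#' axes; rows are indexed top-down from +y. A pixel's value is the arithmetic
#' mean of the values of the vertices assigned to it; pixels containing no
#' vertex are 0.
#'
#' @param coords data frame with columns `x`, `y` (and optionally
#'   `vertex_id`) as returned by [project_hemisphere()].
#' @param values numeric vector, one value per row of `coords`.
#' @param grid_size pixels per side (default 60).
#' @return list with `image` (`grid_size` x `grid_size` matrix) and `map`
#'   (a `projection_map` for this hemisphere: per-vertex `row`, `col`,
#'   `pixel` linear index, per-pixel `counts`, and `grid_size`).
#' @export
rasterize <- function(coords, values, grid_size = 60) {
  if (grid_size < 1) stop_("grid_size must be >= 1")
  stopifnot(length(values) == nrow(coords))
  map <- pixel_assignment(coords, grid_size)
  image <- raster_from_map(map, values)
  list(image = image, map = map)
}

# Vertex -> pixel assignment for one hemisphere raster.
pixel_assignment <- function(coords, grid_size) {
  lim <- sqrt(2)
  h <- 2 * lim / grid_size
  clip <- function(i) pmin(pmax(i, 1L), as.integer(grid_size))
  col <- clip(as.integer(floor((coords$x + lim) / h)) + 1L)
  row_bottom <- clip(as.integer(floor((coords$y + lim) / h)) + 1L)
  row <- as.integer(grid_size) + 1L - row_bottom   # top-down from +y
  pixel <- row + grid_size * (col - 1L)            # column-major linear index
  counts <- tabulate(pixel, nbins = grid_size^2)
  structure(
    list(vertex_id = coords$vertex_id %||% seq_len(nrow(coords)),
         row = row, col = col, pixel = pixel,
         counts = counts, grid_size = as.integer(grid_size)),
    class = "projection_map"
  )
}

# Mean-pool values into the raster described by a projection_map.
raster_from_map <- function(map, values) {
  g2 <- map$grid_size^2
  sums <- numeric(g2)
  agg <- rowsum(values, group = map$pixel)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  img <- sums / pmax(map$counts, 1L)
  matrix(img, map$grid_size, map$grid_size)
}

#' Invert a projection map: vertices sharing each pixel
#'
#' @param map a `projection_map`.
#' @return list of integer vectors, one per pixel (linear index), giving the
#'   vertex ids assigned to that pixel; empty pixels give empty vectors.
#' @export
pixel_to_vertices <- function(map) {
  stopifnot(inherits(map, "projection_map"))
  n_px <- prod(map$image_dim %||% c(map$grid_size, map$grid_size))
  out <- vector("list", n_px)
  grp <- split(map$vertex_id, map$pixel)
  out[as.integer(names(grp))] <- grp
  out[vapply(out, is.null, logical(1))] <- list(integer(0))
  out
}

#' Assemble the two hemisphere rasters and z-score the image
#'
#' Concatenates the left and right hemisphere squares horizontally (left in
#' columns 1..g, right in g+1..2g) and standardizes the whole image to
#' z-scores: \eqn{(p - \bar p)/s}. A constant image (zero SD) is returned as
#' all zeros.
#'
#' @param left_img,right_img square matrices of equal size.
#' @return matrix `g x 2g` with mean 0 and SD 1 (unless degenerate).
#' @export
assemble_and_standardize <- function(left_img, right_img) {
  if (!all(dim(left_img) == dim(right_img)) ||
      nrow(left_img) != ncol(left_img)) {
    stop_("hemisphere images must be square and of equal size")
  }
  img <- cbind(left_img, right_img)
  s <- sd(as.vector(img))
  if (!is.finite(s) || s == 0) {
    img[] <- 0
    return(img)
  }
  (img - mean(img)) / s
}

#' Build the combined vertex-to-pixel map of a source space
#'
#' Projects both hemispheres with the Mollweide projection and records, for
#' every vertex, its pixel in the combined `g x 2g` trial image (left
#' hemisphere in columns 1..g, right in g+1..2g). The map is what makes LRP
#' heatmaps invertible back to the cortex.
#'
#' @param space a `cortical_space`.
#' @param grid_size pixels per hemisphere side (default 60).
#' @return object of class `projection_map` covering all vertices of the
#'   space, with fields `vertex_id`, `row`, `col` (combined image column),
#'   `pixel` (linear index in the combined image, column-major), `counts`
#'   (per combined pixel), `grid_size`, `image_dim = c(g, 2g)`.
#' @export
build_projection_map <- function(space, grid_size = 60) {
  stopifnot(inherits(space, "cortical_space"))
  g <- as.integer(grid_size)
  lmap <- pixel_assignment(project_hemisphere(space, "left"), g)
  rmap <- pixel_assignment(project_hemisphere(space, "right"), g)
  vertex_id <- c(lmap$vertex_id, rmap$vertex_id)
  row <- c(lmap$row, rmap$row)
  col <- c(lmap$col, rmap$col + g)
  pixel <- row + g * (col - 1L)
  counts <- tabulate(pixel, nbins = 2L * g^2)
  ord <- order(vertex_id)
  structure(
    list(vertex_id = vertex_id[ord], row = row[ord], col = col[ord],
         pixel = pixel[ord], counts = counts, grid_size = g,
         image_dim = c(g, 2L * g)),
    class = "projection_map"
  )
}

#' Project windowed trials to standardized 2D input images
#'
#' Converts a windowed trial set (trials x vertices) into z-scored Mollweide
#' images (one `g x 2g` image per trial, stored flat in column-major order).
#'
#' @param windowed a `windowed_trials` object.
#' @param space the `cortical_space` the trials were simulated on.
#' @param grid_size pixels per hemisphere side (default 60).
#' @return object of class `trial_images`: list with `images` (matrix,
#'   trials x pixels), `image_dim`, `map` (`projection_map`), `subject`,
#'   `group`.
#' @export
project_trials <- function(windowed, space, grid_size = 60) {
  stopifnot(inherits(windowed, "windowed_trials"))
  map <- build_projection_map(space, grid_size)
  n_px <- prod(map$image_dim)
  # sparse vertex -> pixel pooling operator (mean over vertices per pixel)
  P <- Matrix::sparseMatrix(i = map$vertex_id, j = map$pixel,
                            x = 1 / map$counts[map$pixel],
                            dims = c(ncol(windowed$data), n_px))
  imgs <- as.matrix(windowed$data %*% P)
  # per-image z-scoring
  mu <- rowMeans(imgs)
  s <- sqrt(rowSums((imgs - mu)^2) / (n_px - 1))
  degenerate <- !is.finite(s) | s == 0
  s[degenerate] <- 1
  imgs <- (imgs - mu) / s
  imgs[degenerate, ] <- 0

  structure(
    list(images = imgs, image_dim = map$image_dim, map = map,
         subject = windowed$subject, group = windowed$group),
    class = "trial_images"
  )
}

#' @export
print.trial_images <- function(x, ...) {
  cat("Trial images:", nrow(x$images), "trials,",
      x$image_dim[1], "x", x$image_dim[2], "pixels",
      sprintf("(%.0f%% empty pixels)\n", 100 * mean(x$map$counts == 0)))
  invisible(x)
}

#' @export
print.projection_map <- function(x, ...) {
  dim_txt <- if (!is.null(x$image_dim)) {
    paste(x$image_dim[1], "x", x$image_dim[2])
  } else {
    paste(x$grid_size, "x", x$grid_size)
  }
  cat("Projection map:", length(x$vertex_id), "vertices ->", dim_txt,
      "pixels;", sum(x$counts == 0), "empty pixels\n")
  invisible(x)
}
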