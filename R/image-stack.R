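#' 3D image stack with physical voxel size
#'
#' Lightweight container for a single-channel z-stack. Voxel indices are
#' 0-based throughout the package: the physical position of voxel index
#' `(i, j, k)` is `(i, j, k) * voxel_size` in nm, so that thresholds stated in
#' nm (150 nm contact, 200 nm association) can be applied directly.
#'
#' @param voxels 3D numeric array of non-negative intensities, dimensions
#'   (x, y, z). A 2D matrix is promoted to a single-plane stack.
#' @param voxel_size numeric length-3, voxel pitch in nm for (x, y, z).
#'   Defaults to the lateral camera pixel of 107.9 nm and the 200 nm z-step
#'   used in the imaging runs this package models.
#' @param channel,round optional channel tag and hybridization round index.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, voxel_size = c(107.9, 107.9, 200),
                        channel = NULL, round = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("image_stack intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (x, y, z nm)")
  structure(
    list(voxels = voxels, voxel_size = voxel_size, channel = channel,
         round = round),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels, voxel size %.1f x %.1f x %.1f nm",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (!is.null(x$channel)) cat(", channel:", x$channel)
  cat("\n")
  invisible(x)
}

#' Binary voxel mask
#'
#' @param mask logical 3D array (same shape as the source stack).
#' @param voxel_size voxel pitch in nm, as in [image_stack()].
#' @param kind `"nuclear_edge"` or `"nucleolus"`.
#' @return A `voxel_mask` object.
#' @export
voxel_mask <- function(mask, voxel_size = c(107.9, 107.9, 200),
                       kind = c("nuclear_edge", "nucleolus")) {
  kind <- match.arg(kind)
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask))
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size), kind = kind),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> kind: %s, %s voxels, %d set\n", x$kind,
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

as_stack <- function(x) {
  if (inherits(x, "image_stack")) return(x)
  image_stack(x)
}

# ---- shared image-processing primitives --------------------------------

# Local-mean background profile a la MATLAB adaptthresh: box-filtered local
# mean scaled by (1.5 - sensitivity), so higher sensitivity lowers the
# estimated background / threshold. Neighborhood defaults to the adaptthresh
# default 2*floor(size/16)+1.
adaptive_background <- function(img, sensitivity = 0.5, size = NULL) {
  if (is.null(size)) size <- 2L * floor(min(dim(img)) / 16) + 1L
  size <- max(3L, as.integer(size))
  if (size %% 2L == 0L) size <- size + 1L
  kern <- matrix(1 / (size * size), size, size)
  bg <- EBImage::filter2(img, kern, boundary = "replicate")
  bg * (1.5 - sensitivity)
}

adaptive_binarize <- function(img, sensitivity = 0.5, size = NULL) {
  img > adaptive_background(img, sensitivity, size)
}

# rescale into [0, 1] after clipping at the given probabilities; when the
# quantile window is degenerate (flat image plus rare structure) fall back to
# the full range so that structure is not drowned in numerical noise
clip_rescale <- function(img, lower_prob, upper_prob) {
  q <- quantile(img, c(lower_prob, upper_prob), names = FALSE)
  rng <- range(img)
  if (rng[2] <= rng[1]) return(array(0, dim(img)))
  if ((q[2] - q[1]) < 1e-3 * (rng[2] - rng[1])) q <- rng
  img <- pmin(pmax(img, q[1]), q[2])
  (img - q[1]) / (q[2] - q[1])
}

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

# grayscale opening by reconstruction: erosion marker, then geodesic dilation
# under the original image until stable (capped iteration count).
opening_by_reconstruction <- function(img, radius, max_iter = 100L) {
  marker <- EBImage::erode(img, disc_brush(radius))
  kern <- EBImage::makeBrush(3L, shape = "box")
  for (i in seq_len(max_iter)) {
    nxt <- pmin(EBImage::dilate(marker, kern), img)
    if (max(abs(nxt - marker)) < 1e-9) return(nxt)
    marker <- nxt
  }
  marker
}

# central-difference 2D gradient magnitude
gradient_magnitude <- function(img) {
  n <- nrow(img); m <- ncol(img)
  gx <- img[c(2:n, n), ] - img[c(1, 1:(n - 1)), ]
  gy <- img[, c(2:m, m)] - img[, c(1, 1:(m - 1))]
  sqrt(gx^2 + gy^2) / 2
}

# regional maxima (plateau-inclusive): pixels equal to the max over their
# 3x3 neighborhood
regional_maxima <- function(img) {
  img == EBImage::dilate(img, EBImage::makeBrush(3L, "box"))
}
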