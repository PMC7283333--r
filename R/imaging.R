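#' Segment cells from a membrane-stain stack
#'
#' Watershed segmentation of a WGA-style membrane stain, for tissue that is
#' essentially a cell monolayer. Pipeline: z-average, min-max normalization,
#' light Gaussian denoising (`smoothing_sigma`),
#' adaptive local-mean background (sensitivity 0.1, 41 px neighborhood),
#' background division, clipping at the 1st/99th intensity percentiles,
#' morphological closing (disk radius 15 px) to connect membrane ridges, then
#' watershed on the inverted ridge image (cell interiors are basins).
#' Retained segments must have an area strictly inside `area_limits` and must
#' not touch the field edge; everything else stays in the label map but is
#' listed in `excluded` with a reason (`too-small`, `too-large`, `edge`).
#'
#' @param wga_stack an [image_stack()] (or 2D/3D array) of the membrane stain.
#' @param sensitivity,background_size adaptive-background parameters.
#' @param closing_radius disk radius (px) for the closing step.
#' @param area_limits open interval (px) of retained cell areas.
#' @param watershed_tolerance minimum basin depth passed to
#'   [EBImage::watershed()].
#' @param smoothing_sigma Gaussian denoising sigma (px) applied to the
#'   z-averaged image; 0 disables.
#' @return A `cell_label_map`: list with `labels` (integer matrix, background
#'   0, labels contiguous 1..K), `excluded` (tibble: label, area, reason) and
#'   `retained` (integer vector of kept labels).
#' @export
segment_cells <- function(wga_stack, sensitivity = 0.1, background_size = 41L,
                          closing_radius = 15L, area_limits = c(2500, 20000),
                          watershed_tolerance = 0.2, smoothing_sigma = 1) {
  stack <- as_stack(wga_stack)
  avg <- apply(stack$voxels, c(1, 2), mean)
  rng <- range(avg)
  if (rng[2] <= rng[1])
    stop("cannot segment a constant image: no intensity gradients")
  norm <- (avg - rng[1]) / (rng[2] - rng[1])
  if (smoothing_sigma > 0) norm <- EBImage::gblur(norm, smoothing_sigma)
  bg <- adaptive_background(norm, sensitivity, background_size)
  flat <- norm / pmax(bg, 1e-6)
  clipped <- clip_rescale(flat, 0.01, 0.99)
  closed <- EBImage::closing(clipped, disc_brush(closing_radius))
  inverted <- max(closed) - closed
  labels <- EBImage::watershed(inverted, tolerance = watershed_tolerance)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  labels <- relabel_contiguous(labels)
  classify_labels(labels, area_limits)
}

relabel_contiguous <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  out
}

classify_labels <- function(labels, area_limits) {
  ids <- sort(unique(labels[labels > 0]))
  areas <- tabulate(labels[labels > 0], nbins = max(ids, 1L))[ids]
  edge <- unique(c(labels[1, ], labels[nrow(labels), ],
                   labels[, 1], labels[, ncol(labels)]))
  reason <- character(length(ids))
  reason[areas <= area_limits[1]] <- "too-small"
  reason[areas >= area_limits[2]] <- "too-large"
  reason[ids %in% edge & reason == ""] <- "edge"
  excluded <- tibble::tibble(label = ids, area = areas, reason = reason)
  excluded <- excluded[excluded$reason != "", , drop = FALSE]
  structure(list(labels = labels,
                 excluded = excluded,
                 retained = setdiff(ids, excluded$label)),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d labels (%d retained, %d excluded)\n",
              max(x$labels), length(x$retained), nrow(x$excluded)))
  invisible(x)
}

#' Nuclear-edge voxel mask from a nuclear stain stack
#'
#' Identifies voxels near the boundary of imaged nuclei, used as the proxy
#' for the nuclear lamina in lamina-association calls. Per z-plane:
#' normalization to the plane maximum, adaptive local-mean background
#' (sensitivity 0.5) and division, clipping at the 1st/3rd intensity
#' quartiles, opening by reconstruction (disk radius 25 px), 2D gradient
#' magnitude, Gaussian smoothing (sigma 5 px), adaptive binarization
#' (sensitivity 0.1). An all-zero plane yields an all-false plane.
#'
#' @param nucleus_stack an [image_stack()] of the nuclear stain.
#' @param opening_radius,gradient_sigma,sensitivity tunables of the pipeline
#'   above.
#' @return A [voxel_mask()] of kind `"nuclear_edge"`.
#' @export
nuclear_edge_mask <- function(nucleus_stack, opening_radius = 25L,
                              gradient_sigma = 5, sensitivity = 0.1) {
  stack <- as_stack(nucleus_stack)
  d <- dim(stack$voxels)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    plane <- stack$voxels[, , k]
    mx <- max(plane)
    if (mx <= 0) next
    plane <- plane / mx
    bg <- adaptive_background(plane, 0.5)
    flat <- plane / pmax(bg, 1e-6)
    clipped <- clip_rescale(flat, 0.25, 0.75)
    opened <- opening_by_reconstruction(clipped, opening_radius)
    grad <- gradient_magnitude(opened)
    smooth <- EBImage::gblur(grad, sigma = gradient_sigma)
    # adaptive call plus an absolute floor so that flat regions whose local
    # mean is near zero do not binarize on numerical noise
    out[, , k] <- adaptive_binarize(smooth, sensitivity) &
      smooth > 0.1 * max(smooth)
  }
  voxel_mask(out, stack$voxel_size, "nuclear_edge")
}

#' Nucleolus voxel mask from a fibrillarin stack
#'
#' Binarizes the nucleolar (fibrillarin immunofluorescence) stack with one
#' adaptive threshold profile shared across z: median-filter the maximum
#' z-projection, normalize it by its maximum (the stored normalization
#' factor), derive an adaptive local-mean threshold profile from it; then
#' binarize each plane after the same median filter and normalization.
#' A voxel value of TRUE means nucleolus-occupied. A stack with zero maximum
#' intensity yields an all-false mask.
#'
#' @param fibrillarin_stack an [image_stack()] of the nucleolar stain.
#' @param median_radius radius of the median filter.
#' @param sensitivity sensitivity of the adaptive threshold profile.
#' @return A [voxel_mask()] of kind `"nucleolus"`.
#' @export
nucleolus_mask <- function(fibrillarin_stack, median_radius = 2L,
                           sensitivity = 0.3) {
  stack <- as_stack(fibrillarin_stack)
  d <- dim(stack$voxels)
  gmax <- max(stack$voxels)
  if (gmax <= 0)
    return(voxel_mask(array(FALSE, d), stack$voxel_size, "nucleolus"))
  vox <- stack$voxels / gmax # keep medianFilter in [0,1]
  proj <- apply(vox, c(1, 2), max)
  projf <- EBImage::medianFilter(proj, median_radius)
  factor <- max(projf)
  if (factor <= 0)
    return(voxel_mask(array(FALSE, d), stack$voxel_size, "nucleolus"))
  profile <- adaptive_background(projf / factor, sensitivity)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    plane <- EBImage::medianFilter(vox[, , k], median_radius) / factor
    # small absolute floor: keeps FFT round-off in the local-mean profile from
    # binarizing empty background
    out[, , k] <- plane > pmax(profile, 1e-3)
  }
  voxel_mask(out, stack$voxel_size, "nucleolus")
}

#' Fit 3D Gaussian spots at candidate positions
#'
#' Least-squares fit of an isotropic-in-xy 3D Gaussian plus constant
#' background in a local window around each seed, giving sub-voxel center
#' estimates for FISH spots. A fit fails (success = FALSE) when the local
#' window is clipped below `min_window`, the optimizer does not converge, or
#' the fitted amplitude does not exceed the fitted background.
#'
#' @param stack an [image_stack()].
#' @param seeds matrix/data frame of seed voxel indices (0-based, columns
#'   x, y, z).
#' @param window half-widths (voxels) of the fitting window in x, y, z.
#' @param min_window minimum allowed window extent per axis after clipping.
#' @return Tibble with one row per seed: fitted center in voxel units
#'   (`x_px`, `y_px`, `z_px`, 0-based) and nm (`x_nm`, ...), `amplitude`,
#'   `background`, widths, residual standard deviation and `success`.
#' @export
fit_spots_3d <- function(stack, seeds, window = c(5L, 5L, 3L),
                         min_window = c(5L, 5L, 3L)) {
  stack <- as_stack(stack)
  vox <- stack$voxels
  d <- dim(vox)
  seeds <- as.matrix(as.data.frame(seeds)[, 1:3])
  res <- purrr::map(seq_len(nrow(seeds)), function(i) {
    s <- round(seeds[i, ]) + 1 # to 1-based array indices
    if (any(s < 1) || any(s > d)) return(failed_fit(i))
    lo <- pmax(s - window, 1)
    hi <- pmin(s + window, d)
    if (any(hi - lo + 1 < min_window)) return(failed_fit(i))
    sub <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    fit_one_spot(sub, lo, stack$voxel_size, i)
  })
  dplyr::bind_rows(res)
}

failed_fit <- function(seed_id) {
  tibble::tibble(seed_id = seed_id, x_px = NA_real_, y_px = NA_real_,
                 z_px = NA_real_, x_nm = NA_real_, y_nm = NA_real_,
                 z_nm = NA_real_, amplitude = NA_real_, background = NA_real_,
                 sigma_xy = NA_real_, sigma_z = NA_real_, residual = NA_real_,
                 success = FALSE)
}

fit_one_spot <- function(sub, lo, voxel_size, seed_id) {
  dd <- dim(sub)
  grid <- expand.grid(x = seq_len(dd[1]), y = seq_len(dd[2]), z = seq_len(dd[3]))
  val <- as.vector(sub)
  peak <- which.max(val)
  start <- list(bg = min(val), A = max(val) - min(val),
                x0 = grid$x[peak], y0 = grid$y[peak], z0 = grid$z[peak],
                sxy = 1.3, sz = 1.2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      val ~ bg + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sxy^2) -
                           (z - z0)^2 / (2 * sz^2)),
      data = cbind(grid, val = val), start = start,
      lower = c(bg = -Inf, A = 0, x0 = 0.5, y0 = 0.5, z0 = 0.5,
                sxy = 0.3, sz = 0.3),
      upper = c(bg = Inf, A = Inf, x0 = dd[1] + 0.5, y0 = dd[2] + 0.5,
                z0 = dd[3] + 0.5, sxy = dd[1], sz = dd[3]),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit(seed_id))
  p <- as.list(coef(fit))
  # back to 0-based whole-stack voxel coordinates
  cx <- p$x0 + lo[1] - 2; cy <- p$y0 + lo[2] - 2; cz <- p$z0 + lo[3] - 2
  ok <- is.finite(p$A) && is.finite(p$bg) && p$A > max(p$bg, 0)
  tibble::tibble(seed_id = seed_id, x_px = cx, y_px = cy, z_px = cz,
                 x_nm = cx * voxel_size[1], y_nm = cy * voxel_size[2],
                 z_nm = cz * voxel_size[3], amplitude = p$A,
                 background = p$bg, sigma_xy = p$sxy, sigma_z = p$sz,
                 residual = sd(stats::residuals(fit)), success = ok)
}

#' Estimate per-round stage drift from fiducial beads
#'
#' Beads are detected in every round (regional maxima above a fraction of the
#' round's peak intensity, refined by Gaussian fitting), coarsely aligned to
#' the reference round by integer cross-correlation of the maximum
#' projections, matched by nearest neighbor within `match_radius_px`, and the
#' per-round offset is the median displacement of the matched beads (robust
#' to individual mismatches). Offsets follow the convention "position in
#' round r = true position + offset r", so correction subtracts the offset.
#'
#' @param bead_stacks list of [image_stack()], one per round.
#' @param reference_round index of the reference round (offset 0).
#' @param dim `"3d"` (chromatin tracing) or `"2d"` (decoding; z offset 0).
#' @param match_radius_px nearest-neighbor match radius after coarse
#'   alignment, in px.
#' @param detect_quantile intensity fraction of the round maximum above which
#'   regional maxima are treated as bead candidates.
#' @return A `drift_table` tibble: round, dx_nm, dy_nm, dz_nm, n_beads, with
#'   attribute `reference_round`.
#' @export
estimate_drift <- function(bead_stacks, reference_round = 1L,
                           dim = c("3d", "2d"), match_radius_px = 5,
                           detect_quantile = 0.3) {
  dim <- match.arg(dim)
  reference_round <- as.integer(reference_round)
  stacks <- lapply(bead_stacks, as_stack)
  n_rounds <- length(stacks)
  stopifnot(n_rounds >= 1, reference_round >= 1, reference_round <= n_rounds)
  centers <- lapply(stacks, detect_beads, detect_quantile = detect_quantile)
  ref <- centers[[reference_round]]
  if (nrow(ref) < 3) stop("fewer than 3 beads detected in the reference round")
  vs <- stacks[[reference_round]]$voxel_size
  rows <- lapply(seq_len(n_rounds), function(r) {
    if (r == reference_round)
      return(tibble::tibble(round = r, dx_nm = 0, dy_nm = 0, dz_nm = 0,
                            n_beads = nrow(ref)))
    cur <- centers[[r]]
    coarse <- coarse_shift(stacks[[reference_round]], stacks[[r]])
    shifted <- cur
    shifted$x_px <- shifted$x_px - coarse[1]
    shifted$y_px <- shifted$y_px - coarse[2]
    m <- match_beads(ref, shifted, match_radius_px)
    if (nrow(m) < 3)
      stop(sprintf("round %d: fewer than 3 beads matched; drift unreliable", r))
    dx <- median(cur$x_px[m$cur] - ref$x_px[m$ref])
    dy <- median(cur$y_px[m$cur] - ref$y_px[m$ref])
    dz <- if (dim == "3d") median(cur$z_px[m$cur] - ref$z_px[m$ref]) else 0
    tibble::tibble(round = r, dx_nm = dx * vs[1], dy_nm = dy * vs[2],
                   dz_nm = dz * vs[3], n_beads = nrow(m))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reference_round") <- reference_round
  class(out) <- c("drift_table", class(out))
  out
}

detect_beads <- function(stack, detect_quantile = 0.3) {
  vox <- stack$voxels
  d <- dim(vox)
  thr <- detect_quantile * max(vox)
  cand <- NULL
  for (k in seq_len(d[3])) {
    plane <- vox[, , k]
    mx <- regional_maxima(plane) & plane > thr
    idx <- which(mx, arr.ind = TRUE)
    if (nrow(idx) > 0)
      cand <- rbind(cand, cbind(idx, k, plane[mx]))
  }
  if (is.null(cand)) return(tibble::tibble(x_px = numeric(), y_px = numeric(),
                                           z_px = numeric()))
  # keep per (x,y) cluster the brightest z; merge near-duplicates laterally
  df <- tibble::tibble(x = cand[, 1] - 1, y = cand[, 2] - 1, z = cand[, 3] - 1,
                       v = cand[, 4])
  df <- df[order(-df$v), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      later <- (i + 1):nrow(df)
      close <- abs(df$x[later] - df$x[i]) <= 2 & abs(df$y[later] - df$y[i]) <= 2
      keep[later][close] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  fits <- fit_spots_3d(stack, df[, c("x", "y", "z")])
  ok <- fits$success & !is.na(fits$x_px)
  tibble::tibble(x_px = fits$x_px[ok], y_px = fits$y_px[ok],
                 z_px = fits$z_px[ok])
}

coarse_shift <- function(ref_stack, cur_stack) {
  a <- apply(ref_stack$voxels, c(1, 2), max)
  b <- apply(cur_stack$voxels, c(1, 2), max)
  # integer-shift maximizing circular cross-correlation via FFT
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE))
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sx <- w[1] - 1; sy <- w[2] - 1
  if (sx > nrow(a) / 2) sx <- sx - nrow(a)
  if (sy > ncol(a) / 2) sy <- sy - ncol(a)
  c(sx, sy)
}

match_beads <- function(ref, cur, radius) {
  if (nrow(cur) == 0) return(data.frame(ref = integer(), cur = integer()))
  out <- lapply(seq_len(nrow(ref)), function(i) {
    d2 <- (cur$x_px - ref$x_px[i])^2 + (cur$y_px - ref$y_px[i])^2
    j <- which.min(d2)
    if (length(j) == 1 && d2[j] <= radius^2) data.frame(ref = i, cur = j)
    else NULL
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(data.frame(ref = integer(), cur = integer()))
  out[!duplicated(out$cur), , drop = FALSE]
}

#' Apply a drift table to physical coordinates
#'
#' @param positions tibble with `round`, `x_nm`, `y_nm`, `z_nm`.
#' @param drift a `drift_table` from [estimate_drift()].
#' @return `positions` with the per-round offsets subtracted.
#' @export
apply_drift <- function(positions, drift) {
  stopifnot(all(c("round", "x_nm", "y_nm", "z_nm") %in% names(positions)))
  idx <- match(positions$round, drift$round)
  if (anyNA(idx)) stop("positions reference rounds absent from the drift table")
  positions$x_nm <- positions$x_nm - drift$dx_nm[idx]
  positions$y_nm <- positions$y_nm - drift$dy_nm[idx]
  positions$z_nm <- positions$z_nm - drift$dz_nm[idx]
  positions
}

#' Link drift-corrected locus positions into chromatin traces
#'
#' Within each nucleus, positions from all readouts are partitioned into at
#' most two spatial clusters (the two chromosome copies of a diploid nucleus)
#' by single-linkage agglomeration cut at `1.5 * territory_radius_nm`. When
#' more than two clusters survive the cut, the two with the most positions
#' are kept (ties broken by total fit amplitude) and the rest are left
#' unassigned. Each trace keeps at most one position per readout, the
#' brightest fit winning; readouts with no assigned position are recorded as
#' missing (NA coordinates).
#'
#' @param positions tibble with `cell_id`, `readout_id`, `x_nm`, `y_nm`,
#'   `z_nm` and optionally `quality` (fit amplitude; defaults to 1).
#' @param n_readouts total number of readouts (regions); defaults to the
#'   maximum observed.
#' @param territory_radius_nm expected chromosome-territory radius.
#' @return Trace tibble: `cell_id`, `copy_id`, `region_id`, `x_nm`, `y_nm`,
#'   `z_nm`, `quality`, with NA rows for missing loci.
#' @export
link_traces <- function(positions, n_readouts = NULL,
                        territory_radius_nm = 1500) {
  stopifnot(all(c("cell_id", "readout_id", "x_nm", "y_nm", "z_nm") %in%
                  names(positions)))
  if (!"quality" %in% names(positions)) positions$quality <- 1
  n_readouts <- n_readouts %||% max(positions$readout_id, 0L)
  cutoff <- 1.5 * territory_radius_nm
  out <- positions |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(df, key) {
      link_one_nucleus(df, key$cell_id, n_readouts, cutoff)
    }) |>
    dplyr::bind_rows()
  out
}

link_one_nucleus <- function(df, cell_id, n_readouts, cutoff) {
  if (nrow(df) == 0) return(NULL)
  pts <- as.matrix(df[, c("x_nm", "y_nm", "z_nm")])
  if (nrow(df) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(pts), method = "single")
    cl <- cutree(hc, h = cutoff)
  }
  sizes <- table(cl)
  if (length(sizes) > 2) {
    amp <- tapply(df$quality, cl, sum)
    ord <- order(-as.vector(sizes), -as.vector(amp))
    keep_cl <- as.integer(names(sizes))[ord[1:2]]
  } else keep_cl <- as.integer(names(sizes))
  purrr::map(seq_along(keep_cl), function(ci) {
    sub <- df[cl == keep_cl[ci], , drop = FALSE]
    # one position per readout: brightest fit wins
    sub <- sub[order(-sub$quality), ]
    sub <- sub[!duplicated(sub$readout_id), , drop = FALSE]
    full <- tibble::tibble(cell_id = cell_id, copy_id = ci,
                           region_id = seq_len(n_readouts))
    dplyr::left_join(
      full,
      sub[, c("readout_id", "x_nm", "y_nm", "z_nm", "quality")],
      by = c(region_id = "readout_id"))
  }) |> dplyr::bind_rows()
}

#' Mean best-match Jaccard overlap between a segmentation and planted labels
#'
#' For each planted cell, finds the segmented label with the largest overlap
#' and computes the Jaccard index (intersection over union) of the two pixel
#' sets.
#'
#' @param labels a `cell_label_map` (or integer label matrix).
#' @param truth planted integer label matrix (background 0).
#' @return Tibble: cell, matched_label, jaccard.
#' @export
segmentation_jaccard <- function(labels, truth) {
  lab <- if (inherits(labels, "cell_label_map")) labels$labels else labels
  ids <- sort(unique(truth[truth > 0]))
  purrr::map_dfr(ids, function(i) {
    tm <- truth == i
    cand <- table(lab[tm])
    cand <- cand[names(cand) != "0"]
    if (length(cand) == 0)
      return(tibble::tibble(cell = i, matched_label = NA_integer_,
                            jaccard = 0))
    best <- as.integer(names(which.max(cand)))
    tibble::tibble(cell = i, matched_label = best,
                   jaccard = sum(tm & (lab == best)) / sum(tm | (lab == best)))
  })
}
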