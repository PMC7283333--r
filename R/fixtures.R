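#' Generate a phantom tissue scene with known ground truth
#'
#' Builds a synthetic monolayer field of view: a packed tissue block whose
#' cells are Voronoi tiles of jittered grid centers, separated by thin bright
#' membrane walls and bounded by a bright tissue rim (the WGA-like channel);
#' each cell holds a filled ellipsoidal nucleus (nuclear-stain channel)
#' containing one or two bright nucleolar blobs (fibrillarin channel). Poisson shot noise on a
#' constant background is applied to every channel. All ground truth (label
#' map, nucleus/nucleolus geometry) is a pure function of `seed`.
#'
#' @param n_cells number of cells (>= 1).
#' @param fov_shape (nx, ny, nz) voxels.
#' @param voxel_size (x, y, z) nm per voxel.
#' @param seed RNG seed.
#' @param cell_radius_px cell size scale; cell centers are spaced 2.3 radii
#'   apart and the field must be large enough to hold the grid.
#' @param background,membrane_amp,nucleus_amp,nucleolus_amp photon levels.
#' @param noise `"poisson"` or `"none"`.
#' @return List with `truth` (cells tibble, `label_map`, nuclei, nucleoli)
#'   and `stacks` (membrane, nucleus, fibrillarin [image_stack()]s).
#' @export
gen_scene <- function(n_cells, fov_shape = c(512L, 512L, 10L),
                      voxel_size = c(107.9, 107.9, 200), seed = 1L,
                      cell_radius_px = 50, background = 20,
                      membrane_amp = 150, nucleus_amp = 100,
                      nucleolus_amp = 200, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(n_cells >= 1)
  nx <- fov_shape[1]; ny <- fov_shape[2]; nz <- fov_shape[3]
  grid_n <- ceiling(sqrt(n_cells))
  pitch <- 2.3 * cell_radius_px
  need <- grid_n * pitch + 2 * cell_radius_px
  if (need > min(nx, ny))
    stop(sprintf("field of view too small for %d cells of radius %.0f px",
                 n_cells, cell_radius_px))
  with_seed(seed, {
    gx <- (seq_len(grid_n) - (grid_n + 1) / 2) * pitch + nx / 2
    gy <- (seq_len(grid_n) - (grid_n + 1) / 2) * pitch + ny / 2
    centers <- expand.grid(cx = gx, cy = gy)[seq_len(n_cells), ]
    centers$cx <- centers$cx + runif(n_cells, -0.03, 0.03) * pitch
    centers$cy <- centers$cy + runif(n_cells, -0.03, 0.03) * pitch
    radii <- cell_radius_px * runif(n_cells, 0.9, 1.1)

    xs <- matrix(seq_len(nx) - 1, nx, ny)
    ys <- matrix(seq_len(ny) - 1, nx, ny, byrow = TRUE)
    # packed tissue: cells are Voronoi tiles of the jittered centers, clipped
    # by the tissue rim; membranes are thin walls on tile boundaries + rim
    d1 <- matrix(Inf, nx, ny); d2 <- matrix(Inf, nx, ny)
    which_cell <- matrix(0L, nx, ny)
    for (i in seq_len(n_cells)) {
      d <- sqrt((xs - centers$cx[i])^2 + (ys - centers$cy[i])^2)
      closer <- d < d1
      d2[closer] <- d1[closer]
      d1[closer] <- d[closer]
      which_cell[closer] <- i
      mid <- !closer & d < d2
      d2[mid] <- d[mid]
    }
    rim_r <- 0.62 * pitch
    wall <- (d2 - d1) < 3 & n_cells > 1
    rim <- abs(d1 - rim_r) <= 1.5
    inside <- d1 < rim_r - 1.5
    label_map <- matrix(0L, nx, ny)
    keep <- inside & !wall
    label_map[keep] <- which_cell[keep]
    membrane2d <- matrix(0, nx, ny)
    membrane2d[(wall & d1 < rim_r) | rim] <- membrane_amp
    membrane2d <- EBImage::gblur(membrane2d, sigma = 1)

    nuclei <- tibble::tibble(
      cell = seq_len(n_cells),
      cx = centers$cx, cy = centers$cy,
      cz = (nz - 1) / 2 + runif(n_cells, -0.5, 0.5),
      rx = radii * 0.55, ry = radii * 0.55,
      rz = pmax(nz * 0.3, 1.2))
    n_nucleoli <- sample(1:2, n_cells, replace = TRUE)
    nucleoli <- purrr::map_dfr(seq_len(n_cells), function(i) {
      k <- n_nucleoli[i]
      # strictly inside the nucleus: offset bounded well below nuclear radius
      ang <- runif(k, 0, 2 * pi)
      off <- runif(k, 0, 0.35)
      tibble::tibble(
        cell = i, nucleolus = seq_len(k),
        cx = nuclei$cx[i] + cos(ang) * off * nuclei$rx[i],
        cy = nuclei$cy[i] + sin(ang) * off * nuclei$ry[i],
        cz = nuclei$cz[i],
        rx = nuclei$rx[i] * runif(k, 0.18, 0.28),
        ry = nuclei$ry[i] * runif(k, 0.18, 0.28),
        rz = pmax(nuclei$rz[i] * 0.4, 0.8))
    })

    nucleus_stack <- array(0, c(nx, ny, nz))
    fib_stack <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      z <- k - 1
      for (i in seq_len(n_cells)) {
        dz2 <- ((z - nuclei$cz[i]) / nuclei$rz[i])^2
        if (dz2 < 1) {
          inside <- ((xs - nuclei$cx[i]) / nuclei$rx[i])^2 +
            ((ys - nuclei$cy[i]) / nuclei$ry[i])^2 <= 1 - dz2
          nucleus_stack[, , k][inside] <- nucleus_amp
        }
      }
      for (j in seq_len(nrow(nucleoli))) {
        dz2 <- ((z - nucleoli$cz[j]) / nucleoli$rz[j])^2
        if (dz2 < 1) {
          inside <- ((xs - nucleoli$cx[j]) / nucleoli$rx[j])^2 +
            ((ys - nucleoli$cy[j]) / nucleoli$ry[j])^2 <= 1 - dz2
          fib_stack[, , k][inside] <- nucleolus_amp
        }
      }
    }
    membrane_stack <- array(rep(membrane2d, nz), c(nx, ny, nz))

    shot <- function(a) {
      if (noise == "none") return(a + background)
      array(rpois(length(a), a + background), dim(a))
    }
    list(
      truth = list(
        seed = seed, voxel_size = voxel_size, fov_shape = fov_shape,
        cells = tibble::tibble(cell = seq_len(n_cells), cx = centers$cx,
                               cy = centers$cy, radius = radii),
        label_map = label_map, nuclei = nuclei, nucleoli = nucleoli),
      stacks = list(
        membrane = image_stack(shot(membrane_stack), voxel_size, "membrane"),
        nucleus = image_stack(shot(nucleus_stack), voxel_size, "nucleus"),
        fibrillarin = image_stack(shot(fib_stack), voxel_size, "fibrillarin")))
  })
}

#' Generate phantom chromatin traces with planted structure
#'
#' Samples per-chromosome-copy locus positions with two planted properties:
#' (a) the mean pairwise distance scales with genomic separation as a power
#' law with exponent `powerlaw_exponent` (positions are fractional Brownian
#' motion per axis, whose Hurst index is exactly that exponent), and (b)
#' positive-score and negative-score loci are displaced in opposite
#' directions along a random axis, with total centroid separation
#' `polarization_strength * separation_nm`. Isotropic Gaussian localization
#' noise and uniform random locus dropout complete the error model.
#'
#' @param n_cells number of cells, each with `copies_per_cell` chromosome
#'   copies.
#' @param scores per-locus compartment score (finite; length = locus count).
#' @param polarization_strength in `[0, 1]`.
#' @param powerlaw_exponent planted distance-scaling exponent (0, 1).
#' @param seed RNG seed.
#' @param step_nm mean spatial distance between genomically adjacent loci.
#' @param separation_nm compartment centroid separation at strength 1.
#' @param noise_nm localization noise s.d. (FISH fitting precision scale).
#' @param dropout per-locus missing probability.
#' @param copies_per_cell chromosome copies per cell (diploid default 2).
#' @param centers optional tibble of cell centers (`cx`, `cy` px) from
#'   [gen_scene()]; traces are then placed near those nuclei.
#' @param voxel_size used with `centers` to convert px to nm.
#' @return Trace tibble (`cell_id`, `copy_id`, `region_id`, `x_nm`, `y_nm`,
#'   `z_nm`, `quality`) with NA coordinates at dropped loci. The planted
#'   expectation parameters are attached as attribute `truth`.
#' @export
gen_traces <- function(n_cells, scores, polarization_strength = 0,
                       powerlaw_exponent = 0.33, seed = 1L, step_nm = 350,
                       separation_nm = 1200, noise_nm = 50, dropout = 0.1,
                       copies_per_cell = 2L, centers = NULL,
                       voxel_size = c(107.9, 107.9, 200)) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite")
  stopifnot(polarization_strength >= 0, polarization_strength <= 1,
            powerlaw_exponent > 0, powerlaw_exponent < 1)
  n <- length(scores)
  sigma <- step_nm / 1.5958 # E[chi_3] for unit per-axis variance
  # fBm covariance so E[d(i,j)] = step_nm * |i-j|^H exactly
  t <- seq_len(n) - 1
  H2 <- 2 * powerlaw_exponent
  C <- 0.5 * (outer(t^H2, t^H2, "+") - abs(outer(t, t, "-"))^H2) * sigma^2
  L <- chol(C[-1, -1] + diag(1e-8 * sigma^2, n - 1))
  signs <- ifelse(scores > 0, 1, -1)
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_cells), function(cell) {
      purrr::map(seq_len(copies_per_cell), function(copy) {
        pos <- matrix(0, n, 3)
        pos[-1, ] <- crossprod(L, matrix(rnorm(3 * (n - 1)), n - 1, 3))
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        shift <- (polarization_strength * separation_nm / 2) * signs
        pos <- pos + outer(shift, u)
        pos <- pos + matrix(rnorm(3 * n, 0, noise_nm), n, 3)
        if (!is.null(centers)) {
          origin <- c(centers$cx[cell] * voxel_size[1],
                      centers$cy[cell] * voxel_size[2],
                      0) + runif(3, -200, 200)
          pos <- sweep(pos, 2, origin, "+")
        }
        miss <- runif(n) < dropout
        tibble::tibble(cell_id = cell, copy_id = copy, region_id = seq_len(n),
                       x_nm = ifelse(miss, NA_real_, pos[, 1]),
                       y_nm = ifelse(miss, NA_real_, pos[, 2]),
                       z_nm = ifelse(miss, NA_real_, pos[, 3]),
                       quality = 1)
      }) |> dplyr::bind_rows()
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(step_nm = step_nm,
                               exponent = powerlaw_exponent,
                               noise_nm = noise_nm,
                               separation_nm = separation_nm,
                               polarization_strength = polarization_strength)
    out
  })
}

#' Planted expectation of the mean distance between two loci
#'
#' Closed form for the [gen_traces()] model without polarization: per-axis
#' displacement variance `sigma^2 |i-j|^(2H) + 2 noise^2`, so the expected
#' Euclidean distance is `E[chi_3] * sqrt(variance)`.
#'
#' @param truth the `truth` attribute of a [gen_traces()] result.
#' @param sep genomic separation |i - j| (loci).
#' @return Expected mean distance (nm).
#' @export
expected_pair_distance <- function(truth, sep) {
  sigma <- truth$step_nm / 1.5958
  v <- sigma^2 * sep^(2 * truth$exponent) + 2 * truth$noise_nm^2
  1.5958 * sqrt(v)
}

#' Generate multiplexed barcode imaging rounds from planted molecules
#'
#' Renders, for each of the 16 readout rounds, a z-stack in which every
#' molecule whose codeword has a 1-bit in that round appears as a 3D Gaussian
#' spot, plus a fiducial-bead channel per round; per-round drift offsets are
#' applied to both. Poisson noise is optional.
#'
#' @param codebook a [validate_codebook()] result.
#' @param molecules_per_gene molecules planted per gene.
#' @param fov_shape (nx, ny, nz) voxels.
#' @param psf_sigma Gaussian spot sigma, px (xy) and planes (z).
#' @param drift_truth 16 x 3 matrix of per-round drift (px); default zero.
#' @param bead_count fiducial beads.
#' @param seed RNG seed.
#' @param amplitude,background photon levels.
#' @param noise `"poisson"` or `"none"`.
#' @param molecules optional pre-placed molecule tibble (`gene_id`, `x_px`,
#'   `y_px`, `z_px`); positions must lie inside the field of view.
#' @return List: `rounds` (16 [image_stack()]s), `beads` (per-round bead
#'   stacks), `truth` (molecules, beads, drift).
#' @export
gen_merfish_stacks <- function(codebook, molecules_per_gene = 20L,
                               fov_shape = c(128L, 128L, 4L),
                               psf_sigma = c(1.1, 0.9),
                               drift_truth = NULL, bead_count = 8L,
                               seed = 1L, amplitude = 60, background = 2,
                               noise = c("poisson", "none"),
                               molecules = NULL) {
  noise <- match.arg(noise)
  stopifnot(psf_sigma[1] > 0)
  n_bits <- nchar(codebook$word[1])
  nx <- fov_shape[1]; ny <- fov_shape[2]; nz <- fov_shape[3]
  drift_truth <- drift_truth %||% matrix(0, n_bits, 3)
  stopifnot(nrow(drift_truth) == n_bits)
  bits <- codeword_bits(codebook$word, n_bits)
  margin <- 6
  with_seed(seed, {
    if (is.null(molecules)) {
      molecules <- purrr::map_dfr(seq_len(nrow(codebook)), function(g) {
        tibble::tibble(
          gene_id = codebook$gene_id[g],
          x_px = runif(molecules_per_gene, margin, nx - 1 - margin),
          y_px = runif(molecules_per_gene, margin, ny - 1 - margin),
          z_px = runif(molecules_per_gene, 0.5, nz - 1.5))
      })
    }
    if (any(molecules$x_px < 0 | molecules$x_px > nx - 1 |
              molecules$y_px < 0 | molecules$y_px > ny - 1 |
              molecules$z_px < 0 | molecules$z_px > nz - 1))
      stop("molecule placed outside the field of view")
    beads <- tibble::tibble(
      x_px = runif(bead_count, margin, nx - 1 - margin),
      y_px = runif(bead_count, margin, ny - 1 - margin),
      z_px = runif(bead_count, 0.8, nz - 1.8))
    gene_idx <- match(molecules$gene_id, codebook$gene_id)
    shot <- function(a) {
      if (noise == "none") return(a + background)
      array(rpois(length(a), a + background), dim(a))
    }
    render <- function(spots, dx, dy, dz) {
      img <- array(0, c(nx, ny, nz))
      if (nrow(spots) > 0)
        img <- render_spots(img, spots$x_px + dx, spots$y_px + dy,
                            spots$z_px + dz, amplitude, psf_sigma)
      img
    }
    rounds <- purrr::map(seq_len(n_bits), function(r) {
      on <- which(bits[gene_idx, r] == 1)
      image_stack(shot(render(molecules[on, ], drift_truth[r, 1],
                              drift_truth[r, 2], drift_truth[r, 3])),
                  channel = "rna", round = r)
    })
    bead_stacks <- purrr::map(seq_len(n_bits), function(r) {
      image_stack(shot(render(beads, drift_truth[r, 1], drift_truth[r, 2],
                              drift_truth[r, 3])),
                  channel = "beads", round = r)
    })
    list(rounds = rounds, beads = bead_stacks,
         truth = list(molecules = molecules, beads = beads,
                      drift = drift_truth, seed = seed))
  })
}

# add point-sampled 3D Gaussians to an image (vectorized over a local window)
render_spots <- function(img, x, y, z, amplitude, psf_sigma) {
  d <- dim(img)
  w <- ceiling(4 * psf_sigma[1])
  wz <- ceiling(4 * psf_sigma[2])
  for (i in seq_along(x)) {
    xi <- max(1, floor(x[i] - w) + 1):min(d[1], ceiling(x[i] + w) + 1)
    yi <- max(1, floor(y[i] - w) + 1):min(d[2], ceiling(y[i] + w) + 1)
    zi <- max(1, floor(z[i] - wz) + 1):min(d[3], ceiling(z[i] + wz) + 1)
    gx <- exp(-((xi - 1 - x[i])^2) / (2 * psf_sigma[1]^2))
    gy <- exp(-((yi - 1 - y[i])^2) / (2 * psf_sigma[1]^2))
    gz <- exp(-((zi - 1 - z[i])^2) / (2 * psf_sigma[2]^2))
    img[xi, yi, zi] <- img[xi, yi, zi] +
      amplitude * outer(outer(gx, gy), gz)
  }
  img
}

#' Generate synthetic Hi-C-like counts from traces
#'
#' Samples a symmetric, zero-diagonal contact-count matrix whose expected
#' counts follow either the empirical contact frequency of the traces at a
#' spatial threshold (`model = "contact"`) or a power of the mean spatial
#' distance, `mean_distance^-exponent` (`model = "powerlaw"`, for planting a
#' known scaling between counts and distance).
#'
#' @param traces trace tibble (>= 2 copies).
#' @param depth total expected read count (> 0).
#' @param seed RNG seed.
#' @param model `"contact"` or `"powerlaw"`.
#' @param contact_threshold_nm threshold for the contact model.
#' @param exponent planted exponent for the power-law model.
#' @param n_regions number of loci.
#' @return Integer count matrix (n x n), symmetric with zero diagonal.
#' @export
gen_hic_counts <- function(traces, depth = 1e5, seed = 1L,
                           model = c("contact", "powerlaw"),
                           contact_threshold_nm = 150, exponent = 5,
                           n_regions = NULL) {
  model <- match.arg(model)
  if (depth <= 0) stop("depth must be positive")
  copies <- split_copies(traces, n_regions)
  if (length(copies) < 2) stop("need at least 2 traces")
  n <- nrow(copies[[1]])
  w <- if (model == "contact") {
    cp <- contact_probability(traces, contact_threshold_nm,
                              n_regions = n_regions)
    p <- cp$probability
    p[is.na(p)] <- 0
    p
  } else {
    dm <- mean_distance_matrix(traces, min_pairs = 1L, n_regions = n_regions)
    m <- dm$mean
    m[is.na(m)] <- max(m, na.rm = TRUE)
    m[m <= 0] <- min(m[m > 0])
    m^(-exponent)
  }
  diag(w) <- 0
  up <- upper.tri(w)
  tot <- sum(w[up])
  if (tot <= 0) stop("no informative contacts to sample from")
  counts <- matrix(0L, n, n)
  with_seed(seed, {
    counts[up] <- rpois(sum(up), depth * w[up] / tot)
  })
  counts + t(counts)
}
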