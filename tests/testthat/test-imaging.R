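scene9 <- gen_scene(9, fov_shape = c(512L, 512L, 6L), seed = 1)

test_that("watershed segmentation recovers the planted cells", {
  lab <- segment_cells(scene9$stacks$membrane)
  expect_equal(length(lab$retained), 9)
  jac <- segmentation_jaccard(lab, scene9$truth$label_map)
  expect_true(all(jac$jaccard >= 0.8))
  # labels are contiguous and partition the non-background area
  ids <- sort(unique(lab$labels[lab$labels > 0]))
  expect_identical(ids, seq_along(ids))
  expect_true(all(!lab$excluded$label %in% lab$retained))
})

test_that("constant images cannot be segmented", {
  expect_error(segment_cells(array(7, c(64, 64, 2))), "constant")
})

test_that("undersized segments are excluded as too-small", {
  # one small and one normal cell drawn as membrane rings on a quiet field
  img <- matrix(5, 320, 320)
  xs <- matrix(seq_len(320) - 1, 320, 320)
  ys <- t(xs)
  d1 <- sqrt((xs - 80)^2 + (ys - 160)^2)   # radius 24 -> area ~1800 px
  d2 <- sqrt((xs - 220)^2 + (ys - 160)^2)  # radius 60 -> area ~11000 px
  img[abs(d1 - 24) <= 1.5] <- 150
  img[abs(d2 - 60) <= 1.5] <- 150
  lab <- segment_cells(image_stack(array(img, c(320, 320, 1))),
                       smoothing_sigma = 0)
  small_lab <- lab$labels[81, 161]
  big_lab <- lab$labels[221, 161]
  expect_true(small_lab %in% lab$excluded$label)
  expect_identical(
    lab$excluded$reason[lab$excluded$label == small_lab], "too-small")
  expect_true(big_lab %in% lab$retained)
})

test_that("nuclear-edge mask traces the planted nuclear boundaries", {
  sc <- gen_scene(4, fov_shape = c(360L, 360L, 6L), seed = 2)
  em <- nuclear_edge_mask(sc$stacks$nucleus, opening_radius = 10)
  expect_identical(dim(em$mask), dim(sc$stacks$nucleus$voxels))
  nu <- sc$truth$nuclei
  d <- dim(em$mask)
  covered <- c()
  for (k in seq_len(d[3])) {
    z <- k - 1
    for (i in seq_len(nrow(nu))) {
      dz2 <- ((z - nu$cz[i]) / nu$rz[i])^2
      if (dz2 >= 0.8) next
      rx <- nu$rx[i] * sqrt(1 - dz2); ry <- nu$ry[i] * sqrt(1 - dz2)
      th <- seq(0, 2 * pi, length.out = 120)
      bx <- round(nu$cx[i] + rx * cos(th)) + 1
      by <- round(nu$cy[i] + ry * sin(th)) + 1
      ok <- bx >= 3 & bx <= d[1] - 2 & by >= 3 & by <= d[2] - 2
      covered <- c(covered, vapply(which(ok), function(j) {
        any(em$mask[(bx[j] - 2):(bx[j] + 2), (by[j] - 2):(by[j] + 2), k])
      }, logical(1)))
    }
  }
  expect_gte(mean(covered), 0.8)
})

test_that("gradients mark both rings of an annulus and zero planes are empty", {
  xs <- matrix(seq_len(200) - 1, 200, 200); ys <- t(xs)
  d <- sqrt((xs - 100)^2 + (ys - 100)^2)
  solid <- matrix(0, 200, 200); solid[d < 60] <- 100
  holed <- solid; holed[d < 25] <- 0
  m_solid <- nuclear_edge_mask(image_stack(array(solid, c(200, 200, 1))),
                               opening_radius = 5)
  m_holed <- nuclear_edge_mask(image_stack(array(holed, c(200, 200, 1))),
                               opening_radius = 5)
  ring_at <- function(m, r) any(m$mask[, , 1][abs(d - r) < 4])
  expect_true(ring_at(m_solid, 60))
  expect_false(ring_at(m_solid, 25))
  expect_true(ring_at(m_holed, 60))
  expect_true(ring_at(m_holed, 25))
  # all-zero plane stays all-false
  zstack <- array(0, c(64, 64, 2)); zstack[, , 1] <- solid[1:64, 1:64]
  mz <- nuclear_edge_mask(image_stack(zstack), opening_radius = 5)
  expect_false(any(mz$mask[, , 2]))
})

test_that("nucleolus mask recovers planted blobs", {
  sc <- gen_scene(4, fov_shape = c(360L, 360L, 6L), seed = 2)
  nm <- nucleolus_mask(sc$stacks$fibrillarin)
  # discrete planted volume: voxels inside any nucleolar ellipsoid
  planted <- 0
  d <- dim(nm$mask)
  xs <- matrix(seq_len(d[1]) - 1, d[1], d[2]); ys <- t(xs)
  for (k in seq_len(d[3])) {
    z <- k - 1
    for (j in seq_len(nrow(sc$truth$nucleoli))) {
      no <- sc$truth$nucleoli[j, ]
      dz2 <- ((z - no$cz) / no$rz)^2
      if (dz2 < 1)
        planted <- planted +
          sum(((xs - no$cx) / no$rx)^2 + ((ys - no$cy) / no$ry)^2 <= 1 - dz2)
    }
  }
  expect_lt(abs(sum(nm$mask) - planted) / planted, 0.25)
  # two disjoint blobs -> two connected components
  img <- array(0, c(120, 120, 2))
  dd <- sqrt((xs[1:120, 1:120] - 30)^2 + (ys[1:120, 1:120] - 30)^2)
  dd2 <- sqrt((xs[1:120, 1:120] - 90)^2 + (ys[1:120, 1:120] - 90)^2)
  img[, , 1][dd < 8] <- 200; img[, , 1][dd2 < 8] <- 200
  img[, , 2] <- img[, , 1]
  m2 <- nucleolus_mask(image_stack(img))
  expect_equal(max(EBImage::bwlabel(m2$mask[, , 1] * 1)), 2)
  # empty stack -> all-false
  m0 <- nucleolus_mask(image_stack(array(0, c(32, 32, 2))))
  expect_false(any(m0$mask))
})

test_that("3D Gaussian fits localize planted spots to sub-voxel accuracy", {
  img <- array(0, c(200, 120, 7))
  img <- nucleome:::render_spots(img, 100.3, 57.8, 3.2, 50, c(1.3, 1.1))
  st <- image_stack(img + 1)
  f <- fit_spots_3d(st, cbind(100, 58, 3))
  expect_true(f$success)
  expect_lt(abs(f$x_px - 100.3), 0.05)
  expect_lt(abs(f$y_px - 57.8), 0.05)
  expect_lt(abs(f$z_px - 3.2), 0.05)
  expect_equal(f$x_nm, f$x_px * 107.9)
  # flat background -> failure
  expect_false(fit_spots_3d(st, cbind(20, 20, 3))$success)
  # two spots 10 px apart at moderate noise resolve separately
  img2 <- array(0, c(100, 100, 7))
  img2 <- nucleome:::render_spots(img2, c(40, 50), c(40, 40), c(3, 3), 60,
                                  c(1.3, 1.1))
  set.seed(1)
  noisy <- array(rpois(length(img2), img2 + 3), dim(img2))
  f2 <- fit_spots_3d(image_stack(noisy), cbind(c(40, 50), c(40, 40), c(3, 3)))
  expect_true(all(f2$success))
  expect_lt(abs(f2$x_px[1] - 40), 0.5)
  expect_lt(abs(f2$x_px[2] - 50), 0.5)
  # out-of-bounds seed fails without affecting the others
  f3 <- fit_spots_3d(st, cbind(c(100, 500), c(58, 58), c(3, 3)))
  expect_identical(f3$success, c(TRUE, FALSE))
})

test_that("bead drift is recovered and subtracted", {
  cb <- validate_codebook(example_codebook(10))
  dr <- matrix(0, 16, 3)
  dr[5, ] <- c(3, -2, 0); dr[9, ] <- c(-1.5, 2.5, 0); dr[16, ] <- c(0.7, 0.4, 0)
  ph <- gen_merfish_stacks(cb, molecules_per_gene = 3, drift_truth = dr,
                           bead_count = 10, seed = 3, noise = "none")
  dt <- estimate_drift(ph$beads, reference_round = 1, dim = "2d")
  expect_identical(attr(dt, "reference_round"), 1L)
  expect_identical(dt$dx_nm[1], 0)
  for (r in c(5, 9, 16)) {
    expect_lt(abs(dt$dx_nm[r] / 107.9 - dr[r, 1]), 0.1)
    expect_lt(abs(dt$dy_nm[r] / 107.9 - dr[r, 2]), 0.1)
  }
  # applying the table inverts the planted drift
  pos <- tibble::tibble(round = 5L, x_nm = 1000 + 3 * 107.9,
                        y_nm = 500 - 2 * 107.9, z_nm = 0)
  corr <- apply_drift(pos, dt)
  expect_equal(corr$x_nm, 1000, tolerance = 15)
  expect_equal(corr$y_nm, 500, tolerance = 15)
})

test_that("drift estimation needs at least three matched beads", {
  cb <- validate_codebook(example_codebook(10))
  ph <- gen_merfish_stacks(cb, molecules_per_gene = 0, bead_count = 2,
                           seed = 4, noise = "none")
  expect_error(estimate_drift(ph$beads, dim = "2d"), "3 beads")
})

test_that("trace linking splits copies, dedupes readouts and records misses", {
  scores <- planted_block_scores(30)
  tr <- gen_traces(8, scores, seed = 5, dropout = 0.06)
  pos <- tr[!is.na(tr$x_nm), ]
  pos$x_nm <- pos$x_nm + ifelse(pos$copy_id == 1, 0, 9000) # separate copies
  pos$readout_id <- pos$region_id
  truth_copy <- pos$copy_id
  linked <- link_traces(
    pos[, c("cell_id", "readout_id", "x_nm", "y_nm", "z_nm", "quality")],
    n_readouts = 30)
  # two traces per cell, each with one row per readout
  counts <- table(linked$cell_id, linked$copy_id)
  expect_true(all(counts == 30))
  # assignment accuracy vs planted copies (copy ids may swap)
  det <- linked[!is.na(linked$x_nm), ]
  planted_side <- det$x_nm > 4500
  acc <- mean((det$copy_id == 2) == planted_side)
  expect_gte(max(acc, 1 - acc), 0.9)
  # duplicate detections of one locus: the brighter fit wins
  dup <- tibble::tibble(cell_id = 1, readout_id = c(1, 1, 2),
                        x_nm = c(0, 10, 50), y_nm = 0, z_nm = 0,
                        quality = c(1, 5, 1))
  got <- link_traces(dup, n_readouts = 2)
  expect_equal(nrow(got), 2)
  expect_equal(got$x_nm[got$region_id == 1], 10)
  # single copy -> one trace
  single <- tibble::tibble(cell_id = 1, readout_id = 1:5,
                           x_nm = rnorm(5, 0, 100), y_nm = rnorm(5, 0, 100),
                           z_nm = rnorm(5, 0, 100), quality = 1)
  expect_equal(max(link_traces(single, n_readouts = 5)$copy_id), 1)
})
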