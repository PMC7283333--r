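test_that("polarization index reproduces its analytic anchor cases", {
  # disjoint hulls -> 1
  far <- polarization_index(unit_tetrahedron(), unit_tetrahedron(c(100, 0, 0)))
  expect_equal(far$pi, 1)
  expect_equal(far$v_s, 0)
  # identical point sets -> 0
  same <- polarization_index(unit_cube(), unit_cube())
  expect_equal(same$pi, 0, tolerance = 1e-9)
  # nested -> 0 (one wraps around the other)
  nested <- polarization_index(unit_cube() * 10, unit_cube() * 0.2 + 4)
  expect_equal(nested$pi, 0, tolerance = 1e-9)
  # half-overlapping unit cubes -> exactly 0.5
  half <- polarization_index(unit_cube(), unit_cube(c(0.5, 0, 0)))
  expect_equal(half$v_a, 1, tolerance = 1e-9)
  expect_equal(half$v_s, 0.5, tolerance = 1e-9)
  expect_equal(half$pi, 0.5, tolerance = 1e-9)
  # degenerate group -> error
  expect_error(polarization_index(unit_tetrahedron()[1:3, ], unit_cube()),
               "degenerate|non-coplanar")
})

test_that("polarization index is invariant to rigid motion and scaling", {
  set.seed(12)
  a <- matrix(rnorm(30), ncol = 3)
  b <- matrix(rnorm(30), ncol = 3) + 0.8
  base <- polarization_index(a, b)$pi
  R <- rotation_3d()
  shift <- c(5, -3, 11)
  tfm <- function(m, s) sweep(m %*% t(R) * s, 2, shift, "+")
  for (s in c(1, 0.37, 250)) {
    expect_equal(polarization_index(tfm(a, s), tfm(b, s))$pi, base,
                 tolerance = 1e-6)
  }
  expect_true(base >= 0 && base <= 1)
})

test_that("label randomization preserves group sizes and calibrates the null", {
  scores <- planted_block_scores(30)
  expect_error(randomized_polarization(
    gen_traces(3, scores, seed = 1), rep("A", 30)), "both compartments")
  # spherically symmetric points: observed PI within the control distribution
  set.seed(40)
  labs <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  tr <- tibble::tibble(
    cell_id = rep(1:30, each = 40), copy_id = 1,
    region_id = rep(1:40, 30),
    x_nm = rnorm(1200, 0, 500), y_nm = rnorm(1200, 0, 500),
    z_nm = rnorm(1200, 0, 500), quality = 1)
  rp <- randomized_polarization(tr, labs, n_perm = 2, seed = 3)
  expect_gt(rp$p_value, 0.01)
  expect_equal(nrow(rp$observed), 30)
  # planted polarized phantom: observed exceeds control decisively
  trp <- gen_traces(100, scores, polarization_strength = 1, seed = 44)
  rpp <- randomized_polarization(trp, scores, seed = 5)
  expect_gt(median(rpp$observed$pi), median(rpp$control$pi))
  expect_lt(rpp$p_value, 0.01)
})

test_that("association uses strict sub-threshold distance to mask voxel centers", {
  mask <- array(FALSE, c(20, 20, 3))
  mask[11, 11, 2] <- TRUE # voxel center at (10, 10, 1) * voxel_size
  vm <- voxel_mask(mask, voxel_size = c(100, 100, 200), kind = "nuclear_edge")
  mk_trace <- function(x, y, z) tibble::tibble(
    cell_id = 1, copy_id = 1, region_id = 1,
    x_nm = x, y_nm = y, z_nm = z, quality = 1)
  at_voxel <- association_ratio(mk_trace(1000, 1000, 200), vm, 200)
  expect_equal(at_voxel$ratio, 1)
  exactly_200 <- association_ratio(mk_trace(1200, 1000, 200), vm, 200)
  expect_equal(exactly_200$ratio, 0) # strict <
  just_inside <- association_ratio(mk_trace(1199.9, 1000, 200), vm, 200)
  expect_equal(just_inside$ratio, 1)
  # monotone non-decreasing in the threshold
  r1 <- association_ratio(mk_trace(1150, 1000, 200), vm, 100)$ratio
  r2 <- association_ratio(mk_trace(1150, 1000, 200), vm, 200)$ratio
  expect_gte(r2, r1)
  # empty mask warns and returns zero ratios
  empty <- voxel_mask(array(FALSE, c(4, 4, 1)), c(100, 100, 200), "nucleolus")
  expect_warning(z <- association_ratio(mk_trace(0, 0, 0), empty), "empty")
  expect_equal(z$ratio, 0)
})

test_that("planted shells at 100 vs 500 nm give association ratios 1 and 0", {
  mask <- array(FALSE, c(30, 30, 3))
  mask[15, 15, 2] <- TRUE
  vm <- voxel_mask(mask, voxel_size = c(107.9, 107.9, 200), "nuclear_edge")
  center <- c(14 * 107.9, 14 * 107.9, 200)
  n <- 20
  mk <- function(offset) tibble::tibble(
    cell_id = seq_len(n), copy_id = 1, region_id = 1,
    x_nm = center[1] + offset, y_nm = center[2], z_nm = center[3],
    quality = 1)
  expect_equal(association_ratio(mk(100), vm, 200)$ratio, 1)
  expect_equal(association_ratio(mk(500), vm, 200)$ratio, 0)
})

test_that("compartment-B chromosome association uses the any-B rule", {
  mask <- array(FALSE, c(20, 20, 1))
  mask[11, 11, 1] <- TRUE
  vm <- voxel_mask(mask, voxel_size = c(100, 100, 200), "nucleolus")
  labels <- c(TRUE, FALSE, FALSE) # locus 1 = A, loci 2-3 = B
  tr <- tibble::tibble(
    cell_id = c(1, 1, 1, 2, 2, 2), copy_id = 1,
    region_id = rep(1:3, 2),
    x_nm = c(1000, 1000, 5000, 1000, 5000, 5000),
    y_nm = c(1000, 1000, 5000, 1000, 5000, 5000),
    z_nm = 0, quality = 1)
  got <- chromosome_b_association(tr, vm, labels, threshold_nm = 200)
  # cell 1: B locus 2 sits at the mask voxel -> associated
  expect_true(got$associated[got$cell_id == "1"])
  # cell 2: only the A locus is near the mask -> not associated
  expect_false(got$associated[got$cell_id == "2"])
})

test_that("chromosome-surface calls mark exactly the hull vertices", {
  # 4-point tetrahedron: every locus is on the surface
  tr4 <- tibble::tibble(cell_id = 1, copy_id = 1, region_id = 1:4,
                        x_nm = unit_tetrahedron()[, 1] * 1000,
                        y_nm = unit_tetrahedron()[, 2] * 1000,
                        z_nm = unit_tetrahedron()[, 3] * 1000, quality = 1)
  sr4 <- chromosome_surface_ratio(tr4)
  expect_true(all(sr4$ratio == 1))
  # one locus strictly inside a surrounding cloud is never on the surface
  set.seed(3)
  cloud <- rbind(matrix(rnorm(60, sd = 500), ncol = 3), c(0, 0, 0))
  tr5 <- tibble::tibble(cell_id = 1, copy_id = 1, region_id = 1:21,
                        x_nm = cloud[, 1], y_nm = cloud[, 2],
                        z_nm = cloud[, 3], quality = 1)
  sr5 <- chromosome_surface_ratio(tr5)
  expect_equal(sr5$ratio[21], 0)
})

test_that("surface ratios match an independent resampling estimate", {
  # loci i.i.d. in a ball: hull-vertex probability per position estimated by
  # an independent oracle that tests extremality point-by-point
  n_loci <- 25; n_copies <- 300
  set.seed(9)
  is_extreme <- function(pts, i) {
    # i is extreme iff it is not inside the hull of the others
    !nucleome:::cpp_in_hull(pts[-i, , drop = FALSE], pts[i, , drop = FALSE])
  }
  tr <- purrr::map_dfr(seq_len(n_copies), function(cc) {
    m <- matrix(rnorm(n_loci * 3), ncol = 3)
    m <- m / (rowSums(m^2)^(1 / 2)) * runif(n_loci)^(1 / 3) * 1000
    tibble::tibble(cell_id = cc, copy_id = 1, region_id = seq_len(n_loci),
                   x_nm = m[, 1], y_nm = m[, 2], z_nm = m[, 3], quality = 1)
  })
  sr <- chromosome_surface_ratio(tr)
  oracle <- vapply(seq_len(200), function(s) {
    m <- matrix(rnorm(n_loci * 3), ncol = 3)
    m <- m / (rowSums(m^2)^(1 / 2)) * runif(n_loci)^(1 / 3) * 1000
    mean(vapply(seq_len(n_loci), function(i) is_extreme(m, i), logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(sr$ratio) - mean(oracle)), 0.03)
})

test_that("score-ratio correlations report exact and undefined cases", {
  s <- seq(-0.5, 0.5, length.out = 20)
  out <- score_ratio_correlation(s, s)
  expect_equal(out$r[out$subset == "all"], 1, tolerance = 1e-12)
  expect_lt(out$p_value[out$subset == "all"], 1e-10)
  split <- score_ratio_correlation(s, s, split_by_sign = TRUE)
  expect_setequal(split$subset, c("all", "A", "B"))
  # n = 2 subset undefined
  tiny <- score_ratio_correlation(c(-1, -2, -3, 0.1, 0.2),
                                  c(1, 2, 3, 4, 5), split_by_sign = TRUE)
  expect_true(is.na(tiny$r[tiny$subset == "A"]))
  # planted linear relation with noise: R near the planted value
  set.seed(5)
  r_obs <- replicate(60, {
    x <- rnorm(40); y <- 0.8 * x + rnorm(40, 0, 0.6)
    score_ratio_correlation(x, y)$r
  })
  planted_r <- 0.8 / sqrt(0.8^2 + 0.6^2)
  expect_lt(abs(mean(r_obs) - planted_r), 0.05)
})

test_that("compartment-axis projection separates the groups by construction", {
  pts <- rbind(matrix(0, 5, 3), cbind(10, matrix(0, 5, 2)))
  labels <- rep(c(TRUE, FALSE), each = 5)
  proj <- compartment_axis_projection(pts, labels)
  expect_equal(mean(proj$displacement[proj$compartment == "A"]), -10)
  expect_equal(mean(proj$displacement[proj$compartment == "B"]), 0)
  # opposite corners of a square share a centroid: axis undefined
  square <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1), 0)
  expect_error(compartment_axis_projection(square, c(TRUE, TRUE, FALSE, FALSE)),
               "coincident")
  # polarized phantom: distributions separate
  scores <- planted_block_scores(30)
  tr <- gen_traces(100, scores, polarization_strength = 1, seed = 50,
                   dropout = 0)
  disp_a <- c(); disp_b <- c()
  for (key in unique(paste(tr$cell_id, tr$copy_id))) {
    sub <- tr[paste(tr$cell_id, tr$copy_id) == key, ]
    p <- compartment_axis_projection(
      as.matrix(sub[, c("x_nm", "y_nm", "z_nm")]), scores)
    disp_a <- c(disp_a, p$displacement[p$compartment == "A"])
    disp_b <- c(disp_b, p$displacement[p$compartment == "B"])
  }
  expect_lt(suppressWarnings(wilcox.test(disp_a, disp_b))$p.value, 0.01)
})
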