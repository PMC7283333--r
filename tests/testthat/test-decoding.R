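codebook10 <- validate_codebook(example_codebook(10))

test_that("codebook validation enforces weight and pairwise distance", {
  ok <- validate_codebook(tibble::tibble(
    gene_id = c("a", "b"),
    word = c("1111000000000000", "0000111100000000")))
  expect_s3_class(ok, "codebook")
  expect_error(validate_codebook(tibble::tibble(
    gene_id = "a", word = "1110000000000000")), "weight.*a")
  expect_error(validate_codebook(tibble::tibble(
    gene_id = c("a", "b"),
    word = c("1111000000000000", "1101100000000000"))), "a.*b|b.*a")
  # brute-force oracle: the accepted codebook really is at pairwise HD >= 4
  hd <- hamming_oracle(codebook10$word)
  expect_true(all(hd[upper.tri(hd)] >= 4))
  # malformed word
  expect_error(validate_codebook(tibble::tibble(gene_id = "x", word = "01")),
               "malformed")
})

test_that("round binarization marks isolated maxima and dilates them", {
  img <- array(0, c(64, 64, 1))
  img[30, 40, 1] <- 100
  b <- binarize_round(image_stack(img + 1), intensity_threshold = 10)
  expect_equal(sum(b), 9) # one 3x3 block
  expect_true(all(b[29:31, 39:41, 1]))
  # below threshold -> empty
  expect_false(any(binarize_round(image_stack(img + 1), 200)))
  # smooth ramp background with 10 planted maxima survives opening
  ramp <- outer(seq(0, 30, length.out = 96), seq(0, 30, length.out = 96), "+")
  set.seed(2)
  px <- cbind(sample(10:86, 10), sample(10:86, 10))
  ramp2 <- ramp
  ramp2[px] <- ramp2[px] + 60
  b2 <- binarize_round(image_stack(array(ramp2, c(96, 96, 1))), 30)
  comp <- EBImage::bwlabel(b2[, , 1] * 1)
  # morphological background subtraction leaves border artifacts at the ramp
  # maximum; away from the border exactly the 10 planted maxima survive
  interior <- unique(comp[6:91, 6:91])
  expect_equal(length(setdiff(interior, 0)), 10)
  expect_true(all(comp[px] > 0))
})

test_that("pixel decoding matches codewords exactly, with optional HD-1 rescue", {
  d <- c(32, 32, 1)
  word3 <- nucleome:::codeword_bits(codebook10$word[3])[1, ]
  bits <- lapply(seq_len(16), function(r) {
    m <- array(FALSE, d)
    if (word3[r] == 1) m[10, 10, 1] <- TRUE
    m
  })
  mols <- decode_pixels(bits, codebook10)
  expect_equal(nrow(mols), 1)
  expect_equal(mols$gene_id, "gene03")
  expect_equal(mols$pixel_count, 1L)
  # flip one on-bit off: exact match fails, HD-1 correction recovers it
  r_on <- which(word3 == 1)[1]
  bits_err <- bits
  bits_err[[r_on]][10, 10, 1] <- FALSE
  expect_equal(nrow(decode_pixels(bits_err, codebook10)), 0)
  rescued <- decode_pixels(bits_err, codebook10, allow_one_bit_correction = TRUE)
  expect_equal(rescued$gene_id, "gene03")
  # shape mismatch across rounds -> error
  bad <- bits; bad[[2]] <- array(FALSE, c(16, 16, 1))
  expect_error(decode_pixels(bad, codebook10), "mismatch")
})

test_that("decoding is equivariant under gene relabeling", {
  ph <- gen_merfish_stacks(codebook10, molecules_per_gene = 10, seed = 5,
                           noise = "none")
  bits <- lapply(ph$rounds, function(s) binarize_round(s, 10))
  mols <- decode_pixels(bits, codebook10)
  perm <- rev(seq_len(nrow(codebook10)))
  relabeled <- codebook10
  relabeled$gene_id <- codebook10$gene_id[perm]
  relabeled$word <- codebook10$word[perm]
  mols2 <- decode_pixels(bits, relabeled)
  a <- mols[order(mols$x_px, mols$y_px, mols$z), ]
  b <- mols2[order(mols2$x_px, mols2$y_px, mols2$z), ]
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$x_px, b$x_px)
})

test_that("phantom molecules are recovered at high rate with correct identity", {
  ph <- gen_merfish_stacks(codebook10, molecules_per_gene = 50,
                           fov_shape = c(256L, 256L, 3L), seed = 7,
                           noise = "none")
  bits <- lapply(ph$rounds, function(s) binarize_round(s, 10))
  mols <- decode_pixels(bits, codebook10)
  tm <- ph$truth$molecules
  recovered <- vapply(seq_len(nrow(tm)), function(i) {
    same <- mols[mols$gene_id == tm$gene_id[i], ]
    if (nrow(same) == 0) return(FALSE)
    any((same$x_px - tm$x_px[i])^2 + (same$y_px - tm$y_px[i])^2 <= 4 &
          abs(same$z - tm$z_px[i]) <= 1.2)
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  # exact matching only: every decoded word is a codeword
  expect_true(all(mols$gene_id %in% codebook10$gene_id))
})

test_that("threshold calibration tracks reference abundances", {
  set.seed(21)
  ref <- setNames(exp(runif(10, 1, 5)), codebook10$gene_id)
  counts_per_gene <- pmax(2L, as.integer(round(ref / max(ref) * 40)))
  mols <- purrr::map_dfr(seq_len(10), function(g) {
    tibble::tibble(gene_id = codebook10$gene_id[g],
                   x_px = runif(counts_per_gene[g], 8, 180),
                   y_px = runif(counts_per_gene[g], 8, 180),
                   z_px = 1)
  })
  ph <- gen_merfish_stacks(codebook10, molecules = mols,
                           fov_shape = c(192L, 192L, 3L),
                           psf_sigma = c(1.1, 0.3), seed = 9, noise = "none")
  cal <- calibrate_thresholds(ph$rounds, codebook10, ref, sweeps = 1L)
  expect_gt(cal$correlation, 0.9)
  planted <- table(factor(mols$gene_id, levels = codebook10$gene_id))
  err <- abs(cal$counts - as.numeric(planted)) / as.numeric(planted)
  expect_lt(median(err), 0.1)
  # scale invariance of the correlation objective
  cal2 <- calibrate_thresholds(ph$rounds, codebook10, ref * 2, sweeps = 1L)
  expect_identical(cal$thresholds, cal2$thresholds)
  # degenerate references
  expect_error(calibrate_thresholds(ph$rounds, codebook10,
                                    ref[1]), "at least 10")
  expect_error(calibrate_thresholds(ph$rounds, codebook10,
                                    setNames(rep(2, 10), codebook10$gene_id)),
               "all abundances equal")
})

test_that("per-cell counting erodes borders and applies QC flags", {
  # two touching square cells
  lab <- matrix(0L, 120, 240)
  lab[11:110, 11:120] <- 1L
  lab[11:110, 121:230] <- 2L
  clm <- structure(list(labels = lab,
                        excluded = tibble::tibble(label = integer(),
                                                  area = integer(),
                                                  reason = character()),
                        retained = c(1L, 2L)), class = "cell_label_map")
  mols <- tibble::tibble(
    gene_id = c(rep("g1", 12), rep("g2", 3), "g1"),
    x_px = c(rep(60, 12), rep(60, 3), 59),
    y_px = c(rep(60, 12), rep(180, 3), 120.5), # last sits on the boundary
    z = 0, pixel_count = 1)
  em <- count_per_cell(mols, clm, area_limits = c(2500, 20000))
  expect_identical(unname(em$counts["1", "g1"]), 12L)
  expect_identical(unname(em$counts["2", "g2"]), 3L)
  expect_equal(em$n_unassigned, 1) # boundary molecule dropped by erosion
  # QC: cell 2 has fewer than 10 molecules
  expect_false(em$qc$retained[em$qc$cell == 2])
  expect_true(em$qc$flag_min_count[em$qc$cell == 2])
  expect_true(em$qc$retained[em$qc$cell == 1])
  # conservation: assigned molecules never exceed decoded molecules
  expect_lte(sum(em$counts), nrow(mols))
  td <- tidy(em)
  expect_equal(sum(td$count), sum(em$counts))
})
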