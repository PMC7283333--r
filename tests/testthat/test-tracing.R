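test_that("mean distance matrix uses pairwise deletion", {
  tr <- tibble::tibble(
    cell_id = c(1, 1, 2, 2), copy_id = 1,
    region_id = c(1, 2, 1, 2),
    x_nm = c(0, 100, 0, 300), y_nm = 0, z_nm = 0, quality = 1)
  dm <- mean_distance_matrix(tr, min_pairs = 1)
  expect_equal(dm$mean[1, 2], 200)
  expect_equal(dm$count[1, 2], 2L)
  # drop the locus in one trace: count falls to 1
  tr2 <- tr[-4, ]
  dm2 <- mean_distance_matrix(tr2, min_pairs = 1, n_regions = 2)
  expect_equal(dm2$count[1, 2], 1L)
  expect_equal(dm2$mean[1, 2], 100)
  # min_pairs masks sparse entries
  dm3 <- mean_distance_matrix(tr2, min_pairs = 2, n_regions = 2)
  expect_true(is.na(dm3$mean[1, 2]))
  expect_error(mean_distance_matrix(tr[0, ]), "no traces")
  # symmetry / zero diagonal
  expect_identical(dm$mean, t(dm$mean))
  expect_true(all(diag(dm$mean) == 0))
})

test_that("contact probability uses a strict threshold", {
  tr <- tibble::tibble(
    cell_id = rep(1:4, each = 2), copy_id = 1,
    region_id = rep(1:2, 4),
    x_nm = rep(c(0, 100), 4), y_nm = 0, z_nm = 0, quality = 1)
  cp <- contact_probability(tr, threshold_nm = 150)
  expect_equal(cp$probability[1, 2], 1)
  # distances exactly at the threshold are NOT contacts
  tr$x_nm <- rep(c(0, 150), 4)
  cp2 <- contact_probability(tr, threshold_nm = 150)
  expect_equal(cp2$probability[1, 2], 0)
})

test_that("planted contact frequencies are recovered within binomial error", {
  set.seed(8)
  n <- 500
  p_target <- 0.3
  # pair at 100 nm with probability p, else far apart
  close <- runif(n) < p_target
  tr <- tibble::tibble(
    cell_id = rep(seq_len(n), each = 2), copy_id = 1,
    region_id = rep(1:2, n),
    x_nm = as.vector(rbind(0, ifelse(close, 100, 600))),
    y_nm = 0, z_nm = 0, quality = 1)
  cp <- contact_probability(tr, threshold_nm = 150)
  expect_lt(abs(cp$probability[1, 2] - p_target), 0.05)
})

test_that("Hi-C contact frequency normalizes by genomic length products", {
  regions <- tibble::tibble(chrom = "c", start = c(0, 2e6),
                            end = c(1e6, 4e6), region_id = c("r1", "r2"))
  counts <- matrix(c(0, 100, 100, 0), 2, 2)
  f <- hic_contact_frequency(counts, regions)
  expect_equal(f[1, 2], 100 / (1e6 * 2e6))
  expect_identical(f, t(f))
  # doubling both lengths divides the frequency by 4
  regions2 <- regions; regions2$end <- regions2$start +
    2 * (regions$end - regions$start)
  expect_equal(hic_contact_frequency(counts, regions2)[1, 2], f[1, 2] / 4)
  # zero counts give zero frequency; zero length errors
  expect_true(all(hic_contact_frequency(matrix(0, 2, 2), regions) == 0))
  regions$end[1] <- regions$start[1]
  expect_error(hic_contact_frequency(counts, regions), "zero-length")
})

test_that("power-law fits are exact on noiseless data", {
  x <- seq(1, 10)
  fit <- fit_distance_powerlaw(x, 2 * x^3)
  expect_equal(fit$exponent, 3, tolerance = 1e-10)
  expect_equal(fit$amplitude, 2, tolerance = 1e-10)
  expect_equal(fit$correlation, 1, tolerance = 1e-10)
  # constant y -> zero exponent, zero correlation
  fit0 <- fit_distance_powerlaw(x, rep(5, 10))
  expect_equal(fit0$exponent, 0, tolerance = 1e-10)
  expect_equal(fit0$correlation, 0)
  # non-positive pairs are excluded with a warning, few points error
  expect_warning(fit_distance_powerlaw(c(1, 2, 3, -1), c(1, 2, 3, 4)),
                 "excluded")
  expect_error(suppressWarnings(fit_distance_powerlaw(c(1, -2), c(1, 1))),
               "at least 3")
})

test_that("a planted distance-count power law is recovered from synthetic Hi-C", {
  scores <- planted_block_scores(40)
  tr <- gen_traces(150, scores, seed = 14, dropout = 0)
  counts <- gen_hic_counts(tr, depth = 5e5, seed = 3, model = "powerlaw",
                           exponent = 5)
  dm <- mean_distance_matrix(tr, min_pairs = 5)
  regions <- synthetic_regions(40)
  freq <- hic_contact_frequency(counts, regions)
  up <- upper.tri(freq)
  ok <- freq[up] > 0
  fit <- fit_distance_powerlaw(dm$mean[up][ok], 1 / freq[up][ok])
  expect_lt(abs(fit$exponent - 5), 0.5)
  expect_gt(fit$correlation, 0.8)
})

test_that("compartment scores recover a planted partition and orient by gene density", {
  scores <- planted_block_scores(50)
  tr <- gen_traces(150, scores, polarization_strength = 1, seed = 16)
  dm <- mean_distance_matrix(tr, min_pairs = 5)
  regions <- synthetic_regions(50)
  # orientation: gene density higher in planted-A regions
  regions$gene_density <- ifelse(scores > 0, 12, 4) + seq(0, 1, length.out = 50)
  cr <- compartment_scores(dm, regions)
  agreement <- mean(sign(cr$scores$score) == sign(scores))
  expect_gte(sum(sign(cr$scores$score) == sign(scores)), 48)
  expect_true(cr$oriented)
  expect_gte(cor(cr$scores$score, regions$gene_density), 0)
  # unit-norm scores
  expect_equal(sum(cr$scores$score^2), 1, tolerance = 1e-9)
  # invariance to a global rescaling of all distances
  dm2 <- dm; dm2$mean <- dm2$mean * 3.7
  cr2 <- compartment_scores(dm2, regions)
  expect_equal(cr2$scores$score, cr$scores$score, tolerance = 1e-6)
  # glance carries the power-law fit
  g <- glance(cr)
  expect_true(g$powerlaw_exponent > 0)
})

test_that("degenerate normalized matrices are rejected", {
  # distances exactly on a power law -> zero-deviation matrix
  n <- 20
  sep <- abs(outer(1:n, 1:n, "-"))
  D <- 300 * sep^0.4
  dm <- structure(list(mean = D, count = matrix(100L, n, n), n_regions = n),
                  class = "distance_matrix")
  regions <- synthetic_regions(n)
  expect_error(compartment_scores(dm, regions), "degenerate|constant")
  # missing entries are reported
  D2 <- D + matrix(runif(n * n), n, n); D2 <- (D2 + t(D2)) / 2; diag(D2) <- 0
  D2[2, 5] <- D2[5, 2] <- NA
  dm2 <- structure(list(mean = D2, count = matrix(100L, n, n), n_regions = n),
                   class = "distance_matrix")
  expect_error(compartment_scores(dm2, regions), "missing")
})

test_that("PCA orientation is deterministic and row/column choice immaterial", {
  scores <- planted_block_scores(30)
  tr <- gen_traces(80, scores, polarization_strength = 0.8, seed = 18)
  dm <- mean_distance_matrix(tr, min_pairs = 5)
  regions <- synthetic_regions(30)
  regions$gene_density <- ifelse(scores > 0, 10, 2)
  a <- compartment_scores(dm, regions)
  b <- compartment_scores(dm, regions)
  expect_identical(a$scores$score, b$scores$score)
  # the correlation matrix is symmetric, so transposing the normalized matrix
  # (rows as observations vs columns) cannot change it
  expect_equal(a$correlation, t(a$correlation), tolerance = 1e-12)
})

test_that("expression fold changes pair with compartment-score changes", {
  expression <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    cell_type = rep(c("hep", "ery"), each = 3),
    mean_count = c(8, 3, 6, 2, 1, 6))
  scores <- tibble::tibble(
    region_id = rep(c("r1", "r2", "r3"), 2),
    cell_type = rep(c("hep", "ery"), each = 3),
    score = c(0.2, 0.1, 0, -0.1, 0.1, 0))
  gene_map <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                             region_id = c("r1", "r2", "r3"))
  res <- expression_fold_vs_score_change(expression, scores, gene_map,
                                         fold_threshold = 3)
  # g1 hep vs ery: fold 4 (>3), delta +0.3 -> concordant
  expect_equal(res$concordant, 1)
  # g2 fold exactly 3 -> excluded (strictly greater than threshold)
  sig <- res$pairs[!is.na(res$pairs$fold) & res$pairs$fold > 3, ]
  expect_false("g2" %in% sig$gene_id)
  # g3 fold 1 both ways -> not counted
  expect_equal(res$concordant + res$discordant, 1)
})

test_that("planted expression-compartment coupling gives concordance above chance", {
  set.seed(30)
  n_genes <- 100
  delta <- rnorm(n_genes, 0, 0.15)
  up <- delta > 0
  fold <- ifelse(up, runif(n_genes, 3.5, 8), runif(n_genes, 0.3, 2))
  base <- runif(n_genes, 2, 10)
  expression <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:n_genes), 2),
    cell_type = rep(c("t1", "t0"), each = n_genes),
    mean_count = c(base * fold, base))
  scores <- tibble::tibble(
    region_id = rep(sprintf("r%03d", 1:n_genes), 2),
    cell_type = rep(c("t1", "t0"), each = n_genes),
    score = c(delta, rep(0, n_genes)))
  gene_map <- tibble::tibble(gene_id = sprintf("g%03d", 1:n_genes),
                             region_id = sprintf("r%03d", 1:n_genes))
  res <- expression_fold_vs_score_change(expression, scores, gene_map)
  expect_gt(res$concordant / (res$concordant + res$discordant), 0.5)
  expect_lt(res$p_value, 0.05)
})
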