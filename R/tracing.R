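#' Mean spatial-distance matrix of traced loci
#'
#' Entry (i, j) is the mean Euclidean distance between loci i and j over all
#' chromosome copies in which both loci were detected (pairwise deletion);
#' the number of contributing copies is recorded per entry, and entries with
#' fewer than `min_pairs` contributing copies are set missing.
#'
#' @param traces trace tibble (`cell_id`, `copy_id`, `region_id`, `x_nm`,
#'   `y_nm`, `z_nm`; NA coordinates mark missing loci).
#' @param min_pairs minimum pair count for an entry to be reported.
#' @param n_regions number of loci; defaults to the maximum region id.
#' @return A `distance_matrix`: list with `mean` (n x n nm), `count` (n x n)
#'   and `n_regions`.
#' @export
mean_distance_matrix <- function(traces, min_pairs = 2L, n_regions = NULL) {
  copies <- split_copies(traces, n_regions)
  if (length(copies) == 0) stop("no traces supplied")
  n <- nrow(copies[[1]])
  sums <- matrix(0, n, n)
  cnts <- matrix(0L, n, n)
  for (m in copies) {
    ok <- complete.cases(m)
    if (sum(ok) < 2) next
    d <- as.matrix(dist(m[ok, , drop = FALSE]))
    idx <- which(ok)
    sums[idx, idx] <- sums[idx, idx] + d
    cnts[idx, idx] <- cnts[idx, idx] + 1L
  }
  mean_d <- sums / cnts
  mean_d[cnts < min_pairs] <- NA_real_
  diag(mean_d)[diag(cnts) > 0] <- 0
  structure(list(mean = mean_d, count = cnts, n_regions = n),
            class = "distance_matrix")
}

# traces tibble -> list of n_regions x 3 coordinate matrices, one per copy
split_copies <- function(traces, n_regions = NULL) {
  req <- c("cell_id", "copy_id", "region_id", "x_nm", "y_nm", "z_nm")
  stopifnot(all(req %in% names(traces)))
  if (nrow(traces) == 0) return(list())
  n <- n_regions %||% max(traces$region_id)
  key <- paste(traces$cell_id, traces$copy_id, sep = "\r")
  lapply(split(seq_len(nrow(traces)), key), function(rows) {
    m <- matrix(NA_real_, n, 3)
    sub <- traces[rows, ]
    m[sub$region_id, ] <- cbind(sub$x_nm, sub$y_nm, sub$z_nm)
    m
  })
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d regions, %d informative entries, median %.0f nm\n",
              x$n_regions, sum(!is.na(x$mean[upper.tri(x$mean)])),
              median(x$mean[upper.tri(x$mean)], na.rm = TRUE)))
  invisible(x)
}

#' Tidy a distance matrix into long (region_i, region_j) rows
#' @param x a `distance_matrix`.
#' @param ... unused.
#' @export
tidy.distance_matrix <- function(x, ...) {
  n <- x$n_regions
  idx <- which(upper.tri(x$mean), arr.ind = TRUE)
  tibble::tibble(region_i = idx[, 1], region_j = idx[, 2],
                 mean_nm = x$mean[idx], n_pairs = x$count[idx])
}

#' Spatial contact probabilities between traced loci
#'
#' Two loci of one chromosome copy are in contact when their spatial distance
#' is strictly below `threshold_nm` (a distance of exactly the threshold is
#' not a contact). The probability is the fraction of informative copies
#' (both loci detected) in contact. With `anchor_region` set, returns the
#' per-region contact probability with that anchor; otherwise the full
#' pairwise matrix.
#'
#' @param traces trace tibble (see [mean_distance_matrix()]).
#' @param threshold_nm contact threshold, default 150 nm.
#' @param anchor_region optional region id.
#' @param n_regions number of loci.
#' @return With an anchor: tibble (region_id, probability, n). Without:
#'   list(probability = matrix, n = matrix); entries with zero informative
#'   copies are NA.
#' @export
contact_probability <- function(traces, threshold_nm = 150,
                                anchor_region = NULL, n_regions = NULL) {
  stopifnot(threshold_nm > 0)
  copies <- split_copies(traces, n_regions)
  if (length(copies) == 0) stop("no traces supplied")
  n <- nrow(copies[[1]])
  hits <- matrix(0L, n, n)
  cnts <- matrix(0L, n, n)
  for (m in copies) {
    ok <- complete.cases(m)
    if (sum(ok) < 2) next
    d <- as.matrix(dist(m[ok, , drop = FALSE]))
    idx <- which(ok)
    hits[idx, idx] <- hits[idx, idx] + (d < threshold_nm)
    cnts[idx, idx] <- cnts[idx, idx] + 1L
  }
  p <- hits / cnts
  p[cnts == 0] <- NA_real_
  diag(p)[diag(cnts) > 0] <- 1 # self-distance 0 < threshold
  if (!is.null(anchor_region)) {
    return(tibble::tibble(region_id = seq_len(n), probability = p[, anchor_region],
                          n = cnts[, anchor_region]))
  }
  list(probability = p, n = cnts)
}

#' Per-region difference in anchored contact probability between two groups
#'
#' Computes, for every traced region, the contact probability with the anchor
#' in group A minus that in group B (e.g. one cell type versus the rest), the
#' quantity used to read out differential promoter contacts.
#'
#' @param traces_a,traces_b trace tibbles for the two groups.
#' @param anchor_region anchor region id.
#' @param threshold_nm contact threshold.
#' @param n_regions number of loci.
#' @return Tibble: region_id, p_a, p_b, difference, n_a, n_b.
#' @export
contact_probability_difference <- function(traces_a, traces_b, anchor_region,
                                           threshold_nm = 150,
                                           n_regions = NULL) {
  a <- contact_probability(traces_a, threshold_nm, anchor_region, n_regions)
  b <- contact_probability(traces_b, threshold_nm, anchor_region, n_regions)
  tibble::tibble(region_id = a$region_id, p_a = a$probability,
                 p_b = b$probability, difference = a$probability - b$probability,
                 n_a = a$n, n_b = b$n)
}

#' Length-normalized Hi-C contact frequency between regions
#'
#' Divides the total contact count between two regions by the product of
#' their genomic lengths, removing the trivial dependence of raw counts on
#' region size.
#'
#' @param count_matrix square non-negative count matrix (same order as
#'   `regions`).
#' @param regions region tibble from [read_regions()] (needs `start`, `end`).
#' @return Symmetric matrix of counts per (length_i * length_j).
#' @export
hic_contact_frequency <- function(count_matrix, regions) {
  count_matrix <- as.matrix(count_matrix)
  n <- nrow(count_matrix)
  stopifnot(ncol(count_matrix) == n, nrow(regions) == n)
  if (any(count_matrix < 0)) stop("counts must be non-negative")
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("zero-length region(s): ",
                          paste(regions$region_id[len <= 0], collapse = ", "))
  count_matrix / outer(len, len)
}

#' Fit a power law y = A * x^k on log-log scale
#'
#' Ordinary least squares of log(y) on log(x). Non-positive pairs are
#' excluded with a warning; at least 3 usable pairs are required. Used both
#' to normalize spatial distance against genomic distance and to check the
#' scaling of inverse contact frequency against spatial distance.
#'
#' @param x,y positive numeric vectors.
#' @return List: `amplitude` (A), `exponent` (k), `correlation` (Pearson
#'   correlation of log x and log y), `n`.
#' @export
fit_distance_powerlaw <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(!ok))
    warning(sprintf("%d non-positive or non-finite pairs excluded from power-law fit",
                    sum(!ok)))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 positive (x, y) pairs")
  fit <- lm(log(y) ~ log(x))
  list(amplitude = exp(unname(coef(fit)[1])),
       exponent = unname(coef(fit)[2]),
       correlation = if (sd(log(x)) == 0 || sd(log(y)) == 0) 0
                     else cor(log(x), log(y)),
       n = length(x))
}

#' A/B compartment scores from a mean spatial-distance matrix
#'
#' The imaging analogue of the Hi-C compartment call: (1) fit a power law of
#' mean spatial distance against genomic distance (region midpoints,
#' diagonal excluded) to get the expected distance at each genomic
#' separation; (2) normalize the observed matrix by the expectation;
#' (3) compute the Pearson correlation matrix between rows of the normalized
#' matrix; (4) take the first principal component of that correlation matrix
#' (columns as variables, mean-centered); its unit-norm coefficients are the
#' compartment scores; (5) orient the sign so that scores correlate
#' positively with gene density, making positive scores compartment A and
#' negative scores compartment B.
#'
#' @param dm a `distance_matrix` from [mean_distance_matrix()], with no
#'   missing off-diagonal entries (after the `min_pairs` filter).
#' @param regions region tibble with `start`, `end` and optionally
#'   `gene_density` (genes/Mb) for sign orientation.
#' @return A `compartment_result`: list with `powerlaw`, `normalized`,
#'   `correlation`, `scores` tibble (region_id, score, compartment),
#'   `oriented` flag.
#' @export
compartment_scores <- function(dm, regions) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- dm$n_regions
  stopifnot(nrow(regions) == n)
  D <- dm$mean
  off <- upper.tri(D)
  if (anyNA(D[off])) {
    idx <- which(is.na(D) & off, arr.ind = TRUE)
    stop("missing distance entries after min_pairs filtering for pairs: ",
         paste(sprintf("(%d,%d)", idx[, 1], idx[, 2])[seq_len(min(5, nrow(idx)))],
               collapse = ", "))
  }
  mid <- (regions$start + regions$end) / 2
  gdist <- abs(outer(mid, mid, "-"))
  pl <- fit_distance_powerlaw(gdist[off], D[off])
  expected <- pl$amplitude * gdist^pl$exponent
  N <- D / expected
  diag(N) <- NA
  # row-row Pearson correlations of the normalized matrix (diagonal dropped
  # pairwise); symmetric, so rows vs columns is immaterial
  C <- suppressWarnings(cor(N, use = "pairwise.complete.obs"))
  if (anyNA(C) || any(apply(N, 1, sd, na.rm = TRUE) < 1e-12))
    stop("degenerate correlations: normalized matrix has constant rows ",
         "(distances follow the power law exactly)")
  pc <- prcomp(C, center = TRUE, scale. = FALSE)
  scores <- pc$rotation[, 1]
  oriented <- FALSE
  gd <- regions[["gene_density"]]
  if (!is.null(gd) && !anyNA(gd)) {
    if (cor(scores, gd) < 0) scores <- -scores
    oriented <- TRUE
  }
  structure(list(
    powerlaw = pl,
    normalized = N,
    correlation = C,
    scores = tibble::tibble(
      region_id = regions$region_id %||% seq_len(n),
      score = unname(scores),
      compartment = ifelse(scores > 0, "A", "B")),
    oriented = oriented), class = "compartment_result")
}

#' @export
print.compartment_result <- function(x, ...) {
  cat(sprintf("<compartment_result> %d regions (%d A / %d B), distance ~ genomic^%.2f%s\n",
              nrow(x$scores), sum(x$scores$compartment == "A"),
              sum(x$scores$compartment == "B"), x$powerlaw$exponent,
              if (x$oriented) "" else " [sign not oriented: no gene density]"))
  invisible(x)
}

#' Tidy compartment scores
#' @param x a `compartment_result`.
#' @param ... unused.
#' @export
tidy.compartment_result <- function(x, ...) x$scores

#' One-row summary of a compartment analysis
#' @param x a `compartment_result`.
#' @param ... unused.
#' @export
glance.compartment_result <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$scores),
                 n_a = sum(x$scores$compartment == "A"),
                 n_b = sum(x$scores$compartment == "B"),
                 powerlaw_exponent = x$powerlaw$exponent,
                 powerlaw_amplitude = x$powerlaw$amplitude,
                 powerlaw_correlation = x$powerlaw$correlation,
                 oriented = x$oriented)
}

#' Expression fold changes versus compartment-score changes
#'
#' For each gene and ordered pair of cell types, pairs the fold change of
#' mean expression with the change in compartment score of the gene's host
#' region, then tallies, among changes with fold strictly above
#' `fold_threshold`, how many come with a score increase versus a decrease
#' (binomial test against 0.5).
#'
#' @param expression tibble: `gene_id`, `cell_type`, `mean_count`.
#' @param scores tibble: `region_id`, `cell_type`, `score`.
#' @param gene_map tibble: `gene_id`, `region_id`.
#' @param fold_threshold strict fold-change cutoff (default 3).
#' @return List: `pairs` (gene, cell-type pair, fold, delta_score),
#'   `concordant`, `discordant`, `p_value`.
#' @export
expression_fold_vs_score_change <- function(expression, scores, gene_map,
                                            fold_threshold = 3) {
  types <- unique(expression$cell_type)
  combos <- expand.grid(type_up = types, type_ref = types,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$type_up != combos$type_ref, ]
  rows <- purrr::pmap(combos, function(type_up, type_ref) {
    e1 <- expression[expression$cell_type == type_up, ]
    e0 <- expression[expression$cell_type == type_ref, ]
    s1 <- scores[scores$cell_type == type_up, ]
    s0 <- scores[scores$cell_type == type_ref, ]
    df <- dplyr::inner_join(e1[, c("gene_id", "mean_count")],
                            e0[, c("gene_id", "mean_count")],
                            by = "gene_id", suffix = c("_up", "_ref"))
    df <- dplyr::inner_join(df, gene_map, by = "gene_id")
    df <- dplyr::inner_join(df, s1[, c("region_id", "score")], by = "region_id")
    df <- dplyr::inner_join(df, s0[, c("region_id", "score")],
                            by = "region_id", suffix = c("_up", "_ref"))
    df$fold <- ifelse(df$mean_count_ref > 0,
                      df$mean_count_up / df$mean_count_ref, NA_real_)
    tibble::tibble(gene_id = df$gene_id, type_up = type_up,
                   type_ref = type_ref, fold = df$fold,
                   delta_score = df$score_up - df$score_ref)
  })
  pairs <- dplyr::bind_rows(rows)
  sig <- pairs[!is.na(pairs$fold) & pairs$fold > fold_threshold &
                 pairs$delta_score != 0, ]
  k <- sum(sig$delta_score > 0)
  m <- nrow(sig)
  p <- if (m > 0) binom.test(k, m, 0.5)$p.value else NA_real_
  list(pairs = pairs, concordant = k, discordant = m - k, p_value = p)
}
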