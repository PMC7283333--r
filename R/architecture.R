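#' Polarization index of two point groups
#'
#' Builds the 3D convex hulls of the A-group and B-group loci of one
#' chromosome copy and computes
#' `PI = sqrt((1 - V_S/V_A) * (1 - V_S/V_B))`,
#' the geometric mean of the non-shared volume fractions, where `V_S` is the
#' volume of the hull intersection. PI = 1 for disjoint hulls (fully
#' polarized, side-by-side compartments); PI = 0 when the hulls coincide or
#' one wraps around (contains) the other.
#'
#' @param points_a,points_b coordinate matrices (n x 3, nm) or data frames
#'   with x/y/z columns; at least 4 non-coplanar points each.
#' @param engine `"exact"` hull-intersection volume (default) with seeded
#'   Monte Carlo fallback, or `"mc"` to force the sampling estimator.
#' @return One-row tibble (class `polarization_result`): `v_a`, `v_b`, `v_s`,
#'   `pi`, `n_a`, `n_b`.
#' @export
polarization_index <- function(points_a, points_b,
                               engine = c("exact", "mc")) {
  engine <- match.arg(engine)
  pa <- as_point_matrix(points_a)
  pb <- as_point_matrix(points_b)
  ha <- cpp_convhull(pa)
  hb <- cpp_convhull(pb)
  if (!ha$ok || !hb$ok)
    stop("degenerate hull: need at least 4 non-coplanar points per group")
  vs <- hull_intersection_volume(pa, pb, method = engine)
  vs <- min(vs, ha$volume, hb$volume) # guard tiny numerical overshoot
  pi_val <- sqrt(max(1 - vs / ha$volume, 0) * max(1 - vs / hb$volume, 0))
  out <- tibble::tibble(v_a = ha$volume, v_b = hb$volume, v_s = vs,
                        pi = pi_val, n_a = nrow(pa), n_b = nrow(pb))
  class(out) <- c("polarization_result", class(out))
  out
}

#' Observed versus label-randomized polarization indices
#'
#' For each chromosome copy, the A/B polarization index is computed with the
#' observed compartment labels and with labels randomly permuted across loci
#' while preserving the number of loci in each compartment. Observed and
#' control distributions are compared with a two-sided Wilcoxon rank-sum
#' test. Copies (or permutations) whose groups cannot form a 3D hull are
#' skipped and counted.
#'
#' @param traces trace tibble (see [mean_distance_matrix()]).
#' @param labels character/logical vector per region: `"A"`/`TRUE` versus
#'   `"B"`/`FALSE`.
#' @param n_perm permutations per copy (default 1: one control per copy).
#' @param seed RNG seed for the permutations.
#' @param n_regions number of loci.
#' @return List: `observed` (tibble cell_id, copy_id, pi), `control` (tibble
#'   with permutation index), `p_value`, `n_skipped`.
#' @export
randomized_polarization <- function(traces, labels, n_perm = 1L, seed = 1L,
                                    n_regions = NULL) {
  stopifnot(n_perm >= 1)
  lab <- normalize_labels(labels)
  if (all(lab) || all(!lab))
    stop("labels must contain both compartments")
  copies <- split_copies(traces, n_regions)
  keys <- copy_keys(copies)
  with_seed(seed, {
    obs <- list(); ctrl <- list(); skipped <- 0L
    for (i in seq_along(copies)) {
      m <- copies[[i]]
      present <- complete.cases(m)
      p <- safe_pi(m[present & lab[seq_len(nrow(m))], , drop = FALSE],
                   m[present & !lab[seq_len(nrow(m))], , drop = FALSE])
      if (is.na(p)) { skipped <- skipped + 1L; next }
      obs[[length(obs) + 1L]] <-
        tibble::tibble(cell_id = keys$cell_id[i], copy_id = keys$copy_id[i],
                       pi = p)
      for (k in seq_len(n_perm)) {
        perm <- sample(lab) # preserves the label multiset
        stopifnot(sum(perm) == sum(lab))
        pc <- safe_pi(m[present & perm[seq_len(nrow(m))], , drop = FALSE],
                      m[present & !perm[seq_len(nrow(m))], , drop = FALSE])
        if (is.na(pc)) { skipped <- skipped + 1L; next }
        ctrl[[length(ctrl) + 1L]] <-
          tibble::tibble(cell_id = keys$cell_id[i], copy_id = keys$copy_id[i],
                         perm = k, pi = pc)
      }
    }
    obs <- dplyr::bind_rows(obs); ctrl <- dplyr::bind_rows(ctrl)
    p_value <- if (nrow(obs) > 0 && nrow(ctrl) > 0)
      suppressWarnings(wilcox.test(obs$pi, ctrl$pi)$p.value) else NA_real_
    list(observed = obs, control = ctrl, p_value = p_value,
         n_skipped = skipped)
  })
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.character(labels) || is.factor(labels)) return(as.character(labels) == "A")
  if (is.numeric(labels)) return(labels > 0)
  stop("labels must be logical, A/B character, or numeric scores")
}

copy_keys <- function(copies) {
  parts <- strsplit(names(copies), "\r", fixed = TRUE)
  list(cell_id = vapply(parts, `[`, character(1), 1),
       copy_id = vapply(parts, `[`, character(1), 2))
}

safe_pi <- function(a, b) {
  if (nrow(a) < 4 || nrow(b) < 4) return(NA_real_)
  tryCatch(polarization_index(a, b)$pi, error = function(e) NA_real_)
}

#' Association ratio of traced loci with a voxel mask
#'
#' A locus is associated with the structure (nuclear edge or nucleolus) when
#' its distance to the nearest TRUE voxel center is strictly below
#' `threshold_nm`; distances use the anisotropic physical voxel spacing. The
#' per-region ratio is the number of chromosome copies in which the locus is
#' associated divided by the number of copies in which it was detected.
#'
#' @param traces trace tibble in the same physical frame as the mask.
#' @param mask a [voxel_mask()].
#' @param threshold_nm association threshold (default 200 nm, strict `<`).
#' @param n_regions number of loci.
#' @return Tibble: region_id, ratio, n_associated, n_informative. With an
#'   empty mask all ratios are 0, with a warning.
#' @export
association_ratio <- function(traces, mask, threshold_nm = 200,
                              n_regions = NULL) {
  copies <- split_copies(traces, n_regions)
  n <- nrow(copies[[1]])
  assoc <- matrix(FALSE, length(copies), n)
  inform <- matrix(FALSE, length(copies), n)
  empty <- !any(mask$mask)
  if (empty) warning("empty mask: all association ratios are 0")
  for (i in seq_along(copies)) {
    m <- copies[[i]]
    present <- complete.cases(m)
    inform[i, ] <- present
    if (empty || !any(present)) next
    d <- mask_distance_nm(m[present, , drop = FALSE], mask)
    assoc[i, present] <- d < threshold_nm
  }
  tibble::tibble(region_id = seq_len(n),
                 ratio = ifelse(colSums(inform) > 0,
                                colSums(assoc) / colSums(inform), NA_real_),
                 n_associated = colSums(assoc),
                 n_informative = colSums(inform))
}

#' Chromosome-level compartment-B association flags
#'
#' A chromosome copy's compartment B is considered associated with the
#' structure if any of its B loci is associated (strict `< threshold_nm` to
#' the nearest mask voxel center).
#'
#' @inheritParams association_ratio
#' @param labels per-region compartment labels (see
#'   [randomized_polarization()]).
#' @return Tibble: cell_id, copy_id, associated.
#' @export
chromosome_b_association <- function(traces, mask, labels, threshold_nm = 200,
                                     n_regions = NULL) {
  lab <- normalize_labels(labels)
  copies <- split_copies(traces, n_regions)
  keys <- copy_keys(copies)
  flag <- vapply(copies, function(m) {
    rows <- which(complete.cases(m) & !lab[seq_len(nrow(m))])
    if (length(rows) == 0 || !any(mask$mask)) return(FALSE)
    any(mask_distance_nm(m[rows, , drop = FALSE], mask) < threshold_nm)
  }, logical(1))
  tibble::tibble(cell_id = keys$cell_id, copy_id = keys$copy_id,
                 associated = unname(flag))
}

# nearest-TRUE-voxel-center distance (nm) for each query point, restricting
# the search to a bounding box around each point for speed
mask_distance_nm <- function(points_nm, mask, margin_nm = 2000) {
  vs <- mask$voxel_size
  d <- dim(mask$mask)
  vapply(seq_len(nrow(points_nm)), function(i) {
    p <- points_nm[i, ]
    repeat {
      lo <- pmax(pmin(floor((p - margin_nm) / vs) + 1, d), 1)
      hi <- pmin(pmax(ceiling((p + margin_nm) / vs) + 1, 1), d)
      sub <- mask$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      idx <- which(sub, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        centers <- sweep(idx - 1, 2, lo - 1, "+") # 0-based whole-mask indices
        centers <- sweep(centers, 2, vs, "*")
        return(sqrt(min(colSums((t(centers) - p)^2))))
      }
      if (all(lo == 1) && all(hi == d)) return(Inf)
      margin_nm <- margin_nm * 4
    }
  }, numeric(1))
}

#' Chromosome-surface ratio of traced loci
#'
#' Per chromosome copy, a locus is on the chromosome surface when it is a
#' vertex of the 3D convex hull of all detected loci of that copy. The
#' per-region surface ratio is the fraction of usable copies in which the
#' locus is a hull vertex. Copies with a degenerate hull are excluded.
#'
#' @param traces trace tibble.
#' @param n_regions number of loci.
#' @return Tibble: region_id, ratio, n_surface, n_informative.
#' @export
chromosome_surface_ratio <- function(traces, n_regions = NULL) {
  copies <- split_copies(traces, n_regions)
  n <- nrow(copies[[1]])
  surf <- matrix(FALSE, length(copies), n)
  inform <- matrix(FALSE, length(copies), n)
  for (i in seq_along(copies)) {
    m <- copies[[i]]
    present <- which(complete.cases(m))
    if (length(present) < 4) next
    h <- cpp_convhull(m[present, , drop = FALSE])
    if (!h$ok) next
    inform[i, present] <- TRUE
    surf[i, present[h$vertices]] <- TRUE
  }
  tibble::tibble(region_id = seq_len(n),
                 ratio = ifelse(colSums(inform) > 0,
                                colSums(surf) / colSums(inform), NA_real_),
                 n_surface = colSums(surf),
                 n_informative = colSums(inform))
}

#' Correlation of compartment scores with association ratios
#'
#' Pearson correlation with a two-sided Student-t p value, optionally
#' computed separately for positive-score (compartment A) and negative-score
#' (compartment B) regions, as association patterns differ qualitatively
#' between the compartments. Subsets with fewer than 3 regions are reported
#' as undefined.
#'
#' @param scores numeric per-region compartment scores.
#' @param ratios numeric per-region ratios, aligned with `scores`.
#' @param split_by_sign compute per-compartment correlations as well.
#' @return Tibble: subset ("all", "A", "B"), n, r, p_value.
#' @export
score_ratio_correlation <- function(scores, ratios, split_by_sign = FALSE) {
  stopifnot(length(scores) == length(ratios))
  one <- function(name, s, r) {
    ok <- is.finite(s) & is.finite(r)
    s <- s[ok]; r <- r[ok]
    if (length(s) < 3 || sd(s) == 0 || sd(r) == 0)
      return(tibble::tibble(subset = name, n = length(s), r = NA_real_,
                            p_value = NA_real_))
    ct <- cor.test(s, r, method = "pearson", alternative = "two.sided")
    tibble::tibble(subset = name, n = length(s), r = unname(ct$estimate),
                   p_value = ct$p.value)
  }
  out <- one("all", scores, ratios)
  if (split_by_sign) {
    out <- dplyr::bind_rows(out,
                            one("A", scores[scores > 0], ratios[scores > 0]),
                            one("B", scores[scores <= 0], ratios[scores <= 0]))
  }
  out
}

#' Project loci onto the A-to-B compartment axis
#'
#' Builds the unit vector `u` from the centroid of the A loci to the centroid
#' of the B loci of one chromosome copy and returns each locus's scalar
#' displacement `dot(p - centroid_B, u)`. By construction the mean
#' displacement of the A loci equals minus the centroid separation and the
#' mean displacement of the B loci equals zero, so A and B distributions
#' separate along the axis whenever the compartments are polarized.
#'
#' @param points coordinate matrix (n x 3) of one chromosome copy (no NAs).
#' @param labels per-locus compartment labels.
#' @return Tibble: locus, compartment, displacement.
#' @export
compartment_axis_projection <- function(points, labels) {
  m <- as_point_matrix(points)
  lab <- normalize_labels(labels)
  stopifnot(length(lab) == nrow(m))
  if (!any(lab) || !any(!lab)) stop("both compartments must be non-empty")
  ca <- colMeans(m[lab, , drop = FALSE])
  cb <- colMeans(m[!lab, , drop = FALSE])
  axis <- cb - ca
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("coincident compartment centroids: axis undefined")
  u <- axis / len
  disp <- as.vector((m - matrix(cb, nrow(m), 3, byrow = TRUE)) %*% u)
  tibble::tibble(locus = seq_len(nrow(m)),
                 compartment = ifelse(lab, "A", "B"),
                 displacement = disp)
}
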