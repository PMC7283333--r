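#' Validate a combinatorial barcode codebook
#'
#' Accepts a codebook iff every 16-bit word has Hamming weight exactly 4 and
#' every pair of words is at Hamming distance >= 4 (the error-robust code
#' family used for multiplexed RNA imaging: any single bit flip can be
#' detected, and corrected when `allow_one_bit_correction` is on downstream).
#'
#' @param words data frame with columns `gene_id` and `word` (16-character
#'   "0"/"1" strings, bit order = imaging round order), or a named character
#'   vector of words.
#' @param n_bits,weight,min_distance code parameters.
#' @return A `codebook` tibble (gene_id, word) on success; otherwise an error
#'   naming the offending gene(s).
#' @export
validate_codebook <- function(words, n_bits = 16L, weight = 4L,
                              min_distance = 4L) {
  if (is.character(words))
    words <- tibble::tibble(gene_id = names(words) %||%
                              paste0("gene", seq_along(words)), word = words)
  stopifnot(all(c("gene_id", "word") %in% names(words)))
  if (anyDuplicated(words$gene_id)) stop("duplicate gene ids in codebook")
  bad_len <- nchar(words$word) != n_bits | grepl("[^01]", words$word)
  if (any(bad_len))
    stop("malformed word for gene(s): ",
         paste(words$gene_id[bad_len], collapse = ", "))
  bits <- codeword_bits(words$word, n_bits)
  w <- rowSums(bits)
  if (any(w != weight))
    stop(sprintf("word weight != %d for gene(s): %s", weight,
                 paste(words$gene_id[w != weight], collapse = ", ")))
  n <- nrow(bits)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      hd <- rowSums(sweep(bits[(i + 1):n, , drop = FALSE], 2, bits[i, ],
                          FUN = "!="))
      j <- which(hd < min_distance)
      if (length(j) > 0)
        stop(sprintf("Hamming distance %d < %d between genes %s and %s",
                     hd[j[1]], min_distance, words$gene_id[i],
                     words$gene_id[i + j[1]]))
    }
  }
  out <- tibble::as_tibble(words[, c("gene_id", "word")])
  class(out) <- c("codebook", class(out))
  out
}

codeword_bits <- function(words, n_bits = 16L) {
  t(vapply(words, function(w) as.integer(strsplit(w, "")[[1]]),
           integer(n_bits), USE.NAMES = FALSE))
}

codeword_int <- function(words, n_bits = 16L) {
  bits <- codeword_bits(words, n_bits)
  as.integer(bits %*% 2^(seq_len(n_bits) - 1))
}

#' Binarize one round of multiplexed RNA imaging
#'
#' Per z-plane: the background is a morphological opening with a disk of
#' radius `opening_radius` px; after background subtraction, regional maxima
#' brighter than `intensity_threshold` become candidate RNA pixels, and the
#' binary image is dilated with a 3x3 square so that one molecule can occupy
#' a few adjacent pixels.
#'
#' @param raw_stack an [image_stack()] for one readout round.
#' @param intensity_threshold positive intensity threshold on the
#'   background-subtracted image.
#' @param opening_radius disk radius for the background opening.
#' @param dilation_width width of the square dilation element.
#' @return Logical array of the same shape as the stack.
#' @export
binarize_round <- function(raw_stack, intensity_threshold,
                           opening_radius = 5L, dilation_width = 3L) {
  stopifnot(intensity_threshold > 0)
  stack <- as_stack(raw_stack)
  d <- dim(stack$voxels)
  out <- array(FALSE, d)
  brush <- disc_brush(opening_radius)
  square <- EBImage::makeBrush(dilation_width, "box")
  for (k in seq_len(d[3])) {
    plane <- stack$voxels[, , k]
    bg <- EBImage::opening(plane, brush)
    sub <- plane - bg
    on <- regional_maxima(sub) & sub > intensity_threshold
    if (any(on))
      on <- EBImage::dilate(on * 1, square) > 0
    out[, , k] <- on
  }
  out
}

#' Decode barcoded pixels into RNA molecules
#'
#' Composes, per voxel, the 16-bit word from the 16 aligned binary round
#' stacks and matches it against the codebook: exact matches by default, or
#' additionally words at Hamming distance 1 from a unique codeword when
#' `allow_one_bit_correction` is on. Adjacent same-gene pixels within a
#' z-plane (8-connectivity; no merging across planes) collapse into a single
#' molecule whose representative position is the pixel centroid.
#'
#' @param bits list of 16 logical arrays of identical shape (round order =
#'   bit order of the codebook).
#' @param codebook a [validate_codebook()] result.
#' @param allow_one_bit_correction logical; default FALSE (exact matching).
#' @return Tibble of molecules: `gene_id`, `x_px`, `y_px` (centroid, 0-based),
#'   `z` (0-based plane), `pixel_count`.
#' @export
decode_pixels <- function(bits, codebook, allow_one_bit_correction = FALSE) {
  n_bits <- nchar(codebook$word[1])
  if (length(bits) != n_bits)
    stop(sprintf("expected %d round stacks, got %d", n_bits, length(bits)))
  dims <- lapply(bits, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("round stacks have mismatched shapes")
  d <- dims[[1]]
  code_ints <- codeword_int(codebook$word, n_bits)
  lut <- integer(2^n_bits) # word value + 1 -> gene index (0 = no call)
  lut[code_ints + 1L] <- seq_along(code_ints)
  if (allow_one_bit_correction) {
    for (g in seq_along(code_ints)) {
      flips <- bitwXor(code_ints[g], 2^(seq_len(n_bits) - 1))
      for (f in flips) {
        slot <- f + 1L
        if (lut[slot] == 0L) lut[slot] <- g
        else if (lut[slot] != g) lut[slot] <- -1L # ambiguous
      }
    }
    lut[lut < 0L] <- 0L
  }
  word <- array(0L, d)
  for (b in seq_len(n_bits))
    word <- word + as.integer(bits[[b]]) * as.integer(2^(b - 1))
  gene_img <- array(lut[word + 1L], d)
  mols <- lapply(seq_len(d[3]), function(k) {
    merge_plane_molecules(gene_img[, , k], k - 1L)
  })
  mols <- dplyr::bind_rows(mols)
  if (nrow(mols) > 0) mols$gene_id <- codebook$gene_id[mols$gene]
  else mols$gene_id <- character()
  mols[, c("gene_id", "x_px", "y_px", "z", "pixel_count")]
}

# union-find over the sparse decoded pixels of one plane (8-connectivity)
merge_plane_molecules <- function(gene_plane, z) {
  on <- which(gene_plane > 0L, arr.ind = TRUE)
  if (nrow(on) == 0)
    return(tibble::tibble(gene = integer(), x_px = numeric(),
                          y_px = numeric(), z = integer(),
                          pixel_count = integer()))
  g <- gene_plane[on]
  n <- nrow(on)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  key <- paste(on[, 1], on[, 2], g, sep = ",")
  index <- setNames(seq_len(n), key)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  for (o in seq_len(nrow(offs))) {
    nb <- paste(on[, 1] + offs[o, 1], on[, 2] + offs[o, 2], g, sep = ",")
    j <- index[nb]
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  tibble::tibble(
    gene = g, x = on[, 1] - 1, y = on[, 2] - 1, root = root) |>
    dplyr::group_by(.data$root) |>
    dplyr::summarise(gene = .data$gene[1], x_px = mean(.data$x),
                     y_px = mean(.data$y), pixel_count = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(z = z) |>
    dplyr::select("gene", "x_px", "y_px", "z", "pixel_count")
}

#' Calibrate per-round binarization thresholds against reference abundances
#'
#' Screens per-round intensity thresholds so that decoded molecule counts
#' agree with an external abundance reference (e.g. bulk RNA-seq). The grid
#' per round is `grid_size` log-spaced intensity values between the 90th and
#' 99.9th percentile of that round's background-subtracted intensities.
#' Initialization matches each round's on-pixel load to the codebook-predicted
#' round loading from the reference abundances; then a deterministic
#' coordinate-wise search maximizes the Pearson correlation between
#' log-transformed decoded per-gene totals and log reference abundances.
#'
#' @param raw_rounds list of [image_stack()]s, one per round.
#' @param codebook a [validate_codebook()] result.
#' @param reference_abundances named numeric vector (gene_id -> abundance),
#'   positive for at least 10 genes and not all equal.
#' @param grid_size,sweeps grid resolution and number of coordinate sweeps.
#' @return List with `thresholds` (numeric per round), `correlation`
#'   (achieved log-scale Pearson correlation) and `counts` (decoded per-gene
#'   totals at the selected thresholds).
#' @export
calibrate_thresholds <- function(raw_rounds, codebook, reference_abundances,
                                 grid_size = 20L, sweeps = 2L) {
  n_rounds <- length(raw_rounds)
  ref <- reference_abundances[codebook$gene_id]
  ref[is.na(ref)] <- 0
  if (sum(ref > 0) < 10)
    stop("need positive reference abundances for at least 10 genes")
  if (length(unique(ref)) < 2)
    stop("degenerate reference: all abundances equal")
  stacks <- lapply(raw_rounds, as_stack)
  grids <- lapply(stacks, function(s) {
    v <- as.vector(s$voxels)
    q <- quantile(v[v > 0], c(0.90, 0.999), names = FALSE)
    q <- pmax(q, 1e-6)
    exp(seq(log(q[1]), log(max(q[2], q[1] * 1.001)), length.out = grid_size))
  })
  # cache binarized stacks for every grid value
  cache <- lapply(seq_len(n_rounds), function(r) {
    lapply(grids[[r]], function(t) binarize_round(stacks[[r]], t))
  })
  bits_mat <- codeword_bits(codebook$word, n_rounds)
  loading <- as.vector(ref %*% bits_mat) # predicted per-round on-load
  loading <- loading / max(loading)
  # initialization: on-pixel count proportional to predicted loading
  counts_at <- vapply(seq_len(n_rounds), function(r)
    vapply(cache[[r]], sum, numeric(1)), numeric(grid_size))
  target <- loading * max(counts_at)
  idx <- vapply(seq_len(n_rounds), function(r) {
    which.min(abs(counts_at[, r] - target[r]))
  }, integer(1))
  objective <- function(idx) {
    bits <- lapply(seq_len(n_rounds), function(r) cache[[r]][[idx[r]]])
    mols <- decode_pixels(bits, codebook)
    tot <- table(factor(mols$gene_id, levels = codebook$gene_id))
    tot <- as.numeric(tot)
    use <- ref > 0
    if (sd(tot[use]) == 0) return(list(value = -Inf, counts = tot))
    list(value = cor(log1p(tot[use]), log(ref[use])), counts = tot)
  }
  best <- objective(idx)
  for (s in seq_len(sweeps)) {
    for (r in seq_len(n_rounds)) {
      for (g in seq_len(grid_size)) {
        if (g == idx[r]) next
        trial <- idx; trial[r] <- g
        obj <- objective(trial)
        if (obj$value > best$value + 1e-12) { idx <- trial; best <- obj }
      }
    }
  }
  list(thresholds = vapply(seq_len(n_rounds), function(r) grids[[r]][idx[r]],
                           numeric(1)),
       correlation = best$value, counts = setNames(best$counts,
                                                   codebook$gene_id))
}

#' Count decoded molecules per segmented cell
#'
#' Each cell's area is first shrunk by erosion with a disk of radius
#' `erosion_radius` px, reducing mis-assignment of molecules between
#' neighboring cells; molecules outside any eroded cell stay unassigned.
#' QC flags follow the acquisition conventions: cells with area outside the
#' open interval `area_limits`, edge-touching cells, and cells with fewer
#' than `min_molecules` assigned molecules are flagged and excluded from
#' analysis views.
#'
#' @param molecules tibble from [decode_pixels()].
#' @param labels a `cell_label_map` from [segment_cells()].
#' @param erosion_radius disk radius for the per-cell erosion.
#' @param area_limits,min_molecules QC thresholds.
#' @param genes optional character vector fixing the gene (column) order.
#' @return An `expression_matrix`: list with `counts` (cells x genes integer
#'   matrix over all labels), `qc` (tibble: cell, area, n_molecules, flags,
#'   retained) and `n_unassigned`.
#' @export
count_per_cell <- function(molecules, labels, erosion_radius = 3L,
                           area_limits = c(2500, 20000), min_molecules = 10L,
                           genes = NULL) {
  lab <- labels$labels
  ids <- sort(unique(lab[lab > 0]))
  genes <- genes %||% sort(unique(molecules$gene_id))
  brush <- disc_brush(erosion_radius)
  eroded <- matrix(0L, nrow(lab), ncol(lab))
  for (id in ids) {
    m <- EBImage::erode((lab == id) * 1, brush) > 0
    eroded[m] <- id
  }
  px <- cbind(round(molecules$x_px) + 1, round(molecules$y_px) + 1)
  inside <- px[, 1] >= 1 & px[, 1] <= nrow(lab) &
    px[, 2] >= 1 & px[, 2] <= ncol(lab)
  cell_of <- rep(0L, nrow(molecules))
  cell_of[inside] <- eroded[px[inside, , drop = FALSE]]
  counts <- matrix(0L, length(ids), length(genes),
                   dimnames = list(ids, genes))
  assigned <- cell_of > 0
  if (any(assigned)) {
    tab <- table(factor(cell_of[assigned], levels = ids),
                 factor(molecules$gene_id[assigned], levels = genes))
    counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                     dimnames = dimnames(tab))
  }
  areas <- tabulate(lab[lab > 0], nbins = max(ids, 1L))[ids]
  edge_excl <- labels$excluded
  qc <- tibble::tibble(
    cell = ids, area = areas, n_molecules = as.integer(rowSums(counts)))
  qc$flag_area <- !(qc$area > area_limits[1] & qc$area < area_limits[2])
  qc$flag_edge <- ids %in% edge_excl$label[edge_excl$reason == "edge"]
  qc$flag_min_count <- qc$n_molecules < min_molecules
  qc$retained <- !(qc$flag_area | qc$flag_edge | qc$flag_min_count)
  structure(list(counts = counts, qc = qc,
                 n_unassigned = sum(!assigned)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, %d molecules unassigned, %d cells retained\n",
              nrow(x$counts), ncol(x$counts), x$n_unassigned,
              sum(x$qc$retained)))
  invisible(x)
}

#' Tidy an expression matrix into long per-cell, per-gene counts
#' @param x an `expression_matrix`.
#' @param ... unused.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts,
                                        responseName = "count",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("cell", "gene_id", "count")) |>
    dplyr::mutate(cell = as.integer(.data$cell),
                  count = as.integer(.data$count))
}
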