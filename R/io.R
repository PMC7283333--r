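#' Read genomic regions from a BED-like file
#'
#' BED conventions: tab-separated, 0-based half-open coordinates on disk
#' (`one_based = TRUE` accepts 1-based inclusive input and converts).
#' Columns: chrom, start, end, name (region_id); an optional 5th column is
#' read as gene density (genes/Mb).
#'
#' @param path file path.
#' @param one_based input uses 1-based inclusive coordinates.
#' @return Tibble: chrom, start, end, region_id, and gene_density when
#'   present; row order preserved.
#' @export
read_regions <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  bad <- which(nf < 4)
  if (length(bad) > 0)
    stop(sprintf("malformed BED line %d: expected at least 4 tab-separated fields",
                 bad[1]))
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  if (one_based) start <- start - 1
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop(sprintf("malformed BED line %d: end <= start", bad[1]))
  out <- tibble::tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = start, end = end,
    region_id = vapply(parts, `[`, "", 4))
  if (anyDuplicated(out$region_id))
    stop("duplicate region ids: ",
         paste(unique(out$region_id[duplicated(out$region_id)]), collapse = ", "))
  if (all(nf >= 5)) {
    gd <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5)))
    if (!anyNA(gd)) out$gene_density <- gd
  }
  out
}

#' Write genomic regions to BED
#' @param regions tibble from [read_regions()].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  cols <- list(regions$chrom, format(regions$start, scientific = FALSE,
                                     trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE),
               regions$region_id)
  if (!is.null(regions[["gene_density"]])) cols <- c(cols, list(regions[["gene_density"]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read / write chromatin traces (CSV)
#'
#' The on-disk schema is `cell_id, copy_id, region_id, x_nm, y_nm, z_nm,
#' quality`; missing loci have empty coordinate fields. Coordinates are in
#' nm — a file whose header carries px-unit columns is rejected rather than
#' silently misread.
#'
#' @param path file path.
#' @return Trace tibble.
#' @export
read_traces <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expected <- c("cell_id", "copy_id", "region_id", "x_nm", "y_nm", "z_nm",
                "quality")
  if (any(grepl("_px$", hdr)))
    stop("trace file carries pixel-unit columns; expected nm coordinates")
  unknown <- setdiff(hdr, expected)
  if (length(unknown) > 0)
    stop("unknown trace column(s): ", paste(unknown, collapse = ", "))
  if (!all(expected[1:6] %in% hdr))
    stop("trace file must have columns ", paste(expected[1:6], collapse = ", "))
  out <- readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_character(), copy_id = readr::col_integer(),
    region_id = readr::col_integer(), x_nm = readr::col_double(),
    y_nm = readr::col_double(), z_nm = readr::col_double(),
    .default = readr::col_double()), progress = FALSE)
  if (!"quality" %in% names(out)) out$quality <- 1
  out
}

#' @rdname read_traces
#' @param traces trace tibble.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write a barcode codebook (CSV: gene_id, word)
#' @param path file path.
#' @param ... passed to [validate_codebook()].
#' @export
read_codebook <- function(path, ...) {
  df <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  validate_codebook(df, ...)
}

#' @rdname read_codebook
#' @param codebook a codebook tibble.
#' @export
write_codebook <- function(codebook, path) {
  readr::write_csv(codebook[, c("gene_id", "word")], path, progress = FALSE)
  invisible(path)
}

#' Read / write image stacks as multi-page TIFF
#'
#' Intensities are stored as 32-bit float TIFF pages (one page per z-plane),
#' divided by `scale` on write (TIFF stores values in the unit interval) and
#' multiplied back on read.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @param voxel_size,channel metadata attached on read.
#' @param scale intensity full-scale used for the unit-interval encoding.
#' @export
write_stack <- function(stack, path, scale = 65535) {
  stack <- as_stack(stack)
  pages <- lapply(seq_len(dim(stack$voxels)[3]),
                  function(k) stack$voxels[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, voxel_size = c(107.9, 107.9, 200),
                       channel = NULL, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]] * scale
  image_stack(vox, voxel_size, channel)
}

#' Write / read a binary voxel mask as multi-page TIFF
#' @param mask a [voxel_mask()].
#' @param path file path.
#' @param voxel_size,kind metadata attached on read.
#' @export
write_mask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask$mask)[3]),
                  function(k) matrix(as.numeric(mask$mask[, , k]),
                                     dim(mask$mask)[1], dim(mask$mask)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, voxel_size = c(107.9, 107.9, 200),
                      kind = "nuclear_edge") {
  s <- read_stack(path, voxel_size)
  voxel_mask(s$voxels > 0.5, voxel_size, kind)
}

#' Write a dense matrix as CSV with region-order header
#' @param m matrix.
#' @param path file path.
#' @param ids column/row identifiers.
#' @export
write_matrix_csv <- function(m, path, ids = NULL) {
  ids <- ids %||% colnames(m) %||% paste0("r", seq_len(ncol(m)))
  df <- as.data.frame(m)
  names(df) <- ids
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}

#' Read a run configuration (YAML)
#'
#' Validates thresholds (all positive) and fills defaults: contact 150 nm,
#' association 200 nm, voxel size (107.9, 107.9, 200) nm, simulator preset
#' `full`.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg config list.
#' @export
validate_run_config <- function(cfg) {
  cfg$thresholds <- cfg$thresholds %||% list()
  cfg$thresholds$contact_nm <- cfg$thresholds$contact_nm %||% 150
  cfg$thresholds$association_nm <- cfg$thresholds$association_nm %||% 200
  if (cfg$thresholds$contact_nm <= 0 || cfg$thresholds$association_nm <= 0)
    stop("thresholds must be positive")
  cfg$voxel_size <- as.numeric(cfg$voxel_size %||% c(107.9, 107.9, 200))
  cfg$seed <- cfg$seed %||% 1L
  cfg$simulator <- cfg$simulator %||% list()
  cfg$simulator$preset <- cfg$simulator$preset %||% "full"
  cfg$simulator$n_runs <- cfg$simulator$n_runs %||% 100L
  cfg$simulator$n_accepted <- cfg$simulator$n_accepted %||% 60000L
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  cfg
}

#' Write an expression matrix as MatrixMarket (MTX) + index sidecars
#'
#' Sparse exchange format for cells x genes counts: `<stem>.mtx` plus
#' `<stem>.cells.txt` and `<stem>.genes.txt` row/column indexes.
#'
#' @param em an `expression_matrix` from [count_per_cell()].
#' @param stem output path without extension.
#' @export
write_expression_mtx <- function(em, stem) {
  idx <- which(em$counts != 0, arr.ind = TRUE)
  m <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
                            x = as.numeric(em$counts[idx]),
                            dims = dim(em$counts))
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(rownames(em$counts), paste0(stem, ".cells.txt"))
  writeLines(colnames(em$counts), paste0(stem, ".genes.txt"))
  invisible(stem)
}
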