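#' Run an end-to-end phantom pipeline
#'
#' Executes the requested stages on a synthetic scene — `synth` (phantom
#' generation), `segment` (cell segmentation + masks), `decode` (barcode
#' decoding + per-cell counts), `trace_stats` (distance matrix + synthetic
#' Hi-C comparison), `compartments` (compartment scores), `architecture`
#' (polarization + association ratios), `simulate` (lattice-polymer
#' ensemble) — writing per-stage artifacts, a manifest per stage (inputs,
#' seed, parameter hash) and a machine-readable `summary.json`. A stage
#' failure halts the run with a stage-named error; completed outputs are
#' retained.
#'
#' @param config a config list (see [read_run_config()]); must contain
#'   `out_dir`. `stages` defaults to all of the above.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
pipeline_run <- function(config) {
  cfg <- validate_run_config(config)
  out_dir <- cfg$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% c("synth", "segment", "decode", "trace_stats",
                              "compartments", "architecture", "simulate")
  state <- new.env(parent = emptyenv())
  state$manifests <- list()
  for (stage in stages) {
    fn <- switch(stage,
                 synth = stage_synth, segment = stage_segment,
                 decode = stage_decode, trace_stats = stage_trace_stats,
                 compartments = stage_compartments,
                 architecture = stage_architecture,
                 simulate = stage_simulate,
                 stop("unknown stage: ", stage))
    t0 <- Sys.time()
    res <- tryCatch(fn(cfg, state, out_dir),
                    error = function(e)
                      stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE))
    state$manifests[[stage]] <- list(
      stage = stage, seed = cfg$seed,
      wall_seconds = as.numeric(Sys.time() - t0, units = "secs"),
      param_hash = rlang::hash(cfg), outputs = res)
    message(sprintf("[%s] done in %.1fs", stage,
                    state$manifests[[stage]]$wall_seconds))
  }
  summary <- list(config_hash = rlang::hash(cfg), seed = cfg$seed,
                  stages = state$manifests)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

stage_synth <- function(cfg, state, out_dir) {
  n_cells <- cfg$n_cells %||% 9L
  scene <- gen_scene(n_cells, fov_shape = cfg$fov_shape %||% c(448L, 448L, 8L),
                     voxel_size = cfg$voxel_size, seed = cfg$seed)
  n_loci <- cfg$n_loci %||% 50L
  scores_planted <- planted_block_scores(n_loci)
  traces <- gen_traces(n_cells, scores_planted,
                       polarization_strength = cfg$polarization %||% 0.8,
                       seed = cfg$seed + 1, centers = scene$truth$cells,
                       voxel_size = cfg$voxel_size)
  state$scene <- scene
  state$traces <- traces
  state$planted_scores <- scores_planted
  f <- file.path(out_dir, "traces.csv")
  write_traces(traces, f)
  write_stack(scene$stacks$membrane, file.path(out_dir, "membrane.tif"))
  list(traces = f)
}

stage_segment <- function(cfg, state, out_dir) {
  if (is.null(state$scene)) stop("requires the synth stage to run first")
  labels <- segment_cells(state$scene$stacks$membrane)
  edge <- nuclear_edge_mask(state$scene$stacks$nucleus)
  nucl <- nucleolus_mask(state$scene$stacks$fibrillarin)
  state$labels <- labels; state$edge <- edge; state$nucleolus <- nucl
  f <- file.path(out_dir, "cells.tif")
  tiff::writeTIFF(labels$labels / max(labels$labels, 1), f,
                  bits.per.sample = 16L)
  write_mask(edge, file.path(out_dir, "nuclear_edge.tif"))
  write_mask(nucl, file.path(out_dir, "nucleolus.tif"))
  list(labels = f)
}

stage_decode <- function(cfg, state, out_dir) {
  if (is.null(state$scene)) stop("requires the synth stage to run first")
  cb <- if (!is.null(cfg$inputs$codebook)) read_codebook(cfg$inputs$codebook)
        else validate_codebook(example_codebook(10))
  phantom <- gen_merfish_stacks(cb, molecules_per_gene = 30L,
                                fov_shape = dim(state$scene$stacks$membrane$voxels),
                                seed = cfg$seed + 2)
  bits <- lapply(phantom$rounds, function(s) binarize_round(s, 10))
  mols <- decode_pixels(bits, cb)
  em <- count_per_cell(mols, state$labels)
  state$expression <- em
  f <- file.path(out_dir, "expression.csv")
  readr::write_csv(tidy(em), f, progress = FALSE)
  list(expression = f)
}

stage_trace_stats <- function(cfg, state, out_dir) {
  if (is.null(state$traces)) stop("requires the synth stage to run first")
  dm <- mean_distance_matrix(state$traces, min_pairs = 2L)
  counts <- gen_hic_counts(state$traces, model = "powerlaw",
                           seed = cfg$seed + 3)
  regions <- synthetic_regions(dm$n_regions)
  freq <- hic_contact_frequency(counts, regions)
  up <- upper.tri(freq)
  ok <- freq[up] > 0 & !is.na(dm$mean[up])
  pl <- fit_distance_powerlaw(dm$mean[up][ok], 1 / freq[up][ok])
  state$dm <- dm; state$regions <- regions
  state$hic_powerlaw <- pl
  f <- file.path(out_dir, "distance_matrix.csv")
  write_matrix_csv(dm$mean, f)
  list(distance_matrix = f,
       hic_exponent = pl$exponent, hic_correlation = pl$correlation)
}

stage_compartments <- function(cfg, state, out_dir) {
  if (is.null(state$dm)) stop("requires the trace_stats stage to run first")
  cr <- compartment_scores(state$dm, state$regions)
  state$compartments <- cr
  f <- file.path(out_dir, "compartment_scores.csv")
  readr::write_csv(tidy(cr), f, progress = FALSE)
  list(scores = f, exponent = cr$powerlaw$exponent)
}

stage_architecture <- function(cfg, state, out_dir) {
  if (is.null(state$compartments) || is.null(state$edge))
    stop("requires the segment and compartments stages to run first")
  labels <- state$compartments$scores$score
  rp <- randomized_polarization(state$traces, labels, seed = cfg$seed + 4)
  sr <- chromosome_surface_ratio(state$traces)
  la <- association_ratio(state$traces, state$edge,
                          cfg$thresholds$association_nm)
  na_ <- association_ratio(state$traces, state$nucleolus,
                           cfg$thresholds$association_nm)
  out <- dplyr::bind_cols(
    sr[, c("region_id", "ratio")] |> stats::setNames(c("region_id", "surface_ratio")),
    lamina_ratio = la$ratio, nucleolar_ratio = na_$ratio)
  f <- file.path(out_dir, "association.csv")
  readr::write_csv(out, f, progress = FALSE)
  readr::write_csv(rp$observed, file.path(out_dir, "polarization.csv"),
                   progress = FALSE)
  state$polarization <- rp
  list(association = f, median_pi = median(rp$observed$pi),
       median_pi_control = median(rp$control$pi))
}

stage_simulate <- function(cfg, state, out_dir) {
  scores <- state$compartments$scores$score %||%
    planted_block_scores(cfg$n_loci %||% 50L)
  ens <- simulate_ensemble(scores, cfg$simulator$preset,
                           n_runs = cfg$simulator$n_runs,
                           n_accepted = cfg$simulator$n_accepted,
                           base_seed = cfg$seed + 5)
  f <- file.path(out_dir, "ensemble.csv")
  readr::write_csv(ens$conformations, f, progress = FALSE)
  readr::write_csv(glance(ens), file.path(out_dir, "ensemble_summary.csv"),
                   progress = FALSE)
  as.list(glance(ens)[1, c("median_pi", "median_pi_control")])
}

#' Synthetic compartment score profile (hepatocyte-like stand-in)
#'
#' A deterministic alternating block profile over `n` loci, normalized to
#' unit norm like a first-principal-component coefficient vector: contiguous
#' A (positive) and B (negative) blocks whose magnitudes rise away from the
#' block boundaries, with a floor (`magnitude_floor`) so that no locus has a
#' vanishing compartment identity. This is a synthetic stand-in with the
#' qualitative structure of a measured mammalian-chromosome compartment
#' profile — many A/B alternations of varying strength along the chromosome
#' — not measured data.
#'
#' @param n number of loci.
#' @param n_blocks approximate number of A/B blocks along the profile.
#' @param magnitude_floor minimum relative score magnitude at block
#'   boundaries.
#' @return Numeric length-n unit-norm score vector (both signs present).
#' @export
planted_block_scores <- function(n = 50L, n_blocks = 13L,
                                 magnitude_floor = 0.12) {
  t <- seq(0, n_blocks * pi, length.out = n)
  s <- sign(sin(t)) *
    (magnitude_floor + (1 - magnitude_floor) * abs(sin(t)))
  s[s == 0] <- magnitude_floor
  s / sqrt(sum(s^2))
}

#' Equally spaced synthetic region table
#' @param n number of regions.
#' @param chrom chromosome name.
#' @param width_bp region width.
#' @param spacing_bp center-to-center spacing.
#' @return Region tibble compatible with [compartment_scores()].
#' @export
synthetic_regions <- function(n, chrom = "chrS", width_bp = 1e5,
                              spacing_bp = 1.2e6) {
  start <- (seq_len(n) - 1) * spacing_bp
  tibble::tibble(chrom = chrom, start = start, end = start + width_bp,
                 region_id = paste0("R", seq_len(n)))
}

#' Small example codebook (16-bit, weight 4, min Hamming distance 4)
#'
#' Deterministically greedily built from the lexicographic enumeration of all
#' weight-4 words, for tests and phantoms.
#'
#' @param n_genes number of codewords (<= 140).
#' @return Tibble (gene_id, word) suitable for [validate_codebook()].
#' @export
example_codebook <- function(n_genes = 10L) {
  combs <- utils::combn(16L, 4L)
  words <- character(0)
  bits_sel <- matrix(0L, 0, 16)
  for (i in seq_len(ncol(combs))) {
    b <- integer(16); b[combs[, i]] <- 1L
    if (nrow(bits_sel) > 0) {
      hd <- rowSums(sweep(bits_sel, 2, b, FUN = "!="))
      if (min(hd) < 4) next
    }
    bits_sel <- rbind(bits_sel, b)
    words <- c(words, paste(b, collapse = ""))
    if (length(words) >= n_genes) break
  }
  if (length(words) < n_genes)
    stop("cannot build that many codewords at Hamming distance 4")
  tibble::tibble(gene_id = sprintf("gene%02d", seq_len(n_genes)),
                 word = words)
}
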