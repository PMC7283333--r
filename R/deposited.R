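#' Reproduce headline statistics from deposited chromatin-tracing data
#'
#' Recomputes, from a local copy of publicly deposited single-cell
#' chromatin traces and a matching bulk Hi-C contact-count matrix, the three
#' headline population statistics of the TAD-scale analysis: the observed
#' versus label-randomized median polarization index, and the correlation
#' and power-law exponent between inverse length-normalized Hi-C contact
#' frequency and mean spatial distance.
#'
#' The deposited tables are not bundled with this package (they are large,
#' externally hosted downloads); point `data_dir` at a directory containing
#' `traces.csv` (schema of [read_traces()]), `regions.bed` and
#' `hic_counts.csv` (dense counts, region order matching the BED).
#'
#' @param data_dir directory holding the deposited tables.
#' @param labels optional per-region compartment labels; defaults to the
#'   sign of freshly computed compartment scores.
#' @param seed RNG seed for the randomization control.
#' @return List: `median_pi`, `median_pi_control`, `pi_p_value`,
#'   `hic_correlation`, `hic_exponent`.
#' @export
deposited_reproduction <- function(data_dir, labels = NULL, seed = 1L) {
  need <- file.path(data_dir, c("traces.csv", "regions.bed", "hic_counts.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0)
    stop("deposited data not found: ", paste(missing, collapse = ", "),
         ". Download the deposited trace tables and the Hi-C counts into '",
         data_dir, "' first.")
  traces <- read_traces(need[1])
  regions <- read_regions(need[2])
  counts <- read_matrix_csv(need[3])
  dm <- mean_distance_matrix(traces, min_pairs = 20L,
                             n_regions = nrow(regions))
  if (is.null(labels)) {
    cr <- compartment_scores(dm, regions)
    labels <- cr$scores$score
  }
  rp <- randomized_polarization(traces, labels, seed = seed,
                                n_regions = nrow(regions))
  freq <- hic_contact_frequency(counts, regions)
  up <- upper.tri(freq)
  ok <- is.finite(freq[up]) & freq[up] > 0 & is.finite(dm$mean[up]) &
    dm$mean[up] > 0
  pl <- fit_distance_powerlaw(dm$mean[up][ok], 1 / freq[up][ok])
  list(median_pi = median(rp$observed$pi),
       median_pi_control = median(rp$control$pi),
       pi_p_value = rp$p_value,
       hic_correlation = pl$correlation,
       hic_exponent = pl$exponent)
}
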