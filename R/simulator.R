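#' Named parameter presets for the lattice polymer model
#'
#' Interaction strengths for the three standard simulation settings:
#' `bb_only` (self-association among compartment-B monomers only), `aa_bb`
#' (A-A and B-B self-association) and `full` (A-A and B-B plus A-surface and
#' B-surface couplings to the extra-chromosomal surroundings).
#'
#' @param preset one of `"bb_only"`, `"aa_bb"`, `"full"`.
#' @return List with `g_aa`, `g_bb`, `g_as`, `g_bs` and `contact_radius`
#'   (2 lattice units, strict).
#' @export
energy_params <- function(preset = c("bb_only", "aa_bb", "full")) {
  preset <- match.arg(preset)
  p <- switch(preset,
              bb_only = c(0, 50, 0, 0),
              aa_bb = c(50, 50, 0, 0),
              full = c(50, 50, 40, 25))
  list(g_aa = p[1], g_bb = p[2], g_as = p[3], g_bs = p[4],
       contact_radius = 2, preset = preset)
}

#' Random self-avoiding initial lattice conformation
#'
#' A random chain of `n` distinct integer lattice points whose consecutive
#' monomers lie at Euclidean distance between 1 and 4 lattice units
#' (the bond constraint maintained throughout the simulation).
#'
#' @param n number of monomers (default 50).
#' @param seed RNG seed; the conformation is a pure function of it.
#' @param max_restarts restarts allowed when the growing chain traps itself.
#' @return Integer n x 3 matrix of lattice coordinates.
#' @export
init_conformation <- function(n = 50L, seed = 1L, max_restarts = 100L) {
  stopifnot(n >= 2)
  with_seed(seed, cpp_random_saw(as.integer(n), as.integer(max_restarts)))
}

#' Check lattice-conformation invariants
#'
#' @param conf integer n x 3 matrix.
#' @return TRUE invisibly; errors when positions repeat (self-avoidance) or a
#'   bond length leaves `[1, 4]` lattice units.
#' @export
check_conformation <- function(conf) {
  conf <- as.matrix(conf)
  if (anyDuplicated(conf) > 0) stop("conformation is not self-avoiding")
  if (nrow(conf) > 1) {
    sq <- rowSums(diff(conf)^2)
    if (any(sq < 1 | sq > 16))
      stop("bond length outside [1, 4] lattice units")
  }
  invisible(TRUE)
}

#' Energy of a lattice conformation
#'
#' Evaluates the score-weighted interaction energy
#' `E = sum_AA g_aa S_i S_j + sum_BB g_bb S_p S_q +
#'    sum_{A surf} g_as (S_m - mean S_A) + sum_{B surf} g_bs (mean S_B - S_n)`
#' with contacts = same-compartment pairs at Euclidean distance strictly
#' below 2 lattice units and surface = convex-hull vertices of all monomers.
#' Monomers with positive score are compartment A, the rest compartment B.
#' Under the default `sign_mode = "attractive"` the Metropolis objective is
#' the negation of this printed expression, making the stated interactions
#' energetically favourable; `"as_printed"` minimizes the expression as
#' written.
#'
#' @param conf integer n x 3 lattice conformation.
#' @param scores per-monomer compartment scores (length n).
#' @param params an [energy_params()] list.
#' @param sign_mode `"attractive"` (default) or `"as_printed"`.
#' @return List: `printed_energy`, `objective` (what Metropolis minimizes),
#'   `pair_term`, `surface_term`.
#' @export
lattice_energy <- function(conf, scores, params,
                           sign_mode = c("attractive", "as_printed")) {
  sign_mode <- match.arg(sign_mode)
  conf <- as.matrix(conf)
  storage.mode(conf) <- "integer"
  check_conformation(conf)
  e <- cpp_lattice_energy(conf, as.numeric(scores), params$g_aa, params$g_bb,
                          params$g_as, params$g_bs)
  e$objective <- if (sign_mode == "attractive") -e$printed_energy
                 else e$printed_energy
  e
}

#' One Metropolis Monte Carlo run of the lattice polymer
#'
#' Starting from a random (or supplied) self-avoiding conformation, repeats:
#' pick a monomer uniformly at random, propose one of its six axis neighbors,
#' abandon the attempt outright if the site is occupied or a bond constraint
#' would break (such attempts are not Metropolis-evaluated and do not count),
#' otherwise accept with the Metropolis probability on the objective. Exactly
#' `n_accepted` accepted moves are simulated; with all couplings zero every
#' constraint-legal proposal is accepted.
#'
#' @param scores per-monomer compartment scores.
#' @param params an [energy_params()] list.
#' @param n_accepted accepted-move budget (default 60000).
#' @param seed RNG seed; the trajectory is a pure function of it.
#' @param init optional initial conformation (default: random self-avoiding
#'   chain drawn under the same seed).
#' @param sign_mode see [lattice_energy()].
#' @return List (class `mc_run`): `conformation` (final), `energy_trace`
#'   (printed energy after each accepted move), `attempts`, `evaluated`,
#'   `seed`.
#' @export
mc_run <- function(scores, params, n_accepted = 60000L, seed = 1L,
                   init = NULL, sign_mode = c("attractive", "as_printed")) {
  sign_mode <- match.arg(sign_mode)
  scores <- as.numeric(scores)
  with_seed(seed, {
    conf0 <- init %||% cpp_random_saw(length(scores), 100L)
    conf0 <- as.matrix(conf0)
    storage.mode(conf0) <- "integer"
    res <- cpp_mc_run(conf0, scores, params$g_aa, params$g_bb, params$g_as,
                      params$g_bs, sign_mode == "attractive",
                      as.integer(n_accepted), 1e5)
    structure(list(conformation = res$conformation,
                   energy_trace = res$energy_trace,
                   attempts = res$attempts, evaluated = res$evaluated,
                   seed = seed, sign_mode = sign_mode, params = params),
              class = "mc_run")
  })
}

#' Equilibration check on an energy trace
#'
#' Linear-trend test on the last `window` accepted moves of the printed
#' energy trace. The window is cut into `n_blocks` consecutive blocks and the
#' trend is the regression of block-mean energy on block index; using block
#' means absorbs the strong move-to-move autocorrelation of the chain.
#'
#' @param run an [mc_run()] result.
#' @param window number of trailing accepted moves (default 10000).
#' @param n_blocks number of blocks the window is averaged into.
#' @return List: `slope` (energy per accepted move), `p_value`,
#'   `equilibrated` (p > 0.01).
#' @export
equilibration_trend <- function(run, window = 10000L, n_blocks = 10L) {
  e <- run$energy_trace
  stopifnot(length(e) >= window)
  tailpart <- e[(length(e) - window + 1):length(e)]
  block <- rep(seq_len(n_blocks), each = window / n_blocks)[seq_len(window)]
  bm <- tapply(tailpart, block, mean)
  idx <- seq_len(n_blocks)
  fit <- summary(lm(bm ~ idx))
  slope <- fit$coefficients[2, 1] / (window / n_blocks)
  p <- fit$coefficients[2, 4]
  list(slope = slope, p_value = p, equilibrated = p > 0.01)
}

#' Simulate an ensemble of polymer conformations
#'
#' Independent seeded Monte Carlo runs (seeds `base_seed + run index`), one
#' final conformation per run. For each conformation the A/B polarization
#' index is computed along with a label-randomized control (compartment
#' labels permuted across monomers, group sizes preserved), and per-monomer
#' chromosome-surface ratios are accumulated across the ensemble together
#' with the Pearson correlation between compartment score and surface ratio,
#' separately for A and B monomers.
#'
#' @param scores per-monomer compartment scores (both signs must occur).
#' @param params an [energy_params()] list or preset name.
#' @param n_runs,n_accepted ensemble size and accepted moves per run.
#' @param base_seed base RNG seed.
#' @param sign_mode see [lattice_energy()].
#' @return A `polymer_ensemble`: list with `conformations` (long tibble),
#'   `pi` (tibble run, pi_obs, pi_ctrl), `surface` (tibble monomer, score,
#'   compartment, surface_ratio), `correlations` (from
#'   [score_ratio_correlation()]), `p_value` (rank-sum observed vs control),
#'   `params`, `seeds`.
#' @export
simulate_ensemble <- function(scores, params = "full", n_runs = 100L,
                              n_accepted = 60000L, base_seed = 1L,
                              sign_mode = c("attractive", "as_printed")) {
  sign_mode <- match.arg(sign_mode)
  if (is.character(params)) params <- energy_params(params)
  scores <- as.numeric(scores)
  n <- length(scores)
  labA <- scores > 0
  if (!any(labA) || !any(!labA))
    stop("scores must define both compartments (positive and non-positive)")
  seeds <- base_seed + seq_len(n_runs)
  runs <- purrr::map(seq_len(n_runs), function(i) {
    mc_run(scores, params, n_accepted, seed = seeds[i], sign_mode = sign_mode)
  })
  surf_hits <- matrix(FALSE, n_runs, n)
  pi_obs <- rep(NA_real_, n_runs)
  pi_ctrl <- rep(NA_real_, n_runs)
  for (i in seq_len(n_runs)) {
    conf <- runs[[i]]$conformation
    h <- cpp_convhull(matrix(as.double(conf), n, 3))
    if (h$ok) surf_hits[i, h$vertices] <- TRUE else surf_hits[i, ] <- TRUE
    pi_obs[i] <- safe_pi(conf[labA, , drop = FALSE], conf[!labA, , drop = FALSE])
    perm <- with_seed(seeds[i] + 1000000L, sample(labA))
    stopifnot(sum(perm) == sum(labA)) # control preserves group sizes
    pi_ctrl[i] <- safe_pi(conf[perm, , drop = FALSE],
                          conf[!perm, , drop = FALSE])
  }
  surface <- tibble::tibble(monomer = seq_len(n), score = scores,
                            compartment = ifelse(labA, "A", "B"),
                            surface_ratio = colMeans(surf_hits))
  correlations <- score_ratio_correlation(scores, surface$surface_ratio,
                                          split_by_sign = TRUE)
  p_value <- suppressWarnings(
    wilcox.test(pi_obs[!is.na(pi_obs)], pi_ctrl[!is.na(pi_ctrl)])$p.value)
  confs <- purrr::imap(runs, function(r, i) {
    tibble::tibble(run = i, monomer = seq_len(n),
                   x = r$conformation[, 1], y = r$conformation[, 2],
                   z = r$conformation[, 3])
  }) |> dplyr::bind_rows()
  structure(list(conformations = confs,
                 pi = tibble::tibble(run = seq_len(n_runs), pi_obs = pi_obs,
                                     pi_ctrl = pi_ctrl),
                 surface = surface, correlations = correlations,
                 p_value = p_value, params = params, seeds = seeds,
                 sign_mode = sign_mode,
                 energy_traces = lapply(runs, `[[`, "energy_trace")),
            class = "polymer_ensemble")
}

#' @export
print.polymer_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<polymer_ensemble> preset %s: %d runs, median PI %.2f (control %.2f), rank-sum p = %.3g\n",
              x$params$preset %||% "custom", nrow(x$pi), g$median_pi,
              g$median_pi_control, x$p_value))
  invisible(x)
}

#' Tidy per-run polarization indices of an ensemble
#' @param x a `polymer_ensemble`.
#' @param ... unused.
#' @export
tidy.polymer_ensemble <- function(x, ...) {
  tidyr::pivot_longer(x$pi, c("pi_obs", "pi_ctrl"), names_to = "group",
                      values_to = "pi") |>
    dplyr::mutate(group = ifelse(.data$group == "pi_obs", "observed",
                                 "control"))
}

#' One-row ensemble summary
#' @param x a `polymer_ensemble`.
#' @param ... unused.
#' @export
glance.polymer_ensemble <- function(x, ...) {
  corr <- function(sub) {
    r <- x$correlations$r[x$correlations$subset == sub]
    if (length(r) == 0) NA_real_ else r
  }
  tibble::tibble(
    n_runs = nrow(x$pi),
    median_pi = median(x$pi$pi_obs, na.rm = TRUE),
    median_pi_control = median(x$pi$pi_ctrl, na.rm = TRUE),
    rank_sum_p = x$p_value,
    r_score_surface_a = corr("A"),
    r_score_surface_b = corr("B"),
    preset = x$params$preset %||% "custom")
}
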