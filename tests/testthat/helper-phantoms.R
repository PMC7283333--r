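# Shared fixtures, all generated in code under fixed seeds.

unit_cube <- function(shift = c(0, 0, 0)) {
  m <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  storage.mode(m) <- "double"
  sweep(m, 2, shift, "+")
}

unit_tetrahedron <- function(shift = c(0, 0, 0)) {
  sweep(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 2, shift, "+")
}

# deterministic rotation matrix
rotation_3d <- function(ax = 0.4, ay = 1.1, az = -0.7) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

# brute-force pairwise Hamming distance oracle for bitstrings
hamming_oracle <- function(words) {
  bits <- t(vapply(words, function(w) as.integer(strsplit(w, "")[[1]]),
                   integer(nchar(words[1]))))
  n <- nrow(bits)
  out <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- sum(bits[i, ] != bits[j, ])
  out
}

# plain-R reference for the printed lattice energy (independent of the C++
# incremental bookkeeping): brute-force pair loop + hull from the exported
# geometry engine
reference_printed_energy <- function(conf, scores, params) {
  n <- nrow(conf)
  labA <- scores > 0
  e <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      if (labA[i] != labA[j]) next
      if (sum((conf[i, ] - conf[j, ])^2) >= 4) next
      e <- e + (if (labA[i]) params$g_aa else params$g_bb) *
        scores[i] * scores[j]
    }
  if (params$g_as != 0 || params$g_bs != 0) {
    h <- convex_hull_3d(conf)
    surf <- if (h$ok) h$vertices else seq_len(n)
    sbarA <- mean(scores[labA]); sbarB <- mean(scores[!labA])
    for (m in surf) {
      e <- e + if (labA[m]) params$g_as * (scores[m] - sbarA)
               else params$g_bs * (sbarB - scores[m])
    }
  }
  e
}

# plain-R reference Metropolis chain for the constraint-only (g = 0) polymer;
# independent implementation used for the detailed-balance cross-check
reference_constraint_chain <- function(n, n_accepted, seed) {
  set.seed(seed)
  conf <- init_conformation(n, seed = seed + 1)
  occ <- new.env(hash = TRUE)
  key <- function(p) paste(p, collapse = ",")
  for (i in seq_len(n)) assign(key(conf[i, ]), TRUE, envir = occ)
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  acc <- 0L
  while (acc < n_accepted) {
    k <- sample.int(n, 1)
    p_new <- conf[k, ] + steps[sample.int(6, 1), ]
    if (exists(key(p_new), envir = occ, inherits = FALSE)) next
    ok <- TRUE
    for (j in c(k - 1, k + 1)) {
      if (j < 1 || j > n) next
      sq <- sum((p_new - conf[j, ])^2)
      if (sq < 1 || sq > 16) { ok <- FALSE; break }
    }
    if (!ok) next
    rm(list = key(conf[k, ]), envir = occ)
    assign(key(p_new), TRUE, envir = occ)
    conf[k, ] <- p_new
    acc <- acc + 1L
  }
  conf
}

end_to_end <- function(conf) sqrt(sum((conf[nrow(conf), ] - conf[1, ])^2))
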