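# Shared fixtures: small phantoms keep the suite fast while exercising the
# same code paths as full-size volumes.

small_config <- function(..., grid_shape = c(24, 24, 16), lumen_radius = 3,
                         noise_sigma = 0) {
  phantom_config(grid_shape = grid_shape, lumen_radius = lumen_radius,
                 noise_sigma = noise_sigma, ...)
}

# Narrowing gives the tube axial structure, which breaks the axial
# degeneracy of a perfectly uniform cylinder under translation.
narrowed_config <- function(..., plaque_narrowing = c(R1 = 0.3, R2 = 0.3,
                                                      R3 = 0.15, R5 = 0.05)) {
  small_config(..., plaque_narrowing = plaque_narrowing)
}

# Independent exhaustive NCC search (triple loop, stats::cor), used as the
# registration oracle.
oracle_best_shift <- function(a, b, radius) {
  d <- dim(a)
  best <- NULL
  for (dz in -radius:radius) for (dy in -radius:radius)
    for (dx in -radius:radius) {
      s <- c(dx, dy, dz)
      ia <- lapply(1:3, function(ax)
        max(1, 1 + s[ax]):min(d[ax], d[ax] + s[ax]))
      if (any(vapply(ia, length, 1L) < 2)) next
      va <- as.numeric(a[ia[[1]], ia[[2]], ia[[3]]])
      vb <- as.numeric(b[ia[[1]] - s[1], ia[[2]] - s[2], ia[[3]] - s[3]])
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
      ncc <- stats::cor(va, vb)
      if (is.null(best) || ncc > best$ncc + 1e-12) best <- list(s = s, ncc = ncc)
    }
  best
}

# Independent integer translation (used to fabricate misaligned scans).
oracle_translate <- function(x, s, fill) {
  d <- dim(x)
  out <- array(fill, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- i - s[1]; jj <- j - s[2]; kk <- k - s[3]
    if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
        kk >= 1 && kk <= d[3])
      out[i, j, k] <- x[ii, jj, kk]
  }
  out
}

# Brute-force Otsu on the raw values (no histogram binning): evaluates the
# between-class variance at every midpoint between consecutive distinct
# values.
oracle_otsu <- function(v) {
  u <- sort(unique(v))
  cands <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cands, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    length(lo) / length(v) * length(hi) / length(v) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  tied <- which(bcv >= max(bcv) * (1 - 1e-12))
  cands[tied[(length(tied) + 1) %/% 2]]
}

random_landmark_tuple <- function(n_slices) {
  repeat {
    x <- sort(sample(0:(n_slices - 1), 4))
    lm <- tryCatch(landmarks(x[1], x[2], x[3], x[4]), error = function(e) NULL)
    if (!is.null(lm) && (lm$cuff_proximal - lm$branch) >= 3) return(lm)
  }
}
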