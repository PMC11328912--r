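# Independent oracles and small fixture builders shared across the suite.

# brute-force FFCF oracle: full outer-product matrix, superdiagonal means over
# valid pairs -- a different computational path from the package estimator
ffcf_oracle <- function(omega, dt_fs, max_lag_ps) {
  valid <- is.finite(omega)
  mu <- mean(omega[valid])
  dw <- ifelse(valid, omega - mu, NA_real_)
  n <- length(omega)
  dt_ps <- dt_fs / 1000
  kmax <- as.integer(floor(max_lag_ps / dt_ps + 1e-9))
  M <- outer(dw, dw)
  C <- numeric(kmax + 1)
  np <- numeric(kmax + 1)
  for (k in 0:kmax) {
    i <- seq_len(n - k)
    vals <- M[cbind(i, i + k)]
    ok <- !is.na(vals)
    np[k + 1] <- sum(ok)
    C[k + 1] <- if (any(ok)) mean(vals[ok]) else NA_real_
  }
  list(C = C, n_pairs = np)
}

# brute-force minimum-image shell membership: all-pairs distances with
# explicit loops over the 27 neighbour images
shell_oracle <- function(frame, topology, cutoff) {
  sol <- frame$coords[vibsolv::solute_atoms(topology) + 1L, , drop = FALSE]
  box <- frame$box
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  included <- integer(0)
  for (mi in seq_along(topology$molecules)) {
    if (mi - 1L == topology$solute_molecule) next
    xyz <- frame$coords[topology$molecules[[mi]] + 1L, , drop = FALSE]
    hit <- FALSE
    for (a in seq_len(nrow(xyz))) {
      for (s in seq_len(nrow(shifts))) {
        p <- xyz[a, ] + if (is.null(box)) c(0, 0, 0) else shifts[s, ] * box
        d <- sqrt(rowSums(sweep(sol, 2, p)^2))
        if (any(d < cutoff)) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) included <- c(included, mi - 1L)
  }
  included
}

# closed-form OLS/Pearson oracle from the explicit sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); syy <- sum(y^2)
  sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

# direct projected-field summation, written independently of the package:
# explicit per-charge loop in spherical terms
field_oracle <- function(charge_pos, charges, rC, rO) {
  u <- (rO - rC) / sqrt(sum((rO - rC)^2))
  m <- (rC + rO) / 2
  e <- 0
  for (i in seq_len(nrow(charge_pos))) {
    rel <- charge_pos[i, ] - m
    r <- sqrt(sum(rel^2))
    cos_th <- sum(rel * u) / r
    e <- e + 14.3996 * charges[i] * cos_th / r^2
  }
  e
}

# tag an arbitrary lag/C data frame as an FFCF curve for fit_kubo
as_ffcf <- function(lag_ps, C_cm2, dt_ps = diff(lag_ps[1:2]),
                    span_ps = 2 * max(lag_ps)) {
  out <- data.frame(lag_ps = lag_ps, C_cm2 = C_cm2,
                    n_pairs = rep(1, length(lag_ps)))
  attr(out, "dt_ps") <- dt_ps
  attr(out, "span_ps") <- span_ps
  class(out) <- c("vib_ffcf", "data.frame")
  out
}

# tiny 3-molecule periodic test frame: 2-atom solute at the box center plus
# three single-site solvent molecules at controllable minimum-image distances
tiny_system <- function(solvent_offsets_A = c(3, 5, 9), box = 20) {
  ctr <- box / 2
  coords <- rbind(c(ctr - 0.6, ctr, ctr), c(ctr + 0.6, ctr, ctr))
  syms <- c("C", "O")
  for (d in solvent_offsets_A) {
    coords <- rbind(coords, c(ctr + 0.6 + d, ctr, ctr))
    syms <- c(syms, "Ar")
  }
  ns <- length(solvent_offsets_A)
  top <- new_topology(
    elements = syms,
    molecules = c(list(0:1), lapply(seq_len(ns), function(i) 1L + i)),
    solute_molecule = 0L, probe_atoms = list(C = 0L, O = 1L),
    charges = c(0, 0, rep(0.2, ns)))
  frame <- new_frame(syms, coords, index = 0L, time_fs = 0,
                     box = rep(box, 3))
  list(frame = frame, topology = top)
}

# random valid multi-frame XYZ content for round-trip property tests
random_series <- function(n_frames, n_atoms, seed, box = NULL) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames) - 1L, function(i) {
    new_frame(sample(c("C", "O", "N", "H"), n_atoms, replace = TRUE),
              matrix(round(runif(n_atoms * 3, -20, 20), 6), n_atoms, 3),
              index = i, time_fs = i * 50, box = box)
  })
  new_frame_series(frames, dt_fs = 50)
}
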