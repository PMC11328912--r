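#' @title Synthetic frequency trajectories and fixture trajectories
#'
#' @description
#' Two generators validate the analysis machinery.
#'
#' * [simulate_ou()] draws an Ornstein-Uhlenbeck frequency trajectory with
#'   prescribed fluctuation amplitude `Delta` and correlation time `tau` using
#'   the **exact discretization**
#'   `dw[k+1] = a dw[k] + Delta sqrt(1 - a^2) xi[k]`, `a = exp(-dt/tau)`, with
#'   `dw[0] ~ N(0, Delta^2)`. The update is distributionally exact for any
#'   step size (no Euler bias), so its FFCF is exactly
#'   `Delta^2 exp(-t/tau)` in expectation and its marginal is Gaussian with
#'   standard deviation `Delta` — the Kubo model the analysis fits.
#' * [generate_fixture_trajectory()] builds a toy solute-in-point-charge
#'   solvent trajectory: a rigid 4-atom solute with a defined C=O axis fixed
#'   at the box center, surrounded by neutral two-site charge dumbbells
#'   (+q/-q, 1 Å apart) performing reflected Gaussian random walks. Its
#'   stub-engine frequencies fluctuate with solvent motion, giving an
#'   end-to-end test bed for carve -> engine -> FFCF with no external
#'   software.
#'
#' One user seed feeds independent sub-streams (initial value / noise;
#' placement / orientations / walks) so components stay independent and runs
#' are bit-reproducible.
#'
#' @name kubo-simulator
NULL

#' Simulate an Ornstein-Uhlenbeck frequency trajectory
#'
#' @param delta fluctuation amplitude `Delta` in cm^-1 (>= 0).
#' @param tau_ps correlation time in ps (> 0).
#' @param dt_fs sampling interval in fs.
#' @param n_steps number of samples (>= 2).
#' @param omega0 mean frequency in cm^-1.
#' @param seed integer seed; the same seed reproduces the trajectory exactly.
#' @return a `vib_freq_traj`.
#' @export
simulate_ou <- function(delta, tau_ps, dt_fs, n_steps, omega0 = 1700,
                        seed = 1) {
  if (delta < 0) vib_stop("delta must be >= 0", "vib_invalid_spec")
  if (tau_ps <= 0) vib_stop("tau_ps must be > 0", "vib_invalid_spec")
  if (n_steps < 2) vib_stop("n_steps must be >= 2", "vib_invalid_spec")
  a <- exp(-fs_to_ps(dt_fs) / tau_ps)
  set.seed(derive_seed(seed, 1L))
  dw <- numeric(n_steps)
  dw[1] <- stats::rnorm(1, 0, delta)
  if (n_steps > 1 && delta > 0) {
    xi <- stats::rnorm(n_steps - 1)
    sig <- delta * sqrt(1 - a^2)
    for (k in seq_len(n_steps - 1)) dw[k + 1] <- dw[k] * a + sig * xi[k]
  }
  new_frequency_trajectory(omega0 + dw, dt_fs = dt_fs)
}

#' Simulate a sum of independent OU components
#'
#' `omega(t) = omega0 + sum_i dw_i(t)` with the components drawn
#' independently; the resulting FFCF is the sum of the component FFCFs,
#' `sum_i Delta_i^2 exp(-t/tau_i)` — the multi-component Kubo target.
#'
#' @param specs list of component specs, each a list/row with `delta`,
#'   `tau_ps` and `seed`; all components share `dt_fs` and `n_steps`.
#' @param dt_fs shared sampling interval in fs.
#' @param n_steps shared sample count.
#' @param omega0 mean frequency in cm^-1.
#' @return a `vib_freq_traj`.
#' @export
simulate_multicomponent <- function(specs, dt_fs, n_steps, omega0 = 1700) {
  seeds <- vapply(specs, function(s) as.integer(s$seed), integer(1))
  if (anyDuplicated(seeds))
    vib_stop("component seeds must be distinct (independence violated)",
             "vib_invalid_spec")
  dw <- numeric(n_steps)
  for (s in specs) {
    tr <- simulate_ou(s$delta, s$tau_ps, dt_fs, n_steps, omega0 = 0,
                      seed = s$seed)
    dw <- dw + tr$omega
  }
  new_frequency_trajectory(omega0 + dw, dt_fs = dt_fs)
}

#' Fixture-trajectory specification
#'
#' Defaults describe the standard test bed: 50 charge dumbbells in a 20 Å
#' box, 2000 frames at 50 fs, site charge 0.25 e and a 0.2 Å per-frame walk
#' step (liquid-like displacement at this cadence).
#'
#' @param n_solvent number of solvent dumbbells (>= 0; 0 gives the zero-field
#'   control).
#' @param box_A orthorhombic box edge in Å.
#' @param charge_e site charge magnitude in e (sites carry +q and -q).
#' @param step_A per-coordinate standard deviation of the Gaussian walk step,
#'   Å per frame.
#' @param n_frames number of frames.
#' @param dt_fs frame interval in fs.
#' @param seed integer seed.
#' @return a list of class `"vib_fixture_spec"`.
#' @export
fixture_spec <- function(n_solvent = 50, box_A = 20, charge_e = 0.25,
                         step_A = 0.2, n_frames = 2000, dt_fs = 50,
                         seed = 1) {
  if (box_A <= 0) vib_stop("box must be positive", "vib_invalid_spec")
  if (n_solvent < 0) vib_stop("n_solvent must be >= 0", "vib_invalid_spec")
  structure(list(n_solvent = as.integer(n_solvent), box_A = box_A,
                 charge_e = charge_e, step_A = step_A,
                 n_frames = as.integer(n_frames), dt_fs = dt_fs,
                 seed = as.integer(seed)),
            class = "vib_fixture_spec")
}

#' Generate a toy solute-in-point-charge-solvent trajectory
#'
#' A rigid 4-atom solute (probe C and O on the x axis, C=O bond 1.21 Å, plus
#' two carrier atoms) sits fixed at the box center. Each solvent molecule is
#' a neutral dumbbell of two sites (+q, -q) 1 Å apart with a random fixed
#' orientation; dumbbell centers perform independent Gaussian random walks
#' reflected at the box walls. Initial placements that clash (site-site
#' distance < 1.5 Å, or < 2.5 Å to a solute atom) are re-sampled up to 100
#' times per molecule, then an error is raised.
#'
#' @param spec a `vib_fixture_spec`.
#' @return a list with `series` (a `vib_frame_series`) and `topology`
#'   (a `vib_topology` with charges and probe atoms; solute atoms carry zero
#'   charge).
#' @export
generate_fixture_trajectory <- function(spec = fixture_spec()) {
  b <- spec$box_A
  center <- rep(b / 2, 3)
  # rigid solute: C, O (the probe C=O along +x), two carriers
  sol_xyz <- rbind(
    C = center + c(-0.605, 0, 0),
    O = center + c(0.605, 0, 0),
    C2 = center + c(-1.55, -1.05, 0),
    N = center + c(-1.45, 1.10, 0))
  sol_sym <- c("C", "O", "C", "N")
  ns <- spec$n_solvent

  set.seed(derive_seed(spec$seed, 2L))  # placement + orientations
  centers <- matrix(NA_real_, ns, 3)
  axes <- matrix(NA_real_, ns, 3)
  site_of <- function(ctr, ax) rbind(ctr + 0.5 * ax, ctr - 0.5 * ax)
  placed_sites <- sol_xyz
  for (i in seq_len(ns)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      ctr <- stats::runif(3, 0.5, b - 0.5)
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      st <- site_of(ctr, ax)
      dmin_solute <- min(sqrt(rowSums(
        (placed_sites[rep(1:4, each = 2), ] -
           st[rep(1:2, times = 4), ])^2)))
      ok_solv <- TRUE
      if (i > 1) {
        prev <- do.call(rbind, lapply(seq_len(i - 1), function(j)
          site_of(centers[j, ], axes[j, ])))
        dd <- sqrt(outer(rowSums(st^2), rowSums(prev^2), `+`) -
                     2 * st %*% t(prev))
        ok_solv <- min(dd) >= 1.5
      }
      if (dmin_solute >= 2.5 && ok_solv) { ok <- TRUE; break }
    }
    if (!ok)
      vib_stop(sprintf(
        "could not place solvent molecule %d without overlap after 100 tries",
        i - 1L), "vib_placement_failure")
    centers[i, ] <- ctr
    axes[i, ] <- ax
  }

  # reflected Gaussian random walks of the dumbbell centers
  set.seed(derive_seed(spec$seed, 3L))
  reflect <- function(x, lo, hi) {
    # fold into [lo, hi] by reflection
    w <- hi - lo
    y <- (x - lo) %% (2 * w)
    lo + ifelse(y > w, 2 * w - y, y)
  }
  frames <- vector("list", spec$n_frames)
  cur <- centers
  sites_of_state <- function(ctrs) {
    if (ns == 0) return(matrix(numeric(0), 0, 3))
    out <- matrix(NA_real_, 2 * ns, 3)
    for (i in seq_len(ns))
      out[(2 * i - 1):(2 * i), ] <- site_of(ctrs[i, ], axes[i, ])
    out
  }
  solv_xyz <- sites_of_state(cur)
  for (f in seq_len(spec$n_frames)) {
    if (f > 1 && ns > 0) {
      # sequential excluded-volume update: a molecule keeps its position when
      # the proposed step would bring a site within 1 Å of another solvent
      # site or 2 Å of a solute atom (the downstream clash guard is 0.5 Å)
      steps <- matrix(stats::rnorm(ns * 3, 0, spec$step_A), ns, 3)
      for (i in seq_len(ns)) {
        prop <- reflect(cur[i, ] + steps[i, ], 0.5, b - 0.5)
        st <- site_of(prop, axes[i, ])
        others <- solv_xyz[-c(2 * i - 1, 2 * i), , drop = FALSE]
        ref <- rbind(sol_xyz, others)
        d2 <- outer(rowSums(st^2), rowSums(ref^2), `+`) - 2 * st %*% t(ref)
        dmin_sol <- sqrt(max(min(d2[, 1:4]), 0))
        dmin_env <- if (nrow(ref) > 4)
          sqrt(max(min(d2[, -(1:4)]), 0)) else Inf
        if (dmin_sol >= 2.0 && dmin_env >= 1.0) {
          cur[i, ] <- prop
          solv_xyz[(2 * i - 1):(2 * i), ] <- st
        }
      }
    }
    if (ns > 0) {
      coords <- rbind(sol_xyz, solv_xyz)
      syms <- c(sol_sym, rep(c("Na", "Cl"), ns))
    } else {
      coords <- sol_xyz
      syms <- sol_sym
    }
    frames[[f]] <- new_frame(syms, coords, index = f - 1L,
                             time_fs = (f - 1) * spec$dt_fs,
                             box = rep(b, 3))
  }

  molecules <- c(list(0:3),
                 if (ns > 0) lapply(seq_len(ns), function(i)
                   c(4L + 2L * (i - 1L), 5L + 2L * (i - 1L))))
  charges <- c(rep(0, 4), rep(c(spec$charge_e, -spec$charge_e), ns))
  topology <- new_topology(
    elements = c(sol_sym, rep(c("Na", "Cl"), ns)),
    molecules = molecules, solute_molecule = 0L,
    probe_atoms = list(C = 0L, O = 1L),
    charges = charges)
  list(series = new_frame_series(frames, dt_fs = spec$dt_fs,
                                 topology = topology),
       topology = topology)
}

#' Write a frame series as a multi-frame extended XYZ file
#'
#' Full-precision coordinates and `time=`/`box=`/`frame=` comment tokens, so
#' written fixtures are byte-identical for a fixed seed and spec and round
#' trips are bit-exact.
#'
#' @param series a `vib_frame_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(series, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in series$frames) {
    n <- length(f$symbols)
    comment <- sprintf("frame=%d time=%s", f$index, fmt_full(f$time_fs))
    if (!is.null(f$box))
      comment <- paste0(comment, sprintf(" box=%s,%s,%s",
                                         fmt_full(f$box[1]),
                                         fmt_full(f$box[2]),
                                         fmt_full(f$box[3])))
    atom_lines <- sprintf("%-3s %s %s %s", f$symbols,
                          fmt_full(f$coords[, 1]), fmt_full(f$coords[, 2]),
                          fmt_full(f$coords[, 3]))
    writeLines(c(as.character(n), comment, atom_lines), con, sep = "\n")
  }
  invisible(path)
}
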