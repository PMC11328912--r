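#' @title Frequency engines: external GFN2-xTB adapter and electrostatic-map stub
#'
#' @description
#' Per-cluster normal modes come from one of two engines.
#'
#' * **External GFN2-xTB**: [prepare_engine_job()] writes the cluster
#'   geometry, a `$fix` constraint file freezing every environment atom
#'   (xtb's 1-based dialect) and the exact command lines for a constrained
#'   optimization followed by a Hessian; it never executes the engine itself.
#'   [parse_engine_frequencies()] reads the documented vibrational output
#'   files — the Gaussian-98-style `g98.out` (frequencies, IR intensities and
#'   displacement vectors) or the Turbomole-style `vibspectrum` (frequencies
#'   and intensities only) — plus the run log for the convergence flag.
#' * **Map stub**: [map_engine_frequencies()] is a deterministic one-parameter
#'   Stark map. It returns a single mode at
#'   `omega = omega0 + stark_slope * E_par`, where `E_par` is the Coulomb
#'   field of all environment point charges evaluated at the C=O midpoint and
#'   projected on the C->O axis (V/Å; positive when a positive charge lies on
#'   the O side of the midpoint). It exists so the full pipeline — carving,
#'   assignment, FFCF — runs deterministically without external software.
#'
#' Negative frequencies encode imaginary modes; they are parsed, flagged and
#' excluded from amide-I assignment. Parsed displacement vectors are
#' renormalized to unit Euclidean norm over all atoms (xtb's g98 output is not
#' normalized).
#'
#' @name qm-engines
NULL

#' Construct a normal mode
#'
#' @param frequency frequency in cm^-1; negative values encode imaginary
#'   modes.
#' @param ir_intensity IR intensity in km/mol, >= 0.
#' @param displacement optional N x 3 per-atom Cartesian displacement matrix;
#'   renormalized to unit norm over all atoms.
#' @return an object of class `"vib_mode"`.
#' @export
new_mode <- function(frequency, ir_intensity, displacement = NULL) {
  if (!is.finite(ir_intensity) || ir_intensity < 0)
    vib_stop("IR intensity must be finite and non-negative",
             "vib_invalid_mode")
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    nrm <- sqrt(sum(displacement^2))
    if (nrm > 0) displacement <- displacement / nrm
  }
  structure(list(frequency = as.numeric(frequency),
                 ir_intensity = as.numeric(ir_intensity),
                 displacement = displacement,
                 imaginary = frequency < 0),
            class = "vib_mode")
}

#' Construct a frequency-job result
#'
#' @param modes list of `vib_mode`, stored sorted by frequency (ascending).
#' @param converged logical convergence flag (NA if the run log was absent).
#' @param engine engine name + version string.
#' @param cluster the source `vib_cluster` (provenance), or `NULL` when the
#'   geometry could not be recovered.
#' @return an object of class `"vib_freq_result"`.
#' @export
new_freq_result <- function(modes, converged, engine, cluster = NULL) {
  if (length(modes) == 0)
    vib_stop("a frequency result must contain at least one mode",
             "vib_parse_error")
  ord <- order(vapply(modes, function(m) m$frequency, numeric(1)))
  structure(list(modes = modes[ord], converged = converged,
                 engine = engine, cluster = cluster),
            class = "vib_freq_result")
}

#' @export
print.vib_freq_result <- function(x, ...) {
  freqs <- vapply(x$modes, function(m) m$frequency, numeric(1))
  cat(sprintf("<vib_freq_result: %d modes (%d imaginary), engine %s, converged: %s>\n",
              length(freqs), sum(freqs < 0), x$engine, format(x$converged)))
  invisible(x)
}

#' Prepare an external-engine job directory for one cluster
#'
#' Writes `cluster.xyz`, a constraint file `xtb.inp` with a `$fix` block
#' listing every frozen atom in xtb's **1-based** dialect, and `run_commands.txt`
#' with the exact command lines (constrained optimization, then Hessian).
#' Nothing is executed.
#'
#' @param cluster a `vib_cluster`.
#' @param workdir directory to create/populate.
#' @param overwrite allow writing into a non-empty existing directory.
#' @return invisibly, a list with the paths written and the command lines.
#' @export
prepare_engine_job <- function(cluster, workdir, overwrite = FALSE) {
  if (all(cluster$frozen_mask))
    vib_stop("nothing to optimize: every atom in the cluster is frozen",
             "vib_invalid_job")
  if (dir.exists(workdir) && length(list.files(workdir)) > 0 && !overwrite)
    vib_stop(sprintf("workdir '%s' exists and is not empty (use overwrite)",
                     workdir), "vib_workdir_collision")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  geom <- file.path(workdir, "cluster.xyz")
  write_cluster_xyz(cluster, geom)
  frozen1 <- which(cluster$frozen_mask)       # xtb atom lists are 1-based
  inp <- file.path(workdir, "xtb.inp")
  if (length(frozen1) > 0) {
    writeLines(c("$fix",
                 sprintf("   atoms: %s", compress_ranges(frozen1)),
                 "$end"), inp)
  } else {
    writeLines(c("$fix", "$end"), inp)
  }
  cmds <- c("xtb cluster.xyz --input xtb.inp --opt tight > xtb_opt.out",
            "xtb xtbopt.xyz --input xtb.inp --hess > xtb_hess.out")
  writeLines(cmds, file.path(workdir, "run_commands.txt"))
  invisible(list(geometry = geom, constraints = inp, commands = cmds))
}

# parse a Gaussian-98-style frequency block file (the dialect xtb writes as
# g98.out): blocks of up to 3 modes with 'Frequencies --', 'IR Inten    --'
# and an 'Atom AN  X Y Z ...' displacement table
parse_g98 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  freq_rows <- grep("Frequencies\\s*--", lines)
  if (length(freq_rows) == 0) return(list())
  modes <- list()
  for (fr in freq_rows) {
    freqs <- as.numeric(strsplit(trimws(sub(".*Frequencies\\s*--", "",
                                            lines[fr])), "\\s+")[[1]])
    # find the IR intensity line within this block
    blk_end <- min(c(freq_rows[freq_rows > fr], length(lines) + 1L))
    blk <- lines[fr:(blk_end - 1L)]
    ir_row <- grep("IR Inten\\s*--", blk)
    ints <- if (length(ir_row))
      as.numeric(strsplit(trimws(sub(".*IR Inten\\s*--", "",
                                     blk[ir_row[1]])), "\\s+")[[1]])
    else rep(0, length(freqs))
    # displacement table: rows after the 'Atom AN' header, columns of 3 per mode
    hdr <- grep("^\\s*Atom\\s+AN", blk)
    disp <- NULL
    if (length(hdr)) {
      rows <- character(0)
      i <- hdr[1] + 1L
      while (i <= length(blk) &&
             grepl("^\\s*\\d+\\s+\\d+(\\s+-?\\d*\\.?\\d+([eE][+-]?\\d+)?)+\\s*$",
                   blk[i])) {
        rows <- c(rows, blk[i]); i <- i + 1L
      }
      if (length(rows)) {
        vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
        m <- do.call(rbind, vals)[, -(1:2), drop = FALSE]
        if (ncol(m) >= 3 * length(freqs)) {
          disp <- lapply(seq_along(freqs), function(k)
            m[, (3 * k - 2):(3 * k), drop = FALSE])
        }
      }
    }
    for (k in seq_along(freqs)) {
      if (!is.finite(freqs[k])) next
      modes[[length(modes) + 1L]] <- new_mode(
        frequency = freqs[k],
        ir_intensity = if (k <= length(ints) && is.finite(ints[k]))
          ints[k] else 0,
        displacement = if (!is.null(disp)) disp[[k]] else NULL)
    }
  }
  modes
}

# parse a Turbomole-style vibspectrum file (frequencies + IR intensities,
# no displacement vectors)
parse_vibspectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("\\$vibrational spectrum", lines)
  if (length(start) == 0)
    vib_stop(sprintf("'%s' is not a vibspectrum file", path),
             "vib_parse_error")
  end <- grep("^\\$end", lines)
  end <- if (length(end)) end[end > start[1]][1] else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  modes <- list()
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 3) next
    nums <- suppressWarnings(as.numeric(toks))
    # first token is the mode counter; an optional symmetry label follows;
    # the next two numeric tokens are wavenumber and intensity
    numeric_after <- which(!is.na(nums))
    numeric_after <- numeric_after[numeric_after > 1]
    if (length(numeric_after) < 2) next
    freq <- nums[numeric_after[1]]
    inten <- nums[numeric_after[2]]
    modes[[length(modes) + 1L]] <- new_mode(freq, max(inten, 0))
  }
  modes
}

#' Parse the vibrational output of an external engine run
#'
#' Looks in `workdir` for `g98.out` (preferred: carries displacement vectors)
#' or `vibspectrum`. The convergence flag is read from any `*.out`/`*.log`
#' run log containing xtb's convergence banner; it is `NA` when no log is
#' found. If an optimized geometry (`xtbopt.xyz`) or the prepared
#' `cluster.xyz` is present it is attached as provenance.
#'
#' @param workdir the job directory.
#' @param engine engine label recorded in the result.
#' @return a `vib_freq_result` with modes sorted by frequency.
#' @export
parse_engine_frequencies <- function(workdir, engine = "xtb") {
  g98 <- file.path(workdir, "g98.out")
  vsp <- file.path(workdir, "vibspectrum")
  if (file.exists(g98)) {
    modes <- parse_g98(g98)
  } else if (file.exists(vsp)) {
    modes <- parse_vibspectrum(vsp)
  } else {
    vib_stop(sprintf(
      "no vibrational output found in '%s' (expected g98.out or vibspectrum)",
      workdir), "vib_parse_error")
  }
  if (length(modes) == 0)
    vib_stop(sprintf("zero modes parsed from vibrational output in '%s'",
                     workdir), "vib_parse_error")
  converged <- NA
  logs <- list.files(workdir, pattern = "\\.(out|log)$", full.names = TRUE)
  logs <- setdiff(logs, g98)
  for (lg in logs) {
    txt <- readLines(lg, warn = FALSE)
    if (any(grepl("GEOMETRY OPTIMIZATION CONVERGED", txt, fixed = TRUE))) {
      converged <- TRUE; break
    }
    if (any(grepl("FAILED TO CONVERGE", txt, fixed = TRUE))) {
      converged <- FALSE; break
    }
  }
  cluster <- NULL
  for (cand in file.path(workdir, c("xtbopt.xyz", "cluster.xyz"))) {
    if (file.exists(cand)) {
      cluster <- tryCatch(read_cluster_xyz(cand), error = function(e) NULL)
      if (!is.null(cluster)) break
    }
  }
  new_freq_result(modes, converged = converged,
                  engine = engine, cluster = cluster)
}

#' Serialize a frequency result in the g98-style fixture dialect
#'
#' Writes the same block layout [parse_engine_frequencies()] reads, with
#' high-precision fields so that serialize-then-parse round trips are
#' lossless. Used to build test fixtures and to archive stub-engine results
#' in a format the external-engine tooling understands.
#'
#' @param result a `vib_freq_result`.
#' @param path output file path (conventionally `g98.out` in a job dir).
#' @return `path`, invisibly.
#' @export
write_g98_frequencies <- function(result, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  out <- c(" Entering Gaussian System", " vibsolv fixture dialect", "")
  modes <- result$modes
  nat <- if (!is.null(modes[[1]]$displacement)) nrow(modes[[1]]$displacement)
         else 0L
  for (b in seq_len(ceiling(length(modes) / 3))) {
    sel <- modes[(3 * b - 2):min(3 * b, length(modes))]
    out <- c(out,
      paste0("  ", paste(sprintf("%20d", seq_along(sel) + 3 * (b - 1)),
                         collapse = " ")),
      paste0("  ", paste(rep(sprintf("%20s", "A"), length(sel)),
                         collapse = " ")),
      paste0(" Frequencies --", paste(
        sprintf("%20.10f", vapply(sel, function(m) m$frequency, numeric(1))),
        collapse = " ")),
      paste0(" IR Inten    --", paste(
        sprintf("%20.10f", vapply(sel, function(m) m$ir_intensity,
                                  numeric(1))), collapse = " ")))
    if (nat > 0) {
      out <- c(out, paste0(" Atom AN", paste(
        rep("      X          Y          Z    ", length(sel)),
        collapse = "")))
      for (a in seq_len(nat)) {
        row <- sprintf("%4d %3d", a, 0L)
        for (m in sel)
          row <- paste0(row, sprintf(" %14.10f %14.10f %14.10f",
                                     m$displacement[a, 1],
                                     m$displacement[a, 2],
                                     m$displacement[a, 3]))
        out <- c(out, row)
      }
    }
    out <- c(out, "")
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Map-engine parameters
#'
#' @param omega0 gas-phase probe frequency in cm^-1 (> 0).
#' @param stark_slope Stark tuning slope in cm^-1 per (V/Å) of field projected
#'   on the C->O axis. Carbonyl stretches red-shift in fields pointing from C
#'   to O, so slopes are conventionally negative.
#' @return an object of class `"vib_map_params"`.
#' @export
map_params <- function(omega0 = 1750, stark_slope = -50) {
  if (omega0 <= 0)
    vib_stop("omega0 must be positive", "vib_invalid_params")
  structure(list(omega0 = as.numeric(omega0),
                 stark_slope = as.numeric(stark_slope)),
            class = "vib_map_params")
}

# projected Coulomb field (V/Å) of environment point charges at the C=O
# midpoint, positive toward O
projected_field <- function(cluster, topology, probe_pos) {
  env_rows <- which(cluster$frozen_mask)
  if (length(env_rows) == 0) return(0)
  if (is.null(topology$charges))
    vib_stop("map engine requires partial charges in the topology",
             "vib_missing_charges")
  q <- topology$charges[cluster$source_atoms[env_rows] + 1L]
  if (any(!is.finite(q)))
    vib_stop("missing charge for an environment atom", "vib_missing_charges")
  rC <- probe_pos$C; rO <- probe_pos$O
  u <- rO - rC
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8)
    vib_stop("zero-length C=O vector", "vib_invalid_probe")
  u <- u / nu
  m <- (rC + rO) / 2
  rel <- sweep(cluster$coords[env_rows, , drop = FALSE], 2, m)
  r2 <- rowSums(rel^2)
  proj <- rel %*% u
  vib_constants$coulomb_eVA * sum(q * proj / (r2^1.5))
}

# locate the probe C and O rows (1-based) within a cluster via source_atoms
probe_rows <- function(cluster, topology) {
  rowC <- match(topology$probe_atoms$C, cluster$source_atoms)
  rowO <- match(topology$probe_atoms$O, cluster$source_atoms)
  if (is.na(rowC) || is.na(rowO))
    vib_stop("probe atoms not found in cluster", "vib_invalid_probe")
  list(C = rowC, O = rowO)
}

#' Deterministic electrostatic-map stub engine
#'
#' Returns exactly one mode at `omega0 + stark_slope * E_par`, where `E_par`
#' is the Coulomb field of all environment (frozen) point charges at the C=O
#' midpoint projected on the unit C->O vector (Coulomb constant
#' 14.3996 eV Å / e^2; sign positive when a positive charge lies beyond O).
#' The mode has unit IR intensity and a displacement localized on C and O
#' along the bond (C moves along +C->O, O opposite), which makes the
#' amide-I assignment step exercise its projection machinery.
#'
#' The field is exactly linear in every environment charge (superposition),
#' a property the test suite verifies.
#'
#' @param cluster a `vib_cluster`.
#' @param topology the parent `vib_topology` carrying partial charges.
#' @param params a `vib_map_params`.
#' @return a `vib_freq_result` with a single mode.
#' @export
map_engine_frequencies <- function(cluster, topology, params) {
  rows <- probe_rows(cluster, topology)
  pos <- list(C = cluster$coords[rows$C, ], O = cluster$coords[rows$O, ])
  epar <- projected_field(cluster, topology, pos)
  omega <- params$omega0 + params$stark_slope * epar
  u <- pos$O - pos$C
  u <- u / sqrt(sum(u^2))
  disp <- matrix(0, length(cluster$symbols), 3)
  disp[rows$C, ] <- u
  disp[rows$O, ] <- -u
  new_freq_result(list(new_mode(omega, ir_intensity = 1,
                                displacement = disp)),
                  converged = TRUE, engine = "map-stub 1.0",
                  cluster = cluster)
}

#' Assign the amide-I mode and its intensity-weighted snapshot frequency
#'
#' Real (non-imaginary) modes inside the assignment window are scored by the
#' magnitude of the projection of their relative C/O displacement on the C->O
#' unit vector, `s = |(d_C - d_O) . u|`, normalized by the maximum over
#' in-window modes. Modes scoring at least half the maximum are candidates,
#' and the snapshot frequency is their IR-intensity-weighted average
#' frequency. When the engine output carries no displacement vectors (the
#' vibspectrum dialect) all in-window real modes score 1 and the weighting is
#' purely by intensity.
#'
#' @param result a `vib_freq_result` whose provenance cluster identifies the
#'   probe geometry.
#' @param topology the parent `vib_topology` (probe atom indices).
#' @param window_cm1 assignment window, default `c(1550, 1850)` cm^-1.
#' @param candidate_frac candidates must score at least this fraction of the
#'   maximum projection score (default 0.5).
#' @return an object of class `"vib_assignment"` with fields
#'   `omega_snap` (cm^-1), `candidates` (data frame of frequency, intensity,
#'   score, candidate flag) and `total_intensity`.
#' @export
assign_amide_I <- function(result, topology, window_cm1 = c(1550, 1850),
                           candidate_frac = 0.5) {
  freqs <- vapply(result$modes, function(m) m$frequency, numeric(1))
  in_win <- freqs > 0 & freqs >= window_cm1[1] & freqs <= window_cm1[2]
  if (!any(in_win))
    vib_stop(sprintf(
      "no real mode inside the assignment window [%g, %g] cm^-1: snapshot unusable",
      window_cm1[1], window_cm1[2]), "vib_assignment_failure")
  sel <- which(in_win)
  have_disp <- !vapply(result$modes[sel],
                       function(m) is.null(m$displacement), logical(1))
  if (all(have_disp) && !is.null(result$cluster)) {
    rows <- probe_rows(result$cluster, topology)
    u <- result$cluster$coords[rows$O, ] - result$cluster$coords[rows$C, ]
    u <- u / sqrt(sum(u^2))
    raw <- vapply(result$modes[sel], function(m) {
      abs(sum((m$displacement[rows$C, ] - m$displacement[rows$O, ]) * u))
    }, numeric(1))
    score <- if (max(raw) > 0) raw / max(raw) else rep(1, length(raw))
  } else {
    score <- rep(1, length(sel))
  }
  is_cand <- score >= candidate_frac * max(score)
  cand <- sel[is_cand]
  ints <- vapply(result$modes[cand], function(m) m$ir_intensity, numeric(1))
  nus <- freqs[cand]
  omega_snap <- if (sum(ints) > 0) sum(ints * nus) / sum(ints) else mean(nus)
  structure(list(
    omega_snap = omega_snap,
    total_intensity = sum(ints),
    candidates = data.frame(frequency = freqs[sel],
                            ir_intensity = vapply(result$modes[sel],
                              function(m) m$ir_intensity, numeric(1)),
                            score = score, candidate = is_cand),
    window_cm1 = window_cm1),
    class = "vib_assignment")
}
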