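#' @title Solvation-shell cluster extraction
#'
#' @description
#' Snapshots are sampled from a trajectory at a fixed cadence and, for each
#' snapshot, a solute-centred cluster is carved: the whole solute plus every
#' solvent molecule with at least one atom within a radial cutoff
#' (minimum-image distance) of any solute atom. Included molecules are
#' translated by whole-box vectors into the periodic image nearest the solute
#' centroid, so the carved cluster is contiguous and each molecule's internal
#' geometry is preserved exactly. All solvent atoms are marked frozen: in the
#' downstream frequency step only the solute is relaxed, which preserves the
#' distribution of environments sampled by the dynamics.
#'
#' @name shell-extraction
NULL

#' Construct and validate a carved cluster
#'
#' @param symbols element symbols.
#' @param coords N x 3 coordinate matrix in Å (already unwrapped).
#' @param solute_atoms 0-based indices of solute atoms within the cluster.
#' @param frozen_mask logical per atom; `TRUE` = held fixed during
#'   optimization. Must be `FALSE` exactly on the solute atoms.
#' @param source_frame index of the originating frame.
#' @param source_time_fs time of the originating frame in fs.
#' @param source_atoms 0-based indices of the cluster atoms in the parent
#'   frame (provenance; used to look up charges in the parent topology).
#' @param box_min optional smallest box edge of the parent frame, used for the
#'   unwrap sanity check.
#' @param check_geometry run the clash guard and extent check (default TRUE).
#' @return an object of class `"vib_cluster"`.
#' @export
new_cluster <- function(symbols, coords, solute_atoms, frozen_mask,
                        source_frame = 0L, source_time_fs = 0,
                        source_atoms = NULL, box_min = NULL,
                        check_geometry = TRUE) {
  coords <- as.matrix(coords)
  n <- length(symbols)
  if (n == 0)
    vib_stop("cluster must contain at least one atom", "vib_invalid_cluster")
  if (nrow(coords) != n)
    vib_stop("coords rows must match symbol count", "vib_invalid_cluster")
  solute_atoms <- as.integer(solute_atoms)
  if (length(solute_atoms) == 0)
    vib_stop("cluster solute atom set must be nonempty", "vib_invalid_cluster")
  frozen_mask <- as.logical(frozen_mask)
  if (length(frozen_mask) != n)
    vib_stop("frozen_mask length must match atom count", "vib_invalid_cluster")
  expected_free <- sort(solute_atoms)
  if (!identical(which(!frozen_mask) - 1L, expected_free))
    vib_stop("frozen_mask must be FALSE exactly on the solute atoms",
             "vib_invalid_cluster")
  if (is.null(source_atoms)) source_atoms <- seq_len(n) - 1L
  if (check_geometry && n > 1) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    if (min(d) < 0.5) {
      pair <- which(d == min(d), arr.ind = TRUE)[1, ]
      vib_stop(sprintf(
        "atom clash in cluster: atoms %d and %d are %.3f Å apart (< 0.5 Å)",
        min(pair) - 1L, max(pair) - 1L, min(d)), "vib_cluster_clash")
    }
    if (!is.null(box_min) && max(d[is.finite(d)]) > box_min)
      vib_stop(sprintf(
        "cluster extent %.2f Å exceeds smallest box edge %.2f Å (unwrap failure)",
        max(d[is.finite(d)]), box_min), "vib_invalid_cluster")
  }
  structure(
    list(symbols = as.character(symbols), coords = unname(coords),
         solute_atoms = solute_atoms, frozen_mask = frozen_mask,
         source_frame = as.integer(source_frame),
         source_time_fs = as.numeric(source_time_fs),
         source_atoms = as.integer(source_atoms)),
    class = "vib_cluster")
}

#' @export
print.vib_cluster <- function(x, ...) {
  cat(sprintf(
    "<vib_cluster: %d atoms (%d solute, %d frozen), frame %d @ %g fs>\n",
    length(x$symbols), length(x$solute_atoms), sum(x$frozen_mask),
    x$source_frame, x$source_time_fs))
  invisible(x)
}

#' Subsample a frame series at a fixed interval
#'
#' Keeps frames at times t0, t0 + interval, t0 + 2*interval, ...; the
#' requested interval must be a positive integer multiple of the series'
#' native spacing (no silent rounding).
#'
#' @param series a `vib_frame_series`.
#' @param interval_fs requested snapshot interval in fs.
#' @return a `vib_frame_series` with the effective sampling interval recorded
#'   as its `dt_fs`.
#' @export
select_snapshots <- function(series, interval_fs) {
  if (interval_fs <= 0)
    vib_stop("snapshot interval must be positive", "vib_invalid_interval")
  ratio <- interval_fs / series$dt_fs
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    vib_stop(sprintf(
      "interval %g fs is not a positive multiple of the native spacing %g fs",
      interval_fs, series$dt_fs), "vib_incommensurate_interval")
  stride <- as.integer(round(ratio))
  keep <- seq(1L, length(series$frames), by = stride)
  new_frame_series(series$frames[keep], dt_fs = series$dt_fs * stride,
                   topology = series$topology)
}

# minimum-image displacement matrix (rows of `d` shifted by whole box vectors)
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
  d
}

#' Map a solvation-shell count to a radial cutoff
#'
#' "Two solvation shells" is operationalized as a radial cutoff measured from
#' any solute atom. Default table: 1 shell = 4.0 Å, 2 shells = 7.5 Å; further
#' shells extend by 3.5 Å each. Any entry can be overridden per run.
#'
#' @param n_shells requested number of solvation shells (>= 1).
#' @param overrides optional named numeric vector/list mapping shell counts to
#'   cutoffs in Å, e.g. `c("2" = 8.2)`.
#' @return radial cutoff in Å.
#' @export
shells_to_cutoff <- function(n_shells, overrides = NULL) {
  if (n_shells < 1)
    vib_stop("n_shells must be >= 1", "vib_invalid_shells")
  key <- as.character(as.integer(n_shells))
  if (!is.null(overrides) && !is.null(overrides[[key]]))
    return(as.numeric(overrides[[key]]))
  defaults <- c("1" = 4.0, "2" = 7.5)
  if (key %in% names(defaults)) return(unname(defaults[key]))
  7.5 + 3.5 * (as.integer(n_shells) - 2L)
}

#' Carve a solute-centred solvation-shell cluster from a frame
#'
#' Includes the whole solute plus every solvent molecule having at least one
#' atom strictly within `cutoff_A` (minimum-image distance) of at least one
#' solute atom. The distance test is half-open: `d < cutoff` includes,
#' `d == cutoff` excludes. Included molecules are rigidly translated by whole
#' box vectors into the image nearest the solute centroid; per-atom re-imaging
#' is never applied, so internal geometries are exact. Atom order of the
#' parent frame is preserved.
#'
#' @param frame a `vib_frame` (periodic if it has a box; a frame without a box
#'   is treated as non-periodic and used as-is).
#' @param topology the `vib_topology` describing molecule membership.
#' @param cutoff_A radial cutoff in Å (>= 0). `0` yields a solute-only
#'   cluster.
#' @return a `vib_cluster` with all solvent atoms frozen.
#' @export
carve_cluster <- function(frame, topology, cutoff_A) {
  if (cutoff_A < 0)
    vib_stop("cutoff must be non-negative", "vib_invalid_cutoff")
  if (length(topology$elements) != length(frame$symbols))
    vib_stop("topology does not match frame atom count",
             "vib_structural_error")
  box <- frame$box
  sol_idx0 <- solute_atoms(topology)            # 0-based
  sol <- frame$coords[sol_idx0 + 1L, , drop = FALSE]
  sol_centroid <- colMeans(sol)

  included <- list()   # molecule -> translated coords
  mol_ids <- integer(0)
  for (mi in seq_along(topology$molecules)) {
    if (mi - 1L == topology$solute_molecule) next
    atoms0 <- topology$molecules[[mi]]
    xyz <- frame$coords[atoms0 + 1L, , drop = FALSE]
    # min-image distance of every molecule atom to every solute atom
    hit <- FALSE
    for (k in seq_len(nrow(xyz))) {
      d <- min_image(sweep(sol, 2, xyz[k, ]), box)
      if (any(sqrt(rowSums(d * d)) < cutoff_A)) { hit <- TRUE; break }
    }
    if (!hit) next
    # translate the whole molecule into the image nearest the solute centroid
    if (!is.null(box)) {
      mol_centroid <- colMeans(xyz)
      shift <- -box * round((mol_centroid - sol_centroid) / box)
      xyz <- sweep(xyz, 2, shift, `+`)
    }
    included[[length(included) + 1L]] <- xyz
    mol_ids <- c(mol_ids, mi)
  }

  # assemble in parent-frame atom order
  keep0 <- sort(c(sol_idx0, unlist(topology$molecules[mol_ids])))
  n <- length(keep0)
  coords <- matrix(NA_real_, n, 3)
  lookup <- match(sol_idx0, keep0)
  coords[lookup, ] <- sol
  for (j in seq_along(mol_ids)) {
    atoms0 <- topology$molecules[[mol_ids[j]]]
    coords[match(atoms0, keep0), ] <- included[[j]]
  }
  frozen <- !(keep0 %in% sol_idx0)
  new_cluster(symbols = topology$elements[keep0 + 1L], coords = coords,
              solute_atoms = which(!frozen) - 1L, frozen_mask = frozen,
              source_frame = frame$index, source_time_fs = frame$time_fs,
              source_atoms = keep0,
              # the extent sanity check is only meaningful when the shell fits
              # in half the box; for larger cutoffs nearest-image placement can
              # legitimately span more than one edge length
              box_min = if (!is.null(box) && cutoff_A <= min(box) / 2)
                min(box) else NULL)
}
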