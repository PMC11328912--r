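#' @title Trajectory frames, topologies and XYZ input/output
#'
#' @description
#' The trajectory layer uses three plain S3 containers:
#'
#' * **frame** — one snapshot: element symbols, an N x 3 coordinate matrix in
#'   Å, an optional orthorhombic box (three edge lengths in Å) and a time
#'   stamp in fs.
#' * **topology** — per-atom elements and (optional) partial charges, a
#'   partition of the atoms into molecules, the index of the solute molecule
#'   and the probe atoms (the carbonyl C and O of the amide group).
#' * **frame_series** — an ordered list of frames sharing one topology and a
#'   declared sampling interval.
#'
#' **Atom indexing is 0-based everywhere the package exposes indices** —
#' topology sidecar files, cluster comment lines, manifests and logs — so that
#' every artifact uses one convention. Internally R's 1-based subscripting is
#' used, with the shift applied at the container boundary.
#'
#' Only orthorhombic boxes are supported; triclinic input raises an
#' unsupported-feature error.
#'
#' @name trajectory-io
NULL

#' Construct and validate a single trajectory frame
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Å.
#' @param index non-negative integer frame index.
#' @param time_fs frame time in fs.
#' @param box optional numeric length-3 vector of orthorhombic box edge
#'   lengths in Å; `NULL` marks a non-periodic frame.
#' @return an object of class `"vib_frame"`.
#' @export
new_frame <- function(symbols, coords, index = 0L, time_fs = 0, box = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    vib_stop("coords must be an N x 3 numeric matrix", "vib_invalid_frame")
  if (length(symbols) != nrow(coords))
    vib_stop(sprintf(
      "symbol count (%d) does not match coordinate rows (%d)",
      length(symbols), nrow(coords)), "vib_invalid_frame")
  if (!all(is.finite(coords)))
    vib_stop("coordinates must all be finite", "vib_invalid_frame")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3)
      vib_stop(paste0(
        "box must be three orthorhombic edge lengths; ",
        "triclinic cells are not supported"), "vib_unsupported_box")
    if (!all(is.finite(box)) || any(box <= 0))
      vib_stop("box edge lengths must be strictly positive",
               "vib_invalid_frame")
  }
  if (index < 0)
    vib_stop("frame index must be non-negative", "vib_invalid_frame")
  structure(
    list(index = as.integer(index), time_fs = as.numeric(time_fs),
         symbols = as.character(symbols), coords = unname(coords), box = box),
    class = "vib_frame")
}

#' @export
print.vib_frame <- function(x, ...) {
  cat(sprintf("<vib_frame #%d: %d atoms, t = %g fs, %s>\n",
              x$index, length(x$symbols), x$time_fs,
              if (is.null(x$box)) "non-periodic"
              else sprintf("box %g x %g x %g Å", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Construct and validate a topology
#'
#' Molecule groups must partition the atom set exactly; the probe atoms must
#' belong to the solute molecule. All indices are 0-based.
#'
#' @param elements character vector of element symbols per atom.
#' @param molecules list of integer vectors (0-based atom indices), one per
#'   molecule, jointly covering every atom exactly once.
#' @param solute_molecule 0-based index into `molecules` naming the solute.
#' @param probe_atoms named integer list/vector with at least `C` and `O`
#'   (0-based atom indices of the carbonyl carbon and oxygen); optional `N`,
#'   `H` entries are carried along.
#' @param charges optional numeric vector of partial charges per atom in
#'   elementary charge units; `NULL` if unknown.
#' @return an object of class `"vib_topology"`.
#' @export
new_topology <- function(elements, molecules, solute_molecule, probe_atoms,
                         charges = NULL) {
  n <- length(elements)
  molecules <- lapply(molecules, function(m) as.integer(m))
  all_idx <- sort(unlist(molecules))
  if (length(all_idx) != n || !identical(all_idx, 0:(n - 1L)))
    vib_stop(paste0(
      "molecule groups must partition the atom set exactly ",
      "(every atom in exactly one molecule)"), "vib_invalid_topology")
  solute_molecule <- as.integer(solute_molecule)
  if (solute_molecule < 0 || solute_molecule >= length(molecules))
    vib_stop("solute_molecule index out of range", "vib_invalid_topology")
  probe_atoms <- lapply(probe_atoms, as.integer)
  if (!all(c("C", "O") %in% names(probe_atoms)))
    vib_stop("probe_atoms must name at least the carbonyl C and O",
             "vib_invalid_topology")
  solute_set <- molecules[[solute_molecule + 1L]]
  for (nm in names(probe_atoms)) {
    if (!probe_atoms[[nm]] %in% solute_set)
      vib_stop(sprintf("probe atom not in solute: %s (index %d)",
                       nm, probe_atoms[[nm]]), "vib_invalid_topology")
  }
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n)
      vib_stop("charges length must equal atom count", "vib_invalid_topology")
    if (!all(is.finite(charges)))
      vib_stop("charges must be finite", "vib_invalid_topology")
  }
  structure(
    list(elements = as.character(elements), charges = charges,
         molecules = molecules, solute_molecule = solute_molecule,
         probe_atoms = probe_atoms),
    class = "vib_topology")
}

#' @export
print.vib_topology <- function(x, ...) {
  cat(sprintf(
    "<vib_topology: %d atoms, %d molecules, solute = molecule %d, %s>\n",
    length(x$elements), length(x$molecules), x$solute_molecule,
    if (is.null(x$charges)) "no charges" else "with charges"))
  invisible(x)
}

#' 0-based atom indices of the solute molecule
#' @param topology a `vib_topology`.
#' @return integer vector of 0-based indices.
#' @export
solute_atoms <- function(topology) {
  topology$molecules[[topology$solute_molecule + 1L]]
}

#' Construct and validate a frame series
#'
#' @param frames list of `vib_frame` objects with strictly increasing times
#'   and identical atom counts.
#' @param dt_fs declared sampling interval in fs.
#' @param topology optional shared `vib_topology`; when given, its atom count
#'   is cross-checked against the frames.
#' @return an object of class `"vib_frame_series"`.
#' @export
new_frame_series <- function(frames, dt_fs, topology = NULL) {
  if (length(frames) == 0)
    vib_stop("frame series must contain at least one frame",
             "vib_invalid_series")
  counts <- vapply(frames, function(f) length(f$symbols), integer(1))
  if (length(unique(counts)) != 1)
    vib_stop(sprintf(
      "inconsistent atom counts across frames (first differing frame %d)",
      which(counts != counts[1])[1] - 1L), "vib_invalid_series")
  times <- vapply(frames, function(f) f$time_fs, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    vib_stop("frame times must be strictly increasing", "vib_invalid_series")
  if (!is.null(topology) && length(topology$elements) != counts[1])
    vib_stop(sprintf(
      "topology atom count (%d) does not match frames (%d)",
      length(topology$elements), counts[1]), "vib_invalid_series")
  if (dt_fs <= 0)
    vib_stop("sampling interval must be positive", "vib_invalid_series")
  structure(list(frames = frames, dt_fs = as.numeric(dt_fs),
                 topology = topology),
            class = "vib_frame_series")
}

#' @export
print.vib_frame_series <- function(x, ...) {
  cat(sprintf("<vib_frame_series: %d frames, dt = %g fs, %d atoms>\n",
              length(x$frames), x$dt_fs, length(x$frames[[1]]$symbols)))
  invisible(x)
}

#' @export
length.vib_frame_series <- function(x) length(x$frames)

# parse "key=value key=value" tokens from an XYZ comment line
parse_comment_tokens <- function(comment) {
  toks <- regmatches(comment,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*=[^ \t]+", comment))[[1]]
  out <- list()
  for (tk in toks) {
    eq <- regexpr("=", tk, fixed = TRUE)
    out[[substr(tk, 1, eq - 1)]] <- substr(tk, eq + 1, nchar(tk))
  }
  out
}

parse_num_list <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

#' Read a multi-frame XYZ trajectory
#'
#' Reads standard multi-block XYZ (`natoms` / comment / `natoms` atom lines
#' per frame). The comment line may carry extended-XYZ-style `key=value`
#' tokens: `time=<fs>`, `box=a,b,c` (Å), `frame=<index>`. When `time` is
#' absent, times are inferred from `dt_fs`; when `frame` is absent, frames are
#' numbered 0, 1, 2, ... in file order.
#'
#' @param path path to the XYZ file.
#' @param dt_fs declared sampling interval in fs, used when comment lines do
#'   not carry `time=` tokens and as the series' declared interval.
#' @param topology optional `vib_topology` cross-checked against the frames.
#' @return a `vib_frame_series`.
#' @export
read_xyz_frames <- function(path, dt_fs = 1, topology = NULL) {
  if (!file.exists(path))
    vib_stop(sprintf("file not found: %s", path), "vib_io_error")
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  pos <- 1L
  fidx <- 0L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0)
      vib_stop(sprintf(
        "malformed atom-count line at frame %d (line %d): '%s'",
        fidx, pos, lines[pos]), "vib_parse_error")
    if (pos + 1L + nat > length(lines))
      vib_stop(sprintf(
        "truncated block at frame %d: expected %d atom lines", fidx, nat),
        "vib_parse_error")
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    fields <- strsplit(trimws(atom_lines), "[ \t]+")
    nf <- vapply(fields, length, integer(1))
    if (any(nf < 4))
      vib_stop(sprintf(
        "malformed atom line in frame %d (need 'symbol x y z')", fidx),
        "vib_parse_error")
    symbols <- vapply(fields, `[`, character(1), 1)
    coords <- matrix(NA_real_, nat, 3)
    for (j in 1:3)
      coords[, j] <- as.numeric(vapply(fields, `[`, character(1), j + 1L))
    if (any(!is.finite(coords)))
      vib_stop(sprintf("non-numeric coordinate in frame %d", fidx),
               "vib_parse_error")
    tok <- parse_comment_tokens(comment)
    tm <- if (!is.null(tok$time)) as.numeric(tok$time) else fidx * dt_fs
    bx <- if (!is.null(tok$box)) parse_num_list(tok$box) else NULL
    idx <- if (!is.null(tok$frame)) as.integer(tok$frame) else fidx
    frames[[length(frames) + 1L]] <-
      new_frame(symbols, coords, index = idx, time_fs = tm, box = bx)
    pos <- pos + 2L + nat
    fidx <- fidx + 1L
  }
  counts <- vapply(frames, function(f) length(f$symbols), integer(1))
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1] - 1L
    vib_stop(sprintf(
      "inconsistent atom counts across frames: frame %d has %d atoms, frame 0 has %d",
      bad, counts[bad + 1L], counts[1]), "vib_structural_error")
  }
  new_frame_series(frames, dt_fs = dt_fs, topology = topology)
}

#' Read a topology sidecar file
#'
#' The sidecar is YAML with fields `elements` (list of symbols), optional
#' `charges` (list of numbers, elementary charge), `molecules` (list of lists
#' of 0-based atom indices), `solute` (0-based molecule index) and `probe`
#' (mapping with at least `C:` and `O:` 0-based atom indices).
#'
#' @param path path to the YAML sidecar.
#' @param frame optional `vib_frame` whose atom count is cross-checked.
#' @return a validated `vib_topology`.
#' @export
read_topology <- function(path, frame = NULL) {
  if (!file.exists(path))
    vib_stop(sprintf("file not found: %s", path), "vib_io_error")
  y <- yaml::read_yaml(path)
  for (req in c("elements", "molecules", "solute", "probe"))
    if (is.null(y[[req]]))
      vib_stop(sprintf("topology sidecar missing required field '%s'", req),
               "vib_parse_error")
  top <- new_topology(
    elements = unlist(y$elements),
    molecules = y$molecules,
    solute_molecule = y$solute,
    probe_atoms = y$probe,
    charges = if (is.null(y$charges)) NULL else unlist(y$charges))
  if (!is.null(frame) && length(top$elements) != length(frame$symbols))
    vib_stop(sprintf(
      "topology atom count (%d) does not match frame (%d)",
      length(top$elements), length(frame$symbols)), "vib_structural_error")
  top
}

#' Write a topology sidecar file
#'
#' @param topology a `vib_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  y <- list(elements = as.list(topology$elements),
            molecules = lapply(topology$molecules, as.list),
            solute = topology$solute_molecule,
            probe = topology$probe_atoms)
  if (!is.null(topology$charges)) y$charges <- as.list(topology$charges)
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

#' Read a single PDB frame (convenience path)
#'
#' Reads coordinates from a PDB file via \pkg{bio3d} and groups atoms into
#' molecules by residue number, a convenient approximation for solvent boxes
#' where each residue is one molecule.
#'
#' @param path path to a PDB file.
#' @return a list with a `vib_frame` (`frame`) and the residue-based molecule
#'   grouping (`molecules`, 0-based indices).
#' @export
read_pdb_frame <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    vib_stop("the PDB convenience reader requires the 'bio3d' package",
             "vib_missing_dependency")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  symbols <- trimws(a$elesy)
  symbols[!nzchar(symbols)] <- substr(trimws(a$elety[!nzchar(symbols)]), 1, 1)
  coords <- cbind(a$x, a$y, a$z)
  resid_key <- paste(a$chain, a$resno, sep = "_")
  groups <- split(seq_len(nrow(a)) - 1L, factor(resid_key,
                                                levels = unique(resid_key)))
  frame <- new_frame(symbols, coords, index = 0L, time_fs = 0)
  list(frame = frame, molecules = unname(groups))
}

# compress a sorted integer vector into "a-b,c,d-e" range notation
compress_ranges <- function(idx) {
  if (length(idx) == 0) return("")
  idx <- sort(unique(as.integer(idx)))
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  parts <- character(length(breaks) - 1L)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- idx[breaks[i] + 1L]; b <- idx[breaks[i + 1L]]
    parts[i] <- if (a == b) as.character(a) else sprintf("%d-%d", a, b)
  }
  paste(parts, collapse = ",")
}

expand_ranges <- function(s) {
  if (!nzchar(s)) return(integer(0))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      out <- c(out, ab[1]:ab[2])
    } else out <- c(out, as.integer(p))
  }
  out
}

#' Write a carved cluster as an XYZ file
#'
#' The comment line records provenance as `key=value` tokens: source frame
#' index and time, the 0-based frozen-atom list and the 0-based source-atom
#' indices into the parent frame. Coordinates are written with 17 significant
#' digits so that write/read round trips are bit-exact.
#'
#' @param cluster a `vib_cluster` (see [carve_cluster()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_xyz <- function(cluster, path) {
  if (length(cluster$symbols) == 0)
    vib_stop("refusing to write an empty cluster", "vib_invalid_cluster")
  frozen <- which(cluster$frozen_mask) - 1L
  comment <- sprintf("frame=%d time=%s frozen=%s source_atoms=%s",
                     cluster$source_frame, fmt_full(cluster$source_time_fs),
                     compress_ranges(frozen),
                     compress_ranges(cluster$source_atoms))
  n <- length(cluster$symbols)
  atom_lines <- sprintf("%-3s %s %s %s", cluster$symbols,
                        fmt_full(cluster$coords[, 1]),
                        fmt_full(cluster$coords[, 2]),
                        fmt_full(cluster$coords[, 3]))
  con <- file(path, "wb")  # binary mode: byte-identical output on any platform
  on.exit(close(con))
  writeLines(c(as.character(n), comment, atom_lines), con, sep = "\n")
  invisible(path)
}

#' Read a cluster XYZ file written by [write_cluster_xyz()]
#'
#' @param path path to the cluster XYZ file.
#' @return a `vib_cluster`.
#' @export
read_cluster_xyz <- function(path) {
  series <- read_xyz_frames(path)
  f <- series$frames[[1]]
  lines <- readLines(path, n = 2L, warn = FALSE)
  tok <- parse_comment_tokens(lines[2])
  n <- length(f$symbols)
  frozen_idx <- if (!is.null(tok$frozen)) expand_ranges(tok$frozen)
                else integer(0)
  src <- if (!is.null(tok$source_atoms)) expand_ranges(tok$source_atoms)
         else seq_len(n) - 1L
  frozen <- rep(FALSE, n)
  frozen[frozen_idx + 1L] <- TRUE
  new_cluster(symbols = f$symbols, coords = f$coords,
              solute_atoms = which(!frozen) - 1L,
              frozen_mask = frozen,
              source_frame = if (!is.null(tok$frame)) as.integer(tok$frame)
                             else 0L,
              source_time_fs = if (!is.null(tok$time)) as.numeric(tok$time)
                               else 0,
              source_atoms = src, check_geometry = FALSE)
}
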