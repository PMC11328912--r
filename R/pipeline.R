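#' @title Snapshot manifests and pipeline drivers
#'
#' @description
#' The stages communicate through a snapshot manifest: one CSV row per
#' snapshot with the 0-based snapshot index, its time, the cluster file, the
#' cluster atom count, the assigned probe frequency and an assignment status.
#' Numeric fields are written with 17 significant digits so that the
#' file-based pipeline reproduces in-memory results bit-for-bit.
#'
#' @name pipeline
NULL

#' Write a snapshot manifest
#'
#' @param manifest data frame with columns `snapshot`, `time_fs`,
#'   `cluster_file`, `n_atoms` and optionally `omega_cm1`, `status`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$time_fs <- fmt_full(m$time_fs)
  if (!is.null(m$omega_cm1))
    m$omega_cm1 <- ifelse(is.finite(manifest$omega_cm1),
                          fmt_full(manifest$omega_cm1), "")
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a snapshot manifest
#'
#' @param path manifest CSV path.
#' @return a data frame with numeric `time_fs`/`omega_cm1`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  m$snapshot <- as.integer(m$snapshot)
  m$time_fs <- as.numeric(m$time_fs)
  if (!is.null(m$n_atoms)) m$n_atoms <- as.integer(m$n_atoms)
  if (!is.null(m$omega_cm1))
    m$omega_cm1 <- suppressWarnings(as.numeric(m$omega_cm1))
  m
}

#' Carve clusters for every snapshot and write them with a manifest
#'
#' @param series a `vib_frame_series` (already subsampled via
#'   [select_snapshots()] if desired).
#' @param topology the `vib_topology`.
#' @param cutoff_A shell cutoff in Å (see [shells_to_cutoff()]).
#' @param outdir directory for cluster files and `manifest.csv`.
#' @return the manifest data frame, invisibly; files are written to `outdir`.
#' @export
extract_clusters <- function(series, topology, cutoff_A, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  n <- length(series$frames)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- series$frames[[i]]
    cl <- carve_cluster(fr, topology, cutoff_A)
    fname <- sprintf("cluster_%06d.xyz", i - 1L)
    write_cluster_xyz(cl, file.path(outdir, fname))
    rows[[i]] <- data.frame(snapshot = i - 1L, time_fs = fr$time_fs,
                            cluster_file = fname,
                            n_atoms = length(cl$symbols))
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(outdir, "manifest.csv"))
  invisible(manifest)
}

#' Run the map stub engine over a cluster directory
#'
#' Reads every cluster file in the manifest, evaluates the electrostatic map,
#' assigns the probe mode and updates the manifest with `omega_cm1` and
#' `status` (`"ok"` or `"failed"`).
#'
#' @param clusters_dir directory holding the cluster files and
#'   `manifest.csv`.
#' @param topology the parent `vib_topology` (charges and probe atoms).
#' @param params a `vib_map_params`.
#' @param window_cm1 assignment window passed to [assign_amide_I()].
#' @return the updated manifest data frame, invisibly; `manifest.csv` is
#'   rewritten in place.
#' @export
run_map_engine <- function(clusters_dir, topology, params,
                           window_cm1 = c(1550, 1850)) {
  manifest <- read_manifest(file.path(clusters_dir, "manifest.csv"))
  omega <- rep(NA_real_, nrow(manifest))
  status <- rep("failed", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      cl <- read_cluster_xyz(file.path(clusters_dir,
                                       manifest$cluster_file[i]))
      fr <- map_engine_frequencies(cl, topology, params)
      assign_amide_I(fr, topology, window_cm1 = window_cm1)
    }, vibsolv_error = function(e) e)
    if (inherits(res, "vib_assignment")) {
      omega[i] <- res$omega_snap
      status[i] <- "ok"
    }
  }
  manifest$omega_cm1 <- omega
  manifest$status <- status
  write_manifest(manifest, file.path(clusters_dir, "manifest.csv"))
  invisible(manifest)
}

#' Parse external-engine job directories into a manifest
#'
#' For each manifest row, looks for a job directory named after the cluster
#' file (without extension) under `jobs_dir`, parses its vibrational output
#' and assigns the probe mode. Snapshots whose job is missing, unparsable,
#' unconverged or without an in-window mode are marked `"failed"`.
#'
#' @param clusters_dir directory holding `manifest.csv`.
#' @param jobs_dir directory of per-snapshot engine job directories.
#' @param topology the parent `vib_topology`.
#' @param window_cm1 assignment window.
#' @param drop_unconverged mark unconverged optimizations as failed
#'   (default TRUE).
#' @return the updated manifest data frame, invisibly.
#' @export
collect_engine_results <- function(clusters_dir, jobs_dir, topology,
                                   window_cm1 = c(1550, 1850),
                                   drop_unconverged = TRUE) {
  manifest <- read_manifest(file.path(clusters_dir, "manifest.csv"))
  omega <- rep(NA_real_, nrow(manifest))
  status <- rep("failed", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    jdir <- file.path(jobs_dir,
                      tools::file_path_sans_ext(manifest$cluster_file[i]))
    res <- tryCatch({
      fr <- parse_engine_frequencies(jdir)
      if (drop_unconverged && isFALSE(fr$converged))
        vib_stop("optimization did not converge", "vib_assignment_failure")
      assign_amide_I(fr, topology, window_cm1 = window_cm1)
    }, error = function(e) e)
    if (inherits(res, "vib_assignment")) {
      omega[i] <- res$omega_snap
      status[i] <- "ok"
    }
  }
  manifest$omega_cm1 <- omega
  manifest$status <- status
  write_manifest(manifest, file.path(clusters_dir, "manifest.csv"))
  invisible(manifest)
}

#' Export an FFCF curve and Kubo fit as CSV + JSON
#'
#' @param curve a `vib_ffcf`.
#' @param fit a `vib_kubo_fit` (optional).
#' @param outdir output directory.
#' @param provenance optional named list merged into the JSON record.
#' @return invisibly, the paths written.
#' @export
export_ffcf <- function(curve, fit = NULL, outdir, provenance = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(outdir, "ffcf.csv")
  utils::write.csv(data.frame(lag_ps = curve$lag_ps, C_cm2 = curve$C_cm2,
                              n_pairs = curve$n_pairs),
                   csv_path, row.names = FALSE)
  json_path <- file.path(outdir, "ffcf_fit.json")
  rec <- list(provenance = c(list(package = "vibsolv"), provenance))
  if (!is.null(fit)) {
    tc <- correlation_time(fit)
    rec$fit <- list(
      components = fit$components, delta0_sq = fit$delta0_sq,
      rmse = fit$rmse, fit_range_ps = fit$fit_range_ps,
      tau_c_conventions = as.list(tc$all),
      diagnostics = fit$diagnostics)
  }
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(list(csv = csv_path, json = json_path))
}
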