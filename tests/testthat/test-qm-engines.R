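# shared 3-atom probe-in-a-field system used across engine tests
probe_system <- function(env_pos = c(5.6, 0, 0), q = 1) {
  n_env <- length(env_pos) / 3
  env_mat <- matrix(env_pos, n_env, 3, byrow = TRUE)
  coords <- rbind(c(-0.6, 0, 0), c(0.6, 0, 0), env_mat)
  syms <- c("C", "O", rep("Na", n_env))
  frozen <- c(FALSE, FALSE, rep(TRUE, n_env))
  cl <- new_cluster(syms, coords, solute_atoms = 0:1, frozen_mask = frozen,
                    source_atoms = seq_along(syms) - 1L)
  top <- new_topology(
    syms, c(list(0:1), lapply(seq_len(n_env), function(i) 1L + i)),
    0L, list(C = 0L, O = 1L),
    charges = c(0, 0, rep(q, n_env)))
  list(cluster = cl, topology = top)
}

test_that("map engine reproduces the hand Coulomb evaluation on the bond axis", {
  # +1e on the C->O axis, 5 A from the C=O midpoint beyond O:
  # omega = 1700 - 50 * (14.3996 / 25) = 1671.2008
  sys <- probe_system(env_pos = c(5, 0, 0), q = 1)
  res <- map_engine_frequencies(sys$cluster, sys$topology,
                                map_params(1700, -50))
  expect_length(res$modes, 1)
  expect_equal(res$modes[[1]]$frequency, 1700 - 50 * 14.3996 / 25,
               tolerance = 1e-12)
  # independent field summation oracle on a random multi-charge arrangement
  set.seed(5)
  pos <- matrix(runif(9, 3, 9), 3, 3)
  sys2 <- probe_system(env_pos = as.vector(t(pos)), q = 1)
  sys2$topology$charges[3:5] <- c(0.4, -0.3, 0.25)
  res2 <- map_engine_frequencies(sys2$cluster, sys2$topology,
                                 map_params(1700, -50))
  e_oracle <- field_oracle(pos, c(0.4, -0.3, 0.25),
                           rC = c(-0.6, 0, 0), rO = c(0.6, 0, 0))
  expect_equal(res2$modes[[1]]$frequency, 1700 - 50 * e_oracle,
               tolerance = 1e-10)
})

test_that("zero environment charge gives exactly omega0", {
  sys <- probe_system(q = 0)
  res <- map_engine_frequencies(sys$cluster, sys$topology,
                                map_params(1684, -40))
  expect_identical(res$modes[[1]]$frequency, 1684)
})

test_that("the map frequency is exactly linear in every environment charge", {
  set.seed(9)
  pos <- matrix(runif(12, 3, 10), 4, 3)
  base <- probe_system(env_pos = as.vector(t(pos)), q = 0)
  mp <- map_params(1700, -50)
  shift_for <- function(charges) {
    s <- base
    s$topology$charges[3:6] <- charges
    map_engine_frequencies(s$cluster, s$topology, mp)$modes[[1]]$frequency -
      1700
  }
  q1 <- c(0.5, 0, 0, 0); q2 <- c(0, -0.3, 0.2, 0.7)
  expect_equal(shift_for(q1 + q2), shift_for(q1) + shift_for(q2),
               tolerance = 1e-12)
  expect_equal(shift_for(3 * q2), 3 * shift_for(q2), tolerance = 1e-12)
})

test_that("degenerate probe geometry is refused", {
  sys <- probe_system()
  sys$cluster$coords[2, ] <- sys$cluster$coords[1, ]  # collapse C=O
  expect_error(
    map_engine_frequencies(sys$cluster, sys$topology, map_params()),
    class = "vib_invalid_probe")
})

test_that("job preparation writes the 1-based constraint list and command lines", {
  set.seed(21)
  n <- 48
  frozen <- rep(TRUE, n); frozen[1:12] <- FALSE
  coords <- matrix(seq_len(n * 3) * 1.9, n, 3)
  cl <- new_cluster(rep("C", n), coords, solute_atoms = 0:11,
                    frozen_mask = frozen, check_geometry = FALSE)
  wd <- withr::local_tempdir()
  job <- prepare_engine_job(cl, file.path(wd, "snap0"))
  inp <- readLines(file.path(wd, "snap0", "xtb.inp"))
  # frozen 0-based {12..47} -> xtb 1-based 13-48
  expect_true(any(grepl("atoms: 13-48", inp)))
  expect_true(file.exists(file.path(wd, "snap0", "cluster.xyz")))
  cmds <- readLines(file.path(wd, "snap0", "run_commands.txt"))
  expect_match(cmds[1], "--opt")
  expect_match(cmds[2], "--hess")
  # collision without overwrite flag
  expect_error(prepare_engine_job(cl, file.path(wd, "snap0")),
               class = "vib_workdir_collision")
  expect_no_error(prepare_engine_job(cl, file.path(wd, "snap0"),
                                     overwrite = TRUE))
})

test_that("an all-frozen cluster has nothing to optimize", {
  cl <- new_cluster(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                    solute_atoms = 0:1, frozen_mask = c(FALSE, FALSE))
  cl$frozen_mask <- c(TRUE, TRUE)  # force the degenerate state
  err <- expect_error(prepare_engine_job(cl, withr::local_tempdir()),
                      class = "vib_invalid_job")
  expect_match(conditionMessage(err), "nothing to optimize")
})

test_that("solute-only clusters get an empty constraint list but a valid job", {
  cl <- new_cluster(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                    solute_atoms = 0:1, frozen_mask = c(FALSE, FALSE))
  wd <- file.path(withr::local_tempdir(), "solute_only")
  prepare_engine_job(cl, wd)
  inp <- readLines(file.path(wd, "xtb.inp"))
  expect_false(any(grepl("atoms:", inp)))
  expect_equal(inp[1], "$fix")
})

test_that("g98-style output parses modes sorted with intensities and flags imaginaries", {
  wd <- withr::local_tempdir()
  # fixture written in the documented dialect: two real modes + one imaginary
  disp <- list(
    matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE),
    matrix(c(0, 1, 0, 0, -1, 0), 2, 3, byrow = TRUE),
    matrix(c(0, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE))
  modes <- list(new_mode(1710.8, 25, disp[[1]]),
                new_mode(-35, 0, disp[[3]]),
                new_mode(1655.2, 310, disp[[2]]))
  res0 <- new_freq_result(modes, converged = TRUE, engine = "fixture")
  write_g98_frequencies(res0, file.path(wd, "g98.out"))
  writeLines("   *** GEOMETRY OPTIMIZATION CONVERGED AFTER 25 ITERATIONS ***",
             file.path(wd, "xtb_opt.out"))
  res <- parse_engine_frequencies(wd)
  freqs <- vapply(res$modes, function(m) m$frequency, numeric(1))
  expect_equal(freqs, c(-35, 1655.2, 1710.8))
  expect_true(res$modes[[1]]$imaginary)
  expect_equal(res$modes[[2]]$ir_intensity, 310)
  expect_true(res$converged)
})

test_that("serialize-then-parse round trip preserves the frequency result", {
  set.seed(14)
  n_at <- 5
  modes <- lapply(1:4, function(i) {
    d <- matrix(rnorm(n_at * 3), n_at, 3)
    new_mode(800 + 250 * i + runif(1), runif(1, 0, 400), d)
  })
  res0 <- new_freq_result(modes, converged = TRUE, engine = "fixture")
  wd <- withr::local_tempdir()
  write_g98_frequencies(res0, file.path(wd, "g98.out"))
  res <- parse_engine_frequencies(wd)
  expect_length(res$modes, 4)
  for (i in 1:4) {
    expect_equal(res$modes[[i]]$frequency, res0$modes[[i]]$frequency,
                 tolerance = 1e-9)
    expect_equal(res$modes[[i]]$ir_intensity, res0$modes[[i]]$ir_intensity,
                 tolerance = 1e-9)
    expect_equal(res$modes[[i]]$displacement, res0$modes[[i]]$displacement,
                 tolerance = 1e-8)
  }
})

test_that("vibspectrum output parses, with and without symmetry labels", {
  wd <- withr::local_tempdir()
  writeLines(c(
    "$vibrational spectrum",
    "#  mode     symmetry     wave number   IR intensity    selection rules",
    "#                         cm**(-1)        km*mol**(-1)  IR     RAMAN",
    "     1                      -0.00         0.00000      -      -",
    "     6        a            -35.00         0.00000      YES     YES",
    "     7        a           1655.20       310.00000      YES     YES",
    "     8        a           1710.80        25.00000      YES     YES",
    "$end"), file.path(wd, "vibspectrum"))
  res <- parse_engine_frequencies(wd)
  freqs <- vapply(res$modes, function(m) m$frequency, numeric(1))
  expect_equal(freqs, c(-35, 0, 1655.2, 1710.8))
  expect_true(is.na(res$converged))  # no run log present
  expect_null(res$modes[[3]]$displacement)
})

test_that("missing or empty vibrational output is a parse error naming the file", {
  wd <- withr::local_tempdir()
  err <- expect_error(parse_engine_frequencies(wd), class = "vib_parse_error")
  expect_match(conditionMessage(err), "g98.out or vibspectrum")
  writeLines(c("$vibrational spectrum", "$end"),
             file.path(wd, "vibspectrum"))
  expect_error(parse_engine_frequencies(wd), class = "vib_parse_error")
})

test_that("a single in-window mode is chosen regardless of intensity", {
  sys <- probe_system()
  res <- map_engine_frequencies(sys$cluster, sys$topology,
                                map_params(1700, -50))
  res$modes[[1]]$ir_intensity <- 0
  asg <- assign_amide_I(res, sys$topology)
  expect_equal(asg$omega_snap, res$modes[[1]]$frequency)
})

test_that("projection scoring keeps the C=O-localized mode and drops spectators", {
  sys <- probe_system()
  n <- length(sys$cluster$symbols)
  d_strong <- matrix(0, n, 3); d_strong[1, 1] <- 0.9; d_strong[2, 1] <- -0.9
  d_weak <- matrix(0, n, 3)
  d_weak[1, 1] <- 0.05; d_weak[2, 1] <- -0.05; d_weak[3, 2] <- 1
  res <- new_freq_result(list(new_mode(1650, 100, d_strong),
                              new_mode(1700, 100, d_weak)),
                         converged = TRUE, engine = "constructed",
                         cluster = sys$cluster)
  asg <- assign_amide_I(res, sys$topology)
  expect_equal(asg$omega_snap, 1650)
  expect_equal(sum(asg$candidates$candidate), 1)
  expect_true(all(asg$candidates$score >= 0 & asg$candidates$score <= 1))
})

test_that("candidate modes are intensity-weight averaged and imaginaries excluded", {
  sys <- probe_system()
  n <- length(sys$cluster$symbols)
  d <- matrix(0, n, 3); d[1, 1] <- 1; d[2, 1] <- -1
  res <- new_freq_result(list(new_mode(1640, 300, d), new_mode(1680, 100, d),
                              new_mode(-1650, 500, d)),
                         converged = TRUE, engine = "constructed",
                         cluster = sys$cluster)
  asg <- assign_amide_I(res, sys$topology)
  expect_equal(asg$omega_snap, (300 * 1640 + 100 * 1680) / 400)
  # imaginary mode never among scored candidates
  expect_equal(nrow(asg$candidates), 2)
})

test_that("no real in-window mode marks the snapshot unusable", {
  sys <- probe_system()
  n <- length(sys$cluster$symbols)
  d <- matrix(0, n, 3); d[1, 1] <- 1
  res <- new_freq_result(list(new_mode(900, 10, d), new_mode(-1650, 10, d)),
                         converged = TRUE, engine = "constructed",
                         cluster = sys$cluster)
  expect_error(assign_amide_I(res, sys$topology),
               class = "vib_assignment_failure")
})

test_that("assignment is invariant under global rotation of cluster and displacements", {
  sys <- probe_system(env_pos = c(4, 2, 1, -3, 5, 2), q = 0.5)
  n <- length(sys$cluster$symbols)
  set.seed(4)
  d1 <- matrix(rnorm(n * 3), n, 3); d2 <- matrix(rnorm(n * 3), n, 3)
  d1[1, ] <- c(2, 0, 0); d1[2, ] <- c(-2, 0, 0)  # strongly C=O localized
  mk_res <- function(cl, da, db)
    new_freq_result(list(new_mode(1600, 50, da), new_mode(1800, 70, db)),
                    converged = TRUE, engine = "constructed", cluster = cl)
  asg0 <- assign_amide_I(mk_res(sys$cluster, d1, d2), sys$topology)
  # random rotation matrix via QR
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  cl_rot <- sys$cluster
  cl_rot$coords <- sys$cluster$coords %*% t(R)
  asg1 <- assign_amide_I(mk_res(cl_rot, d1 %*% t(R), d2 %*% t(R)),
                         sys$topology)
  expect_equal(asg1$candidates$score, asg0$candidates$score,
               tolerance = 1e-10)
  expect_equal(asg1$omega_snap, asg0$omega_snap, tolerance = 1e-10)
})
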