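test_that("snapshot selection arithmetic matches the sampling cadence", {
  # 250 ps at native 50 fs: 5001 frames; re-selecting at 50 fs is the identity
  frames <- lapply(0:5000, function(i)
    new_frame("C", matrix(c(i %% 7, 0, 0), 1, 3), index = i,
              time_fs = i * 50))
  series <- new_frame_series(frames, dt_fs = 50)
  sel <- select_snapshots(series, 50)
  expect_length(sel, 5001)
  expect_equal(sel$dt_fs, 50)
  # every 100 fs halves the count (t = 0 included)
  sel2 <- select_snapshots(series, 100)
  expect_length(sel2, 2501)
  expect_equal(sel2$dt_fs, 100)
  expect_equal(sel2$frames[[2]]$time_fs, 100)
})

test_that("incommensurate snapshot intervals are rejected, never rounded", {
  frames <- lapply(0:10, function(i)
    new_frame("C", matrix(0, 1, 3), index = i, time_fs = i * 50))
  series <- new_frame_series(frames, dt_fs = 50)
  expect_error(select_snapshots(series, 75),
               class = "vib_incommensurate_interval")
  expect_error(select_snapshots(series, -50),
               class = "vib_invalid_interval")
})

test_that("cutoff 0 carves the solute alone with an all-FALSE frozen mask", {
  sys <- tiny_system()
  cl <- carve_cluster(sys$frame, sys$topology, 0)
  expect_equal(length(cl$symbols), 2)
  expect_false(any(cl$frozen_mask))
  expect_equal(cl$solute_atoms, 0:1)
})

test_that("solvent at minimum-image distances 3, 5, 9 with cutoff 6 keeps exactly two molecules", {
  sys <- tiny_system(solvent_offsets_A = c(3, 5, 9))
  cl <- carve_cluster(sys$frame, sys$topology, 6)
  expect_equal(sum(cl$frozen_mask), 2)
  oracle <- shell_oracle(sys$frame, sys$topology, 6)
  expect_equal(sort(cl$source_atoms[cl$frozen_mask]),
               sort(unlist(sys$topology$molecules[oracle + 1L])))
})

test_that("the distance test is half-open: d == cutoff excludes", {
  sys <- tiny_system(solvent_offsets_A = c(4, 8))
  # the first solvent site sits exactly 4 A from the O probe atom
  cl_eq <- carve_cluster(sys$frame, sys$topology, 4)
  expect_equal(sum(cl_eq$frozen_mask), 0)
  cl_gt <- carve_cluster(sys$frame, sys$topology, 4 + 1e-9)
  expect_equal(sum(cl_gt$frozen_mask), 1)
})

test_that("carving agrees with the brute-force minimum-image oracle on random frames", {
  set.seed(101)
  for (rep in 1:12) {
    box <- runif(1, 12, 25)
    n_solv <- sample(5:40, 1)
    ctr <- box / 2
    coords <- rbind(c(ctr - 0.6, ctr, ctr), c(ctr + 0.6, ctr, ctr))
    syms <- c("C", "O")
    mols <- list(0:1)
    nxt <- 2L
    for (i in seq_len(n_solv)) {
      na <- sample(1:3, 1)
      base <- runif(3, 0, box)
      xyz <- sweep(matrix(runif(na * 3, -0.5, 0.5), na, 3), 2, base, `+`)
      coords <- rbind(coords, xyz)
      syms <- c(syms, rep("Ar", na))
      mols <- c(mols, list(nxt:(nxt + na - 1L)))
      nxt <- nxt + na
    }
    top <- new_topology(syms, mols, 0L, list(C = 0L, O = 1L))
    frame <- new_frame(syms, coords, box = rep(box, 3))
    cutoff <- runif(1, 2, box / 2)
    cl <- tryCatch(carve_cluster(frame, top, cutoff),
                   vib_cluster_clash = function(e) NULL)
    if (is.null(cl)) next  # random placement clashed; the guard is its own test
    oracle_mols <- shell_oracle(frame, top, cutoff)
    expect_equal(sort(cl$source_atoms[cl$frozen_mask]),
                 sort(as.integer(unlist(top$molecules[oracle_mols + 1L]))),
                 info = sprintf("rep %d cutoff %.2f", rep, cutoff))
    # whole-molecule rule: no fragments
    for (m in oracle_mols)
      expect_true(all(top$molecules[[m + 1L]] %in% cl$source_atoms))
    # monotonicity in the cutoff
    cl_small <- tryCatch(carve_cluster(frame, top, cutoff / 2),
                         vib_cluster_clash = function(e) NULL)
    if (!is.null(cl_small))
      expect_true(all(cl_small$source_atoms %in% cl$source_atoms))
  }
})

test_that("carving is invariant under rigid translation modulo the box", {
  sys <- tiny_system(solvent_offsets_A = c(3, 5, 9), box = 20)
  cl0 <- carve_cluster(sys$frame, sys$topology, 6)
  set.seed(7)
  for (rep in 1:5) {
    shift <- runif(3, -30, 30)
    f2 <- sys$frame
    moved <- sweep(sys$frame$coords, 2, shift, `+`)
    # wrap whole molecules into the primary cell (trajectories keep
    # molecules intact; atom-wise wrapping would split them)
    for (m in sys$topology$molecules) {
      ctr <- colMeans(moved[m + 1L, , drop = FALSE])
      moved[m + 1L, ] <- sweep(moved[m + 1L, , drop = FALSE], 2,
                               20 * floor(ctr / 20), `-`)
    }
    f2$coords <- moved
    cl2 <- carve_cluster(f2, sys$topology, 6)
    expect_identical(cl2$source_atoms, cl0$source_atoms)
    # internal geometry identical: compare distances to the probe C
    d0 <- sqrt(rowSums(sweep(cl0$coords, 2, cl0$coords[1, ])^2))
    d2 <- sqrt(rowSums(sweep(cl2$coords, 2, cl2$coords[1, ])^2))
    expect_equal(d2, d0, tolerance = 1e-9)
  }
})

test_that("unwrapping translates whole molecules to the image nearest the solute", {
  # an intact dimer near the lower box wall is included through the periodic
  # image and must arrive translated by one whole box vector, bond unchanged
  box <- 10
  coords <- rbind(c(5, 5, 5), c(6.2, 5, 5),   # solute C, O at center
                  c(0.2, 5, 5), c(0.7, 5, 5)) # intact solvent dimer
  top <- new_topology(c("C", "O", "N", "N"), list(0:1, 2:3), 0L,
                      list(C = 0L, O = 1L))
  frame <- new_frame(c("C", "O", "N", "N"), coords, box = rep(box, 3))
  cl <- carve_cluster(frame, top, 4.9)
  expect_equal(length(cl$symbols), 4)
  rows <- which(cl$frozen_mask)
  bond <- sqrt(sum((cl$coords[rows[1], ] - cl$coords[rows[2], ])^2))
  expect_equal(bond, 0.5, tolerance = 1e-12)
  expect_equal(sort(cl$coords[rows, 1]), c(10.2, 10.7))  # shifted by +box
})

test_that("clashing trajectories are reported with the offending atom pair", {
  sys <- tiny_system(solvent_offsets_A = c(0.1))
  err <- expect_error(carve_cluster(sys$frame, sys$topology, 5),
                      class = "vib_cluster_clash")
  expect_match(conditionMessage(err), "atoms [0-9]+ and [0-9]+")
})

test_that("shell counts map to configured cutoffs with overrides", {
  expect_equal(shells_to_cutoff(2), 7.5)
  expect_equal(shells_to_cutoff(1), 4.0)
  expect_equal(shells_to_cutoff(2, overrides = list("2" = 8.2)), 8.2)
  expect_equal(shells_to_cutoff(3), 11.0)
  expect_error(shells_to_cutoff(0), class = "vib_invalid_shells")
})

test_that("a two-shell carve of a solvated amide exceeds 100 atoms", {
  # dense packed box emulating a 40 A solvent box at water-like site density
  set.seed(33)
  box <- 24
  grid <- seq(1.4, box - 1.4, by = 3.1)
  pts <- as.matrix(expand.grid(grid, grid, grid))
  pts <- pts + matrix(runif(length(pts), -0.45, 0.45), nrow(pts), 3)
  ctr <- box / 2
  sol_xyz <- rbind(c(ctr - 0.6, ctr, ctr), c(ctr + 0.6, ctr, ctr),
                   c(ctr - 1.5, ctr - 1.1, ctr), c(ctr - 1.4, ctr + 1.1, ctr))
  keep <- apply(pts, 1, function(p)
    min(sqrt(rowSums(sweep(sol_xyz, 2, p)^2))) > 2.2)
  pts <- pts[keep, ]
  # each grid point seeds a 3-site water-like molecule
  n_mol <- nrow(pts)
  solv <- do.call(rbind, lapply(seq_len(n_mol), function(i)
    rbind(pts[i, ], pts[i, ] + c(0.76, 0.59, 0), pts[i, ] + c(-0.76, 0.59, 0))))
  syms <- c("C", "O", "C", "N", rep(c("O", "H", "H"), n_mol))
  coords <- rbind(sol_xyz, solv)
  mols <- c(list(0:3), lapply(seq_len(n_mol), function(i)
    (4L + 3L * (i - 1L)):(6L + 3L * (i - 1L))))
  top <- new_topology(syms, mols, 0L, list(C = 0L, O = 1L))
  frame <- new_frame(syms, coords, box = rep(box, 3))
  cl <- carve_cluster(frame, top, shells_to_cutoff(2))
  expect_gt(length(cl$symbols), 100)
})
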