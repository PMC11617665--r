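rand_xyz <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 3), n, 3)
}

rot_z <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)

test_that("Kabsch fit removes rigid motion and never reflects", {
  P <- rand_xyz(10, 1)
  fit_id <- kabsch_superpose(P, P)
  expect_equal(fit_id$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit_id$rotation, diag(3), tolerance = 1e-8)

  Q <- P %*% rot_z(pi / 2) + matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  fit <- kabsch_superpose(Q, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # a mirrored copy cannot be superposed by a proper rotation
  M <- P; M[, 1] <- -M[, 1]
  fitm <- kabsch_superpose(M, P)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-10)
  expect_gt(fitm$rmsd, 0.1)
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3 atoms")
})

test_that("superposed RMSD matches the quaternion closed form", {
  for (seed in 1:5) {
    P <- rand_xyz(8, seed)
    Q <- rand_xyz(8, seed + 100)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_superpose_rmsd(P, Q),
                 tolerance = 1e-6)
  }
  # 4-point toy set with one displaced atom
  A <- matrix(c(0,0,0, 1,0,0, 0,1,0, 0,0,1), 4, 3, byrow = TRUE)
  B <- A; B[4, ] <- c(0.3, 0.1, 1.4)
  expect_equal(kabsch_superpose(B, A)$rmsd, oracle_superpose_rmsd(B, A),
               tolerance = 1e-6)
  # superposition never increases RMSD
  expect_lte(kabsch_superpose(B, A)$rmsd, rmsd(B, A))
})

test_that("plain RMSD follows its definition and is a pseudometric", {
  a <- matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  b <- matrix(c(1, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, b), sqrt(5))
  one <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(rmsd(one, one + c(2, 0, 0)), 2)
  for (seed in 1:5) {
    x <- rand_xyz(6, seed); y <- rand_xyz(6, seed + 50); z <- rand_xyz(6, seed + 90)
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z))
  }
  expect_error(rmsd(a, matrix(0, 3, 3)), "atom count")
})

test_that("RMSD series is zero for static or merely translated frames", {
  tr <- gen_trajectory(n_frames = 6, n_residues = 5)
  expect_equal(rmsd_series(tr)$rmsd, rep(0, 6), tolerance = 1e-10)
  # translate one frame: superposition removes it
  tr$coords[, , 4] <- tr$coords[, , 4] + 5
  expect_equal(rmsd_series(tr)$rmsd[4], 0, tolerance = 1e-10)
  expect_equal(rmsd_series(tr)$time_ns, 0:5)
})

test_that("RMSD series mean matches the closed form for a planted wobble", {
  # amplitude pattern +a,-a,-a,+a at positions symmetric about the centroid:
  # zero net translation and zero net torque, so superposition leaves the
  # displacement field untouched (to first order in a)
  a <- 0.5
  amps <- rep(0, 12); amps[c(3, 5, 8, 10)] <- c(a, -a, -a, a)
  tr <- gen_trajectory(n_frames = 40, n_residues = 12, waveform = "sine",
                       amplitudes = amps, cycles = 4)
  # 12 of 36 atoms displaced by a*sin(phase); reference is frame 1 (phase
  # 0): frame RMSD = a*|sin|/sqrt(3), mean |sin| over whole cycles = 2/pi
  ser <- rmsd_series(tr, selection = NULL)
  expect_equal(mean(ser$rmsd), (a / sqrt(3)) * (2 / pi), tolerance = 0.05)
})

test_that("RMSF recovers planted amplitudes and ignores rigid motion", {
  tr0 <- gen_trajectory(n_frames = 10, n_residues = 6)
  expect_equal(rmsf(tr0)$rmsf, rep(0, 6), tolerance = 1e-10)

  amps <- c(rep(0, 11), 1.2)
  tr <- gen_trajectory(n_frames = 50, n_residues = 12, amplitudes = amps)
  r <- rmsf(tr, align = FALSE)
  truth <- attr(tr, "truth")$expected_rmsf
  expect_equal(r$rmsf, truth$rmsf, tolerance = 1e-8)

  # two-frame square wave: rmsf exactly the amplitude
  tr2 <- gen_trajectory(n_frames = 2, n_residues = 4,
                        amplitudes = c(0, 0, 0, 0.7))
  expect_equal(rmsf(tr2, align = FALSE)$rmsf[4], 0.7, tolerance = 1e-10)

  # invariance under a global rigid motion applied to every frame
  trm <- tr
  for (f in seq_len(dim(trm$coords)[3])) {
    th <- 0.1 * f
    trm$coords[, , f] <- trm$coords[, , f] %*% rot_z(th) +
      matrix(rep(c(f, -f, 2 * f), each = nrow(trm$atoms)), ncol = 3)
  }
  rm_ <- rmsf(trm, align = TRUE)
  ra <- rmsf(tr, align = TRUE)
  expect_equal(rm_$rmsf, ra$rmsf, tolerance = 1e-6)

  expect_error(rmsf(gen_trajectory(n_frames = 2, n_residues = 3)[["atoms"]]),
               "trajectory3d")
})

test_that("contact occupancy equals the planted schedule", {
  dist <- c(3, 3, 5, 3, 6, 7, 3, 9)
  tr <- gen_trajectory(n_frames = 8, n_residues = 5, ligand_distances = dist)
  cc <- contact_residues(tr, cutoff = 4)
  probe <- attr(tr, "truth")$probe_resid
  expect_equal(cc$resid, probe)
  expect_equal(cc$occupancy, mean(dist <= 4))

  # frame-window restriction
  cc2 <- contact_residues(tr, cutoff = 4, frames = 1:4)
  expect_equal(cc2$occupancy, mean(dist[1:4] <= 4))

  # ligand always beyond the cutoff: empty map
  far <- gen_trajectory(n_frames = 4, n_residues = 5,
                        ligand_distances = rep(9, 4))
  expect_equal(nrow(contact_residues(far, cutoff = 4)), 0L)

  # fixed 3 A contact in all frames: occupancy 1 for the probe only
  always <- gen_trajectory(n_frames = 5, n_residues = 5,
                           ligand_distances = rep(3, 5))
  ca <- contact_residues(always, cutoff = 4)
  expect_equal(ca$resid, attr(always, "truth")$probe_resid)
  expect_equal(ca$occupancy, 1)
})

test_that("MM/PBSA combination follows the component arithmetic", {
  # direct arithmetic case: planted deltas 0, -20, -30, +15, -5 and -TdS 10
  e <- gen_energy_components(n_frames = 10, sds = 0, minus_TdS = 10, seed = 3)
  m <- mmpbsa_combine(e)
  expect_equal(m$dG_bind, -30)
  expect_equal(m$dG_sd, 0)
  expect_true(m$entropy_included)
  s <- setNames(m$summary$mean, m$summary$component)
  expect_equal(s[["dE_MM"]], -50)
  expect_equal(s[["dG_solv"]], 10)
  expect_equal(s[["dH"]], -40)

  # without entropy the result is flagged enthalpy-only
  e2 <- gen_energy_components(n_frames = 10, sds = 0, seed = 3)
  m2 <- mmpbsa_combine(e2)
  expect_false(m2$entropy_included)
  expect_equal(m2$dG_bind, -40)

  # stochastic case: mean/sd match a direct per-frame oracle recomputation
  e3 <- gen_energy_components(n_frames = 100, sds = 5, seed = 11)
  m3 <- mmpbsa_combine(e3)
  per_frame <- sapply(sort(unique(e3$frame)), function(f) {
    g <- function(sys) e3[e3$frame == f & e3$system == sys, ]
    co <- g("complex"); re <- g("receptor"); li <- g("ligand")
    sum(co[, 3:7]) - sum(re[, 3:7]) - sum(li[, 3:7])
  })
  expect_equal(m3$dG_bind, mean(per_frame))
  expect_equal(m3$dG_sd, sd(per_frame))

  # linearity and frame-permutation invariance
  e4 <- e3
  e4[, 3:7] <- e4[, 3:7] * 2
  expect_equal(mmpbsa_combine(e4)$dG_bind, 2 * m3$dG_bind)
  e5 <- e3[sample(nrow(e3)), ]
  expect_equal(mmpbsa_combine(e5)$dG_bind, m3$dG_bind)

  # structural errors
  expect_error(mmpbsa_combine(e3[e3$system != "ligand", ]), "incomplete")
})

test_that("trajectories round-trip through multi-MODEL PDB", {
  tr <- gen_trajectory(n_frames = 5, n_residues = 4,
                       amplitudes = c(0, 0, 0.4, 0),
                       ligand_distances = rep(3.5, 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(tr, f)
  tr2 <- read_pdb_trajectory(f)
  expect_equal(dim(tr2$coords), dim(tr$coords))
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-3) # PDB prints 3 decimals
  expect_equal(tr2$atoms$atom, tr$atoms$atom)
  expect_equal(tr2$atoms$resname, tr$atoms$resname)
  expect_equal(rmsf(tr2, align = FALSE)$rmsf, rmsf(tr, align = FALSE)$rmsf,
               tolerance = 1e-3)
})
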