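test_that("displacement current reproduces the hand-evaluated window value", {
  # 10 ions of +1 e, each moving +1 A in a 40 ps window, Lz = 100 A:
  # I = 10 e A / (40 ps * 100 A) = 2.5e-3 e/ps = 0.4005 nA
  atoms <- toy_atoms(10, species = "ION_K", charge = 1)
  f1 <- cbind(0, 0, seq(10, 55, by = 5))
  f2 <- f1; f2[, 3] <- f2[, 3] + 1
  tr <- toy_traj(list(f1, f2), atoms, box = c(100, 100, 100), dt = 40)
  ct <- displacement_current(tr)
  expect_equal(ct$I, 10 * 1 / (40 * 100) * 160.2176634, tolerance = 1e-12)
  expect_equal(ct$I, 0.4005, tolerance = 2e-4)
})

test_that("charge symmetry, linearity and time reversal hold", {
  set.seed(21)
  n <- 8
  atoms <- toy_atoms(n, species = rep(c("ION_K", "ION_CL"), each = n / 2),
                     charge = rep(c(1, -1), each = n / 2))
  frames <- lapply(1:5, function(i) cbind(0, 0, stats::runif(n, 5, 95)))
  tr <- toy_traj(frames, atoms)
  # opposite charges with identical displacements cancel
  trs <- toy_traj(lapply(1:5, function(i) cbind(0, 0, rep(10 + i, n))),
                  atoms)
  expect_equal(displacement_current(trs)$I, rep(0, 4))
  # doubling charges doubles each window current
  atoms2 <- atoms; atoms2$charge <- 2 * atoms$charge
  tr2 <- toy_traj(frames, atoms2)
  expect_equal(displacement_current(tr2)$I, 2 * displacement_current(tr)$I)
  # reversing frame order negates each window current
  trr <- toy_traj(rev(frames), atoms)
  expect_equal(displacement_current(trr)$I,
               -rev(displacement_current(tr)$I))
})

test_that("periodic crossings are minimum-image unwrapped", {
  atoms <- toy_atoms(1, charge = 1)
  tr <- toy_traj(list(cbind(0, 0, 99), cbind(0, 0, 1)), atoms,
                 box = c(100, 100, 100), dt = 40)
  # wrapped jump 99 -> 1 is a +2 A displacement, not -98 A
  expect_equal(displacement_current(tr)$I,
               1 * 2 / (40 * 100) * 160.2176634)
  raw <- displacement_current(tr, unwrap = FALSE)
  expect_equal(raw$I, 1 * (-98) / (40 * 100) * 160.2176634)
})

test_that("species currents decompose the total and empty species are zero", {
  pore <- make_pore(pore_geometry("cylinder", radius = 5, length = 40))
  st <- make_trajectory(pore,
                        electrolyte_spec(n_water = 10, n_k = 6, n_cl = 6,
                                         drift = c(ION_K = 0.02,
                                                   ION_CL = -0.015),
                                         diffusion = 0.02, seed = 9),
                        n_frames = 8)
  tr <- st$trajectory
  tot <- displacement_current(tr)
  iK <- species_current(tr, "ION_K")
  iC <- species_current(tr, "ION_CL")
  iW <- species_current(tr, "WATER")
  expect_equal(iK$I + iC$I + iW$I, tot$I, tolerance = 1e-12)
  expect_equal(iW$I, rep(0, 7))  # water carries no charge
  expect_equal(species_current(tr, "PEPTIDE")$I, rep(0, 7))
  # static Cl: zero Cl trace
  st2 <- make_trajectory(make_pore(pore_geometry("cylinder", 5, 40)),
                         electrolyte_spec(n_k = 4, n_cl = 4, n_water = 0,
                                          drift = c(ION_K = 0.02),
                                          diffusion = 0, seed = 2),
                         n_frames = 4)
  expect_equal(species_current(st2$trajectory, "ION_CL")$I, rep(0, 3))
})

test_that("drift-only trajectories reproduce sum(q v)/Lz to machine precision", {
  pore <- make_pore(pore_geometry("cylinder", radius = 5, length = 50))
  st <- make_trajectory(pore,
                        electrolyte_spec(n_water = 0, n_k = 10, n_cl = 10,
                                         drift = c(ION_K = 0.025,
                                                   ION_CL = -0.025),
                                         diffusion = 0, seed = 4),
                        n_frames = 10)
  expected <- st$ground_truth$expected_current_nA
  # 20 charges at 0.025 A/ps through Lz = 50 A
  expect_equal(expected, 20 * 0.025 / 50 * 160.2176634, tolerance = 1e-12)
  ct <- displacement_current(st$trajectory)
  expect_equal(ct$I, rep(expected, 9), tolerance = 1e-12)
})

test_that("unbiased random-walk ions give zero mean current within 3 SE", {
  pore <- make_pore(pore_geometry("cylinder", radius = 6, length = 60))
  st <- make_trajectory(pore,
                        electrolyte_spec(n_water = 0, n_k = 15, n_cl = 15,
                                         diffusion = 0.1, seed = 31),
                        n_frames = 251)
  ct <- displacement_current(st$trajectory)
  mc <- mean_current(ct, block = 400)
  expect_gte(mc$n_windows, 200)
  expect_lt(abs(mc$mean), 3 * mc$se)
})

test_that("mean current handles discards, blocks and degenerate inputs", {
  atoms <- toy_atoms(1, charge = 1)
  # constant drift: constant trace
  frames <- lapply(0:20, function(i) cbind(0, 0, 10 + 0.5 * i))
  tr <- toy_traj(frames, atoms)
  ct <- displacement_current(tr)
  mc <- mean_current(ct, discard = 200, block = 80)
  expect_equal(mc$mean, 0.5 / (40 * 100) * 160.2176634)
  expect_equal(mc$se, 0)
  # piecewise trace: only the post-discard half is averaged
  zserie <- 10 + cumsum(c(0, rep(1, 10), rep(0.5, 10)))
  tr2 <- toy_traj(lapply(zserie, function(z) cbind(0, 0, z)), atoms)
  ct2 <- displacement_current(tr2)
  mc2 <- mean_current(ct2, discard = 400)
  expect_equal(mc2$mean,
               0.5 / (40 * 100) * 160.2176634)
  expect_error(mean_current(ct, discard = 1e6), "duration")
  # zero-length selection gives an all-zero trace, missing charge errors
  expect_equal(displacement_current(tr, atoms = integer(0))$I, rep(0, 20))
  trb <- tr; trb$atoms$charge <- NA_real_
  expect_error(displacement_current(trb, atoms = 1L), "charge")
})

test_that("blockage arithmetic and degenerate reference", {
  expect_equal(blockage(1, 1)$blockage, 0)
  expect_equal(blockage(0, 1)$blockage, 1)
  expect_equal(blockage(0.4, 1.0)$blockage, 0.6)
  expect_error(blockage(0.4, 0), "degenerate")
})
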