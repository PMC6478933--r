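test_that("amino-acid table is complete and returns the reference volumes", {
  tab <- aa_properties()
  expect_equal(nrow(tab), 20)
  expect_setequal(tab$hclass,
                  c("HYDROPHOBIC", "POLAR", "POSITIVE", "NEGATIVE"))
  expect_true(all(tab$vdw_volume > 0 & tab$apparent_volume > 0 &
                    tab$asa > 0))
  expect_equal(aa_lookup("A")$vdw_volume, 88.6)
  expect_equal(aa_lookup("W")$vdw_volume, 227.8)
  expect_equal(aa_lookup("Q")$vdw_volume, 143.9)
  expect_equal(aa_lookup("F")$vdw_volume, 189.9)
  expect_setequal(tab$code[tab$hclass == "NEGATIVE"], c("D", "E"))
  expect_setequal(tab$code[tab$hclass == "POSITIVE"], c("K", "R"))
  expect_equal(aa_lookup("H")$hclass, "POLAR")
  expect_equal(aa_lookup("H", positive_his = TRUE)$hclass, "POSITIVE")
  expect_error(aa_lookup("B"), "unknown")
})

test_that("replica statistics: mean, SEM, and the single-replica flag", {
  rs <- replica_stats(c(1, 2, 3))
  expect_equal(rs$mean, 2)
  expect_equal(rs$sem, 1 / sqrt(3))
  one <- replica_stats(5)
  expect_equal(one$mean, 5)
  expect_equal(one$sem, 0)
  expect_true(one$single_replica)
  expect_error(replica_stats(numeric(0)), "at least one")
})

test_that("pearson_and_fit agrees with brute-force covariance sums", {
  fit <- pearson_and_fit(1:5, 2 * (1:5) + 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(pearson_and_fit(1:5, -(1:5))$r, -1)
  expect_error(pearson_and_fit(rep(1, 5), 1:5), "degenerate")

  set.seed(8)
  x <- stats::rnorm(40); y <- 0.3 * x + stats::rnorm(40)
  got <- pearson_and_fit(x, y)
  # independent brute-force computation from raw sums
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  expect_equal(got$r, sxy / sqrt(sxx * syy), tolerance = 1e-12)
  expect_equal(got$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(got$intercept, sum(y) / n - sxy / sxx * sum(x) / n,
               tolerance = 1e-12)
})

test_that("class contrast detects shifted classes and handles degenerate ones", {
  set.seed(3)
  # null: same distribution in both classes
  v0 <- stats::rnorm(20)
  cls <- rep(c("HYDROPHOBIC", "POLAR"), each = 10)
  null <- class_contrast(v0, cls)
  expect_lt(abs(null$difference), 1.5)
  # strong shift (5 sigma) is significant at 0.01
  v1 <- c(stats::rnorm(10, 5), stats::rnorm(10, 0))
  shifted <- class_contrast(v1, cls)
  expect_lt(shifted$p_value, 0.01)
  expect_gt(shifted$difference, 3)
  # singleton class is excluded with a warning
  expect_warning(
    res <- class_contrast(c(v1, 0), c(cls, "NEGATIVE")),
    "excluding")
  expect_false("NEGATIVE" %in% names(res$class_means))
  # residue-code lookup path
  bs <- c(A = 0.5, V = 0.55, L = 0.6, I = 0.58, S = 0.3, T = 0.35,
          N = 0.32, Q = 0.4)
  byname <- class_contrast(bs)
  expect_named(byname$class_means, c("HYDROPHOBIC", "POLAR"))
})

test_that("ion/water ratio counts species in the pore region", {
  n <- 106
  atoms <- toy_atoms(n)
  atoms$species <- c(rep("ION_K", 3), rep("ION_CL", 3), rep("WATER", 100))
  inside <- cbind(stats::runif(n, -3, 3), stats::runif(n, -3, 3),
                  stats::runif(n, 10, 40))
  tr <- toy_traj(list(inside, inside), atoms, box = c(20, 20, 50))
  r <- ion_water_ratio(tr, z_range = c(0, 50))
  expect_equal(r$ratio, 0.06)
  # no ions -> 0
  atoms2 <- atoms; atoms2$species[1:6] <- "WATER"
  tr2 <- toy_traj(list(inside), atoms2, box = c(20, 20, 50))
  expect_equal(ion_water_ratio(tr2, z_range = c(0, 50))$ratio, 0)
  expect_error(ion_water_ratio(tr, z_range = c(500, 600)),
               "does not intersect")
  tr3 <- tr; tr3$atoms$species[7:106] <- "OTHER"
  expect_error(ion_water_ratio(tr3, z_range = c(0, 50)), "degenerate")
})

test_that("radius of gyration: closed form, rigid-motion invariance, relaxation", {
  atoms <- toy_atoms(2, mass = 1)
  # two unit masses 2 A apart: Rg = 1 A
  f <- rbind(c(0, 0, 0), c(0, 0, 2))
  tr <- toy_traj(list(f, f), atoms)
  expect_equal(radius_of_gyration(tr, 1:2)$rg, c(1, 1))
  # rigid translation leaves Rg constant
  chain <- cbind(stats::rnorm(6), stats::rnorm(6), stats::rnorm(6))
  atoms6 <- toy_atoms(6, mass = c(12, 1, 14, 16, 12, 1))
  frames <- lapply(0:4, function(i) sweep(chain, 2, c(i, -i, 2 * i), "+"))
  trc <- toy_traj(frames, atoms6)
  rg <- radius_of_gyration(trc, 1:6)$rg
  expect_equal(rg, rep(rg[1], 5), tolerance = 1e-12)

  # exponentially relaxing series (tau = 10 ns): estimate within 50% of
  # the band-entry time tau * log(amplitude/band)
  set.seed(12)
  tau <- 10000  # ps
  tt <- seq(0, 60000, by = 200)
  rgser <- 8 * (1 + 0.15 * exp(-tt / tau)) +
    stats::rnorm(length(tt), sd = 0.02)
  atoms1 <- toy_atoms(2, mass = 1)
  frames <- lapply(rgser, function(r) rbind(c(0, 0, 0), c(0, 0, 2 * r)))
  trg <- new_trajectory(atoms1,
                        t(vapply(frames, function(f) as.vector(t(f)),
                                 numeric(6))),
                        matrix(100, length(frames), 3),
                        frame_interval = 200)
  est <- radius_of_gyration(trg, 1:2)
  t_expected <- tau * log(0.15 / 0.05)
  expect_lt(abs(est$relaxation_time - t_expected), 0.5 * t_expected)
})

test_that("SMD displacement arithmetic converts units correctly", {
  expect_equal(smd_displacement(0.025, 17), 425)
  expect_equal(smd_displacement(1, 1), 1000)
  expect_error(smd_displacement(0, 17), "> 0")
  expect_error(smd_displacement(0.025, -1), "> 0")
})
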