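# Rg, Kabsch superposition, RMSD/RMSF series, intramolecular H-bond counts.

unit_cube_frame <- function(edge = 2) {
  corners <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  mini_frame(frag("DG", 1L, paste0("C", 1:8), rep("C", 8), corners))
}

test_that("radius of gyration matches closed forms", {
  single <- mini_frame(frag("DG", 1L, "C1", "C", rbind(c(1, 2, 3))))
  expect_equal(radius_of_gyration(single, selection = 1), 0)

  two <- mini_frame(frag("DG", 1L, c("C1", "C2"), c("C", "C"),
                         rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(radius_of_gyration(two, selection = 1:2), 1.0)

  cube <- unit_cube_frame(2)
  expect_equal(radius_of_gyration(cube, selection = 1:8), sqrt(3),
               tolerance = 1e-12)

  # mass weighting matters for heteroatomic selections
  mixed <- mini_frame(frag("DG", 1L, c("O1", "C1"), c("O", "C"),
                           rbind(c(0, 0, 0), c(2, 0, 0))))
  rg_w <- radius_of_gyration(mixed, selection = 1:2)
  rg_u <- radius_of_gyration(mixed, selection = 1:2, mass_weighted = FALSE)
  m <- c(15.999, 12.011)
  com <- 2 * m[2] / sum(m)
  expect_equal(rg_w, sqrt(sum(m * c(com^2, (2 - com)^2)) / sum(m)))
  expect_equal(rg_u, 1.0)

  expect_error(radius_of_gyration(single, selection = integer(0)), "empty")
})

test_that("Rg is rigid-motion invariant and scales linearly", {
  fr <- random_polar_frame(5)
  sel <- fr$partition$receptor
  rg0 <- radius_of_gyration(fr, sel)
  set.seed(1)
  fr2 <- transform_frame(fr, random_rotation(), runif(3, -20, 20))
  expect_equal(radius_of_gyration(fr2, sel), rg0, tolerance = 1e-9)
  fr3 <- fr
  fr3$atoms[, c("x", "y", "z")] <- fr3$atoms[, c("x", "y", "z")] * 2.5
  expect_equal(radius_of_gyration(fr3, sel), 2.5 * rg0, tolerance = 1e-9)
})

test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(2)
  x <- matrix(rnorm(18), 6, 3)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  shifted <- sweep(x, 2, c(5, 0, 0), `+`)
  expect_equal(kabsch_superpose(shifted, x)$rmsd, 0, tolerance = 1e-10)

  rotated <- x %*% t(random_rotation())
  expect_equal(kabsch_superpose(rotated, x)$rmsd, 0, tolerance = 1e-10)

  expect_error(kabsch_superpose(x, x[1:5, ]), "differ in size")
  line <- cbind(1:6, 2 * (1:6), -(1:6))
  expect_error(kabsch_superpose(line + 0, line + 0), "degenerate")
})

test_that("Kabsch RMSD matches a quaternion-parameterized minimizer", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(rnorm(18), 6, 3)
    y <- matrix(rnorm(18), 6, 3)
    got <- kabsch_superpose(x, y)$rmsd
    xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
    obj <- function(q) {
      R <- aptaprof:::quat_to_rotation(q)
      sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
    }
    opt <- optim(c(1, 0.1, 0.1, 0.1), obj,
                 control = list(reltol = 1e-15, maxit = 5000))
    expect_equal(got, opt$value, tolerance = 1e-6)
    expect_lte(got, opt$value + 1e-8)  # never worse than the optimizer
  }
})

test_that("Kabsch RMSD is symmetric in its arguments", {
  set.seed(12)
  x <- matrix(rnorm(24), 8, 3)
  y <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_superpose(x, y)$rmsd, kabsch_superpose(y, x)$rmsd,
               tolerance = 1e-9)
})

test_that("superposed RMSD agrees with the bio3d reference implementation", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  y <- x + matrix(rnorm(30, sd = 0.4), 10, 3)
  got <- kabsch_superpose(x, y)$rmsd
  ref <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_lt(abs(got - ref), 5e-4)  # bio3d prints at 3-decimal precision
})

test_that("RMSD series is zero for rigid-motion copies and paired self", {
  spec <- fixture_spec(seed = 6, n_frames = 6,
                       planted = list(plant("hbond", 1:6),
                                      plant("pistack", 1:6)))
  traj <- make_complex(spec)  # pure rigid motion per frame
  series <- rmsd_series(traj)
  expect_true(all(abs(series$value) < 1e-9))
  paired <- rmsd_series(traj, paired = traj)
  expect_true(all(abs(paired$value) < 1e-12))
})

test_that("raw RMSD of a single displaced atom follows sqrt(d^2/N)", {
  base <- mini_frame(frag("DG", 1L, paste0("C", 1:5), rep("C", 5),
                          matrix(seq(0, 14, 1), 5, 3)))
  f2 <- base; f3 <- base
  d <- 1.7
  f3$atoms$x[2] <- f3$atoms$x[2] + d
  traj <- new_trajectory(list(base, f2, f3))
  series <- rmsd_series(traj, selection = 1:5, fit = FALSE)
  expect_equal(series$value[1:2], c(0, 0))
  expect_equal(series$value[3], sqrt(d^2 / 5), tolerance = 1e-12)
})

test_that("RMSF matches its definition and the two-frame closed form", {
  # two frames, one atom oscillating x = +/- 1 A
  a1 <- frag("DG", 1L, paste0("C", 1:4), rep("C", 4),
             rbind(c(1, 0, 0), c(5, 5, 0), c(-5, 5, 0), c(0, -7, 0)))
  f1 <- mini_frame(a1)
  a2 <- a1; a2$x[1] <- -1
  f2 <- mini_frame(a2)
  traj <- new_trajectory(list(f1, f2))
  prof <- rmsf_profile(traj, selection = 1:4, fit = FALSE)
  expect_equal(prof$per_atom$rmsf[1], 1.0, tolerance = 1e-12)
  expect_equal(prof$per_atom$rmsf[2:4], rep(0, 3))

  # static trajectory: all zero
  static <- new_trajectory(list(f1, f1, f1))
  expect_true(all(rmsf_profile(static, selection = 1:4,
                               fit = FALSE)$per_atom$rmsf == 0))

  # random trajectory equals direct recomputation from the definition
  set.seed(31)
  frames <- lapply(1:10, function(i) {
    a <- a1
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + rnorm(12, sd = 0.3)
    mini_frame(a)
  })
  rtraj <- new_trajectory(frames)
  prof_r <- rmsf_profile(rtraj, selection = 1:4, fit = FALSE)
  coords <- simplify2array(lapply(frames, function(f)
    as.matrix(f$atoms[, c("x", "y", "z")])))
  manual <- sqrt(rowMeans(apply(coords, 3, function(m)
    rowSums((m - apply(coords, 1:2, mean))^2))))
  expect_equal(prof_r$per_atom$rmsf, manual, tolerance = 1e-12)
})

test_that("RMSF is order-independent and region means are consistent", {
  spec <- fixture_spec(seed = 14, n_frames = 6, noise_sigma = 0.2,
                       planted = list(plant("hbond", 1:6),
                                      plant("pistack", 1:6)))
  traj <- make_complex(spec)
  prof <- rmsf_profile(traj)
  shuffled <- new_trajectory(traj$frames[c(4, 1, 6, 2, 5, 3)])
  prof_s <- rmsf_profile(shuffled)
  # one-pass mean fitting makes order independence hold to ~1e-4 rather
  # than machine precision (the first-pass reference frame differs)
  expect_equal(prof$per_atom$rmsf, prof_s$per_atom$rmsf, tolerance = 1e-3)

  regions <- list(site = 24, rest = 26)
  prof_reg <- rmsf_profile(traj, regions = regions)
  pr <- prof_reg$per_region
  covered <- prof_reg$per_atom$resid %in% unlist(regions)
  expect_equal(sum(pr$n_atoms * pr$mean_rmsf),
               sum(prof_reg$per_atom$rmsf[covered]), tolerance = 1e-9)
  expect_error(rmsf_profile(traj, regions = list(empty = 999)), "matches no")
})

test_that("intramolecular H-bond counts recover planted base-pair bonds", {
  helix <- make_helix_frame(n_pairs = 6)
  traj <- new_trajectory(list(helix))
  series <- intramolecular_hbond_series(traj)
  expect_equal(series$value, 12)

  apart <- make_helix_frame(n_pairs = 6, separation = 20)
  expect_equal(intramolecular_hbond_series(
    new_trajectory(list(apart)))$value, 0)

  # random receptor soup: counts equal the brute-force enumeration
  gcfg <- interaction_config("gromacs")
  for (seed in c(8, 27)) {
    fr <- random_polar_frame(seed)
    fr_g <- assign_roles(fr, gcfg)
    got <- nrow(detect_hbonds(fr_g, gcfg, c("receptor", "receptor")))
    want <- NROW(brute_hbonds(fr_g, gcfg, c("receptor", "receptor")))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("stat series summaries are recomputable from the values", {
  spec <- fixture_spec(seed = 44, n_frames = 5, noise_sigma = 0.1,
                       planted = list(plant("hbond", 1:5)))
  traj <- make_complex(spec)
  rg <- rg_series(traj)
  s <- attr(rg, "summary")
  expect_equal(unname(s["mean"]), mean(rg$value))
  expect_equal(unname(s["min"]), min(rg$value))
  expect_true(all(rg$value >= 0))
})
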