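# Detector geometry: planted cases, brute-force equivalence, invariances.

cfg <- interaction_config()

test_that("hydrogen bonds obey the distance and angle criteria", {
  build <- function(da) {
    atoms <- rbind(
      frag("EST", 36L, c("O3", "HO3", "C1"), c("O", "H", "C"),
           rbind(c(0, 0, 0), c(0.96, 0, 0), c(-1.36, 0, 0)), "L"),
      frag("DC", 26L, c("O2", "C2"), c("O", "C"),
           rbind(c(da, 0, 0), c(da + 1.23, 0, 0))))
    mini_frame(atoms)
  }
  recs <- detect_hbonds(build(2.9), cfg)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$chem_type, "O–H⋯O")
  expect_equal(recs$d1, 2.9, tolerance = 1e-9)
  expect_equal(recs$a1, 180, tolerance = 1e-9)
  expect_equal(recs$donor_side, "ligand")
  expect_equal(recs$resid, 26L)

  expect_equal(nrow(detect_hbonds(build(6.0), cfg)), 0)

  # same distance, bent geometry below the angle cutoff -> no record
  bent <- build(2.9)
  bent$atoms[bent$atoms$name == "HO3", c("x", "y")] <- c(0, 0.96)
  expect_equal(nrow(detect_hbonds(mini_frame(bent$atoms), cfg)), 0)
})

test_that("each donor hydrogen keeps only its nearest qualifying acceptor", {
  atoms <- rbind(
    frag("EST", 36L, c("O3", "HO3"), c("O", "H"),
         rbind(c(0, 0, 0), c(0.96, 0, 0)), "L"),
    frag("DC", 26L, "O2", "O", rbind(c(2.9, 0, 0))),
    frag("DT", 25L, "O4", "O", rbind(c(3.4, 0.3, 0))))
  recs <- detect_hbonds(mini_frame(atoms), cfg)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$resid, 26L)
})

test_that("detected H-bonds equal exhaustive brute-force enumeration", {
  for (seed in 1:30) {
    fr <- random_polar_frame(seed)
    got <- detect_hbonds(fr, cfg)
    want <- brute_hbonds(fr, cfg)
    expect_equal(nrow(got), NROW(want), info = paste("seed", seed))
    if (NROW(want)) {
      key_got <- sort(paste(got$donor_side, got$rec_atom, got$lig_atom,
                            round(got$d1, 6)))
      key_want <- sort(paste(
        ifelse(want$d %in% fr$partition$ligand, "ligand", "receptor"),
        ifelse(want$d %in% fr$partition$ligand, fr$atoms$name[want$a],
               fr$atoms$name[want$d]),
        ifelse(want$d %in% fr$partition$ligand, fr$atoms$name[want$d],
               fr$atoms$name[want$a]),
        round(want$dda, 6)))
      expect_equal(key_got, key_want, info = paste("seed", seed))
    }
  }
})

test_that("water bridges require the pivot water and type by donor element", {
  spec <- fixture_spec(seed = 2, n_frames = 1,
                       planted = list(plant("water_bridge", 1)))
  fr <- make_complex(spec)$frames[[1]]
  recs <- detect_water_bridges(fr, cfg)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$chem_type, "O–H⋯O–H⋯O")
  expect_equal(recs$donor_side, "ligand")
  expect_false(is.na(recs$water_id))

  # deleting the pivot water removes the bridge
  no_water <- fr$atoms[fr$atoms$resname != "SOL", ]
  expect_equal(nrow(detect_water_bridges(mini_frame(no_water), cfg)), 0)

  # base-donor variant types as N-H...O-H...O
  spec_n <- fixture_spec(seed = 2, n_frames = 1,
                         planted = list(plant("water_bridge", 1,
                                              chem = "N–H⋯O–H⋯O")))
  recs_n <- detect_water_bridges(make_complex(spec_n)$frames[[1]], cfg)
  expect_equal(nrow(recs_n), 1)
  expect_equal(recs_n$chem_type, "N–H⋯O–H⋯O")
  expect_equal(recs_n$donor_side, "receptor")
})

test_that("water bridges equal the brute-force quadruple enumeration", {
  for (seed in 31:50) {
    fr <- random_polar_frame(seed, n_waters = 6)
    got <- detect_water_bridges(fr, cfg)
    want <- brute_water_bridges(fr, cfg)
    expect_equal(nrow(got), NROW(want), info = paste("seed", seed))
    if (NROW(want)) {
      expect_equal(sort(paste(got$donor_side, got$water_id)),
                   sort(paste(want$donor_side, fr$atoms$resid[want$w])),
                   info = paste("seed", seed))
    }
  }
})

test_that("bridges are the composition of their two hydrogen-bond legs", {
  # every reported bridge's legs must individually satisfy the bridge
  # distance window, and the donor leg must be a genuine H-bond to the water
  planted <- make_complex(fixture_spec(seed = 1, n_frames = 1,
                                       planted = list(plant("water_bridge",
                                                            1))))
  frames <- c(list(planted$frames[[1]]),
              lapply(c(7, 19, 42), random_polar_frame, n_waters = 8))
  checked <- 0L
  for (fr in frames) {
    recs <- detect_water_bridges(fr, cfg)
    if (!nrow(recs)) next
    checked <- checked + 1L
    expect_true(all(recs$d1 >= cfg$waterbridge_dist_min &
                      recs$d1 <= cfg$waterbridge_dist_max))
    expect_true(all(recs$d2 >= cfg$waterbridge_dist_min &
                      recs$d2 <= cfg$waterbridge_dist_max))
    expect_true(all(recs$a1 >= cfg$waterbridge_theta_min))
    expect_true(all(recs$a2 >= cfg$waterbridge_omega_min &
                      recs$a2 <= cfg$waterbridge_omega_max))
  }
  expect_gte(checked, 1L)  # the planted bridge guarantees coverage
})

test_that("ring plane fitting is exact on symmetric input", {
  hexagon <- t(vapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  fit <- fit_ring_plane(hexagon)
  expect_equal(fit$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$normal, c(0, 0, 1), tolerance = 1e-12)

  shifted <- sweep(hexagon, 2, c(1, 2, 3), `+`)
  fit2 <- fit_ring_plane(shifted)
  expect_equal(fit2$centroid, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(fit2$normal, fit$normal, tolerance = 1e-12)

  expect_error(fit_ring_plane(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("plane normal of a puckered ring matches a numeric minimizer", {
  set.seed(4)
  puckered <- t(vapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3),
      runif(1, -0.1, 0.1)), numeric(3)))
  fit <- fit_ring_plane(puckered)
  # independent oracle: minimize sum of squared plane distances over
  # spherical angles of the normal
  obj <- function(p) {
    n <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    sum((sweep(puckered, 2, colMeans(puckered)) %*% n)^2)
  }
  opt <- optim(c(0.1, 0.1), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14))
  n_opt <- c(sin(opt$par[1]) * cos(opt$par[2]),
             sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[1]))
  if (n_opt[3] < 0) n_opt <- -n_opt
  expect_equal(abs(sum(fit$normal * n_opt)), 1, tolerance = 1e-6)
  expect_lt(acos(min(1, abs(fit$normal[3]))) * 180 / pi, 5)
})

test_that("pi-stacking distinguishes parallel, offset and T-shaped geometry", {
  stack_frame <- function(dz, lateral = 0, tilt = 0) {
    base <- aptaprof:::thymine_template(24L)
    m <- as.matrix(base[, c("x", "y", "z")])
    if (tilt != 0) {
      th <- tilt * pi / 180
      R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                  3, 3, byrow = TRUE)
      m <- m %*% t(R)
    }
    m <- sweep(m, 2, c(lateral, 0, dz), `+`)
    base$x <- m[, 1]; base$y <- m[, 2]; base$z <- m[, 3]
    mini_frame(rbind(base, ligand_template()))
  }
  ideal <- detect_pistacking(stack_frame(3.5), cfg)
  expect_equal(nrow(ideal), 1)
  expect_equal(ideal$chem_type, "parallel")
  expect_equal(ideal$d1, 3.5, tolerance = 1e-6)

  # coplanar rings far apart laterally: offset violation
  expect_equal(nrow(detect_pistacking(stack_frame(0, lateral = 4), cfg)), 0)

  # perpendicular rings at 4.8 A with small offset: T-shaped
  tshape <- detect_pistacking(stack_frame(4.8, tilt = 90), cfg)
  expect_equal(nrow(tshape), 1)
  expect_equal(tshape$chem_type, "T-shaped")

  # intermediate tilt (45 deg) belongs to neither class
  expect_equal(nrow(detect_pistacking(stack_frame(4.0, tilt = 45), cfg)), 0)
})

test_that("pi-stacking agrees with an independent PCA-based oracle", {
  set.seed(99)
  for (rep in 1:15) {
    base <- aptaprof:::thymine_template(24L)
    m <- as.matrix(base[, c("x", "y", "z")])
    R <- random_rotation()
    m <- m %*% t(R)
    m <- sweep(m, 2, c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 3, 6)), `+`)
    base$x <- m[, 1]; base$y <- m[, 2]; base$z <- m[, 3]
    fr <- assign_roles(mini_frame(rbind(base, ligand_template())), cfg)
    got <- detect_pistacking(fr, cfg)
    want <- brute_pistack(fr, cfg)
    expect_equal(nrow(got), NROW(want), info = paste("rep", rep))
    if (NROW(want))
      expect_equal(sort(got$chem_type), sort(want$type))
  }
})

test_that("hydrophobic contacts reduce to one record per residue/ligand atom", {
  cfg_l <- interaction_config(strict_hydrogens = FALSE)  # H-less toy frame
  atoms <- rbind(
    frag("EST", 36L, "C1", "C", rbind(c(0, 0, 0)), "L"),
    frag("DT", 24L, c("C5'", "C4'", "C3'"), c("C", "C", "C"),
         rbind(c(3.2, 0, 0), c(3.8, 1.0, 0), c(4.6, 1.8, 0))))
  recs <- detect_hydrophobic(mini_frame(atoms), cfg_l)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$d1, 3.2, tolerance = 1e-9)
  expect_equal(recs$rec_atom, "C5'")

  far <- atoms
  far[far$resname == "DT", "x"] <- far[far$resname == "DT", "x"] + 5
  expect_equal(nrow(detect_hydrophobic(mini_frame(far), cfg_l)), 0)

  for (seed in 51:70) {
    fr <- random_polar_frame(seed, n_groups = 16)
    got <- detect_hydrophobic(fr, cfg)
    want <- brute_hydrophobic(fr, cfg)
    expect_equal(nrow(got), NROW(want), info = paste("seed", seed))
    if (NROW(want))
      expect_equal(sort(round(got$d1, 9)), sort(round(want$d, 9)))
  }
})

test_that("profiling concatenates per-frame detections deterministically", {
  spec <- fixture_spec(seed = 13, n_frames = 5,
                       planted = list(plant("hbond", 1:4)))
  traj <- make_complex(spec)
  recs <- profile_trajectory(traj)
  expect_equal(sum(recs$iclass == "hbond"), 4)
  expect_equal(sort(unique(recs$frame[recs$iclass == "hbond"])), 1:4)

  # full profile equals the union of per-frame detector calls
  per_frame <- lapply(traj$frames, function(f) {
    f <- assign_roles(f, cfg)
    rbind(detect_hbonds(f, cfg), detect_water_bridges(f, cfg),
          detect_pistacking(f, cfg), detect_hydrophobic(f, cfg))
  })
  manual <- do.call(rbind, per_frame)
  expect_equal(nrow(recs), nrow(manual))
  expect_equal(sort(paste(recs$frame, recs$iclass, recs$rec_atom)),
               sort(paste(manual$frame, manual$iclass, manual$rec_atom)))
})

test_that("enlarging distance maxima never removes records (monotonicity)", {
  for (seed in c(3, 17)) {
    fr <- random_polar_frame(seed)
    tight <- interaction_config(hbond_da_max = 3.0, hydrophobic_max = 3.2)
    loose <- interaction_config(hbond_da_max = 4.5, hydrophobic_max = 4.5)
    key <- function(r) paste(r$iclass, r$rec_atom, r$lig_atom, r$donor_side)
    expect_true(all(key(detect_hbonds(fr, tight)) %in%
                      key(detect_hbonds(fr, loose))))
    expect_true(all(key(detect_hydrophobic(fr, tight)) %in%
                      key(detect_hydrophobic(fr, loose))))
  }
})

test_that("records are invariant under rigid motion of the whole frame", {
  spec <- fixture_spec(seed = 23, n_frames = 1,
                       planted = list(plant("hbond", 1), plant("pistack", 1),
                                      plant("water_bridge", 1),
                                      plant("hydrophobic", 1)))
  fr <- make_complex(spec)$frames[[1]]
  set.seed(8)
  fr2 <- transform_frame(fr, random_rotation(), runif(3, -10, 10))
  profile1 <- rbind(detect_hbonds(assign_roles(fr, cfg), cfg),
                    detect_water_bridges(assign_roles(fr, cfg), cfg),
                    detect_pistacking(assign_roles(fr, cfg), cfg),
                    detect_hydrophobic(assign_roles(fr, cfg), cfg))
  profile2 <- rbind(detect_hbonds(assign_roles(fr2, cfg), cfg),
                    detect_water_bridges(assign_roles(fr2, cfg), cfg),
                    detect_pistacking(assign_roles(fr2, cfg), cfg),
                    detect_hydrophobic(assign_roles(fr2, cfg), cfg))
  expect_equal(nrow(profile1), nrow(profile2))
  expect_equal(profile1$d1, profile2$d1, tolerance = 1e-6)
  expect_equal(profile1$d2, profile2$d2, tolerance = 1e-6)
  expect_equal(profile1$a1, profile2$a1, tolerance = 1e-6)
})

test_that("records survive a TSV round trip unchanged", {
  spec <- fixture_spec(seed = 4, n_frames = 3,
                       planted = list(plant("hbond", 1:3),
                                      plant("water_bridge", 2)))
  recs <- profile_trajectory(make_complex(spec))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(recs, path)
  back <- read_records(path)
  expect_equal(back$iclass, recs$iclass)
  expect_equal(back$chem_type, recs$chem_type)
  expect_equal(back$d1, recs$d1, tolerance = 1e-9)
})
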