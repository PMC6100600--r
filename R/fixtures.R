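# Synthetic fixtures: small receptor-ligand-water systems with planted,
# geometrically exact interactions and rigid-body trajectory motion. These
# are geometric test articles, not physically realistic DNA dynamics.

# ---- ligand template: a two-anchor diol mimic with one aromatic ring ----
# Benzene ring in the z = 0 plane centred at the origin; a hydroxyl anchor
# ("3") on the -x side, an aliphatic chain ending in a second hydroxyl
# ("17-beta") on the +x side. Geometry uses standard bond lengths so the
# distance-based bond inference reproduces the intended connectivity.
ligand_template <- function(resid = 36L, chain = "L") {
  hex <- function(angle_deg, radius)
    c(radius * cos(angle_deg * pi / 180), radius * sin(angle_deg * pi / 180), 0)
  atoms <- rbind(
    data.frame(name = "C1", element = "C", t(hex(180, 1.39))),
    data.frame(name = "C2", element = "C", t(hex(120, 1.39))),
    data.frame(name = "C3", element = "C", t(hex(60, 1.39))),
    data.frame(name = "C4", element = "C", t(hex(0, 1.39))),
    data.frame(name = "C5", element = "C", t(hex(300, 1.39))),
    data.frame(name = "C6", element = "C", t(hex(240, 1.39))),
    data.frame(name = "H2", element = "H", t(hex(120, 2.47))),
    data.frame(name = "H3", element = "H", t(hex(60, 2.47))),
    data.frame(name = "H5", element = "H", t(hex(300, 2.47))),
    data.frame(name = "H6", element = "H", t(hex(240, 2.47))),
    data.frame(name = "O3", element = "O", t(c(-2.75, 0, 0))),
    data.frame(name = "HO3", element = "H", t(c(-3.71, 0, 0))),
    data.frame(name = "C7", element = "C", t(c(2.89, 0, 0))),
    data.frame(name = "C8", element = "C", t(c(4.00, 0.90, 0))),
    data.frame(name = "C17", element = "C", t(c(5.50, 0.30, 0))),
    data.frame(name = "O17", element = "O", t(c(6.86, 0.30, 0))),
    data.frame(name = "HO17", element = "H", t(c(7.82, 0.30, 0))))
  names(atoms)[3:5] <- c("x", "y", "z")
  atoms$resname <- "EST"
  atoms$resid <- resid
  atoms$chain <- chain
  atoms
}

# A planar thymine-like base: ring template atoms N1,C2,N3,C4,C5,C6 plus
# substituents; used as the pi-stacking partner.
thymine_template <- function(resid, chain = "A", z = 0) {
  ang <- c(N1 = 0, C2 = 60, N3 = 120, C4 = 180, C5 = 240, C6 = 300)
  rad <- 1.37
  pos <- function(a, r) unname(c(r * cos(a * pi / 180),
                                 r * sin(a * pi / 180), z))
  atoms <- rbind(
    data.frame(name = "N1", element = "N", t(pos(ang["N1"], rad))),
    data.frame(name = "C2", element = "C", t(pos(ang["C2"], rad))),
    data.frame(name = "N3", element = "N", t(pos(ang["N3"], rad))),
    data.frame(name = "C4", element = "C", t(pos(ang["C4"], rad))),
    data.frame(name = "C5", element = "C", t(pos(ang["C5"], rad))),
    data.frame(name = "C6", element = "C", t(pos(ang["C6"], rad))),
    data.frame(name = "O2", element = "O", t(pos(ang["C2"], 2.60))),
    data.frame(name = "O4", element = "O", t(pos(ang["C4"], 2.60))),
    data.frame(name = "C7", element = "C", t(pos(ang["C5"], 2.87))),
    data.frame(name = "H3", element = "H", t(pos(ang["N3"], 2.38))),
    data.frame(name = "H6", element = "H", t(pos(ang["C6"], 2.45))))
  names(atoms)[3:5] <- c("x", "y", "z")
  atoms$resname <- "DT"
  atoms$resid <- resid
  atoms$chain <- chain
  atoms
}

fragment <- function(resname, resid, names, elements, coords, chain = "A") {
  df <- as.data.frame(coords)
  names(df) <- c("x", "y", "z")
  df$name <- names
  df$element <- elements
  df$resname <- resname
  df$resid <- resid
  df$chain <- chain
  df
}

# Planting slots. Each planted interaction class/subtype occupies its own
# approach direction around the ligand so classes never interfere; the
# geometry satisfies the default thresholds with >= 10 % margin, and moving
# a slot's atoms +12 A outward violates them with >= 10 % margin.
.fixture_slots <- function() {
  u <- function(...) c(...)
  list(
    `hbond/O` = list(
      resid = 26L,
      atoms = fragment("DC", 26L, c("O2", "C2"), c("O", "C"),
                       rbind(u(-5.65, 0, 0), u(-6.88, 0, 0))),
      away = u(-1, 0, 0)),
    `hbond/N` = list(
      resid = 12L,
      atoms = fragment("DT", 12L, c("N4", "H4", "C4"), c("N", "H", "C"),
                       rbind(u(-2.75, 2.9, 0), u(-2.75, 1.9, 0),
                             u(-2.75, 4.3, 0))),
      away = u(0, 1, 0)),
    `water_bridge/O` = list(
      resid = 25L,
      atoms = rbind(
        fragment("DT", 25L, c("O4", "C4"), c("O", "C"),
                 rbind(u(10.64, 3.20, 0), u(10.96, 4.39, 0))),
        fragment("SOL", 201L, c("OW", "HW1", "HW2"), c("O", "H", "H"),
                 rbind(u(9.86, 0.30, 0),
                       u(9.86 + 0.96 * 0.2588, 0.30 + 0.96 * 0.9659, 0),
                       u(9.86 + 0.96 * 0.2588, 0.30 - 0.96 * 0.9659, 0)),
                 chain = "W")),
      away = u(1, 0, 0)),
    `water_bridge/N` = list(
      resid = 23L,
      atoms = rbind(
        fragment("DG", 23L, c("N2", "H21", "C2"), c("N", "H", "C"),
                 rbind(u(3.9620, -3.4769, 0), u(4.9280, -3.2179, 0),
                       u(2.6096, -3.8395, 0))),
        fragment("SOL", 202L, c("OW", "HW1", "HW2"), c("O", "H", "H"),
                 rbind(u(6.86, -2.70, 0), u(6.86, -1.74, 0),
                       u(6.86 - 0.68, -3.38, 0)), chain = "W")),
      away = u(0, -1, 0)),
    `pistack/parallel` = list(
      resid = 24L,
      atoms = thymine_template(24L, z = 4.5),
      away = u(0, 0, 1)),
    `hydrophobic/C` = list(
      resid = 11L,
      atoms = fragment("DG", 11L, c("C2'", "C3'"), c("C", "C"),
                       rbind(u(-2.445, -4.235, 0), u(-3.195, -5.534, 0))),
      away = u(-0.5, -0.866, 0)))
}

.slot_key <- function(iclass, chem) {
  sub <- switch(iclass,
    hbond = if (!is.null(chem) && startsWith(chem, "N")) "N" else "O",
    water_bridge = if (!is.null(chem) && startsWith(chem, "N")) "N" else "O",
    pistack = "parallel",
    hydrophobic = "C",
    stop("unknown interaction class: ", iclass))
  paste(iclass, sub, sep = "/")
}

#' Declare a planted interaction for a fixture
#'
#' @param iclass one of `"hbond"`, `"water_bridge"`, `"pistack"`,
#'   `"hydrophobic"`.
#' @param frames frame indices (1-based) in which the interaction is
#'   present; in all other frames its geometry is violated by a wide margin.
#' @param chem optional chemical subtype: for hbond and water_bridge, a
#'   label starting with `"N"` plants the base-donor variant
#'   (N-H...O / N-H...O-H...O) instead of the default hydroxyl-donor one.
#' @return a planting descriptor for [fixture_spec()].
#' @export
plant <- function(iclass, frames, chem = NULL) {
  list(iclass = iclass, frames = as.integer(frames), chem = chem,
       slot = .slot_key(iclass, chem))
}

#' Fixture specification
#'
#' Defines a deterministic synthetic receptor-ligand-water system: which
#' interactions are planted in which frames, the rigid-body motion applied
#' per frame, optional Gaussian coordinate noise, and decoy waters placed
#' at least 6 A from every solute atom.
#'
#' @param seed integer seed controlling motion, noise and decoy placement.
#' @param n_frames number of frames.
#' @param planted list of [plant()] descriptors; at most one per
#'   class/subtype slot (conflicting geometry is refused).
#' @param noise_sigma per-atom Gaussian noise, A (default 0: planted
#'   geometry is exact up to PDB precision).
#' @param n_decoy_waters number of far-away decoy waters.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_frames = 1L, planted = list(),
                         noise_sigma = 0, n_decoy_waters = 0L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  slots <- vapply(planted, function(p) p$slot, "")
  if (anyDuplicated(slots))
    stop("infeasible planting: conflicting geometry for slot(s) ",
         paste(unique(slots[duplicated(slots)]), collapse = ", "))
  for (p in planted) {
    if (any(p$frames < 1 | p$frames > n_frames))
      stop("planted frames outside 1..n_frames")
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 planted = planted, noise_sigma = noise_sigma,
                 n_decoy_waters = as.integer(n_decoy_waters)),
            class = "fixture_spec")
}

#' Build a fixture trajectory with planted interactions
#'
#' Deterministic given the spec's seed: profiling the output with the
#' default configuration recovers exactly the planted (class, frame)
#' multiset. Planted geometries satisfy their class's default thresholds
#' with at least 10 % margin (asserted at build time); in frames where an
#' interaction is absent, its partner fragment is moved 12 A outward, which
#' violates every distance window by far more than 10 %.
#'
#' @param spec a [fixture_spec()].
#' @return an `md_trajectory`; `attr(, "planted")` carries the expected
#'   (iclass, frame) data.frame, `attr(, "remarks")` the seed provenance
#'   stamp that [write_pdb_trajectory()] emits as REMARK records.
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  slots <- .fixture_slots()
  lig <- ligand_template()
  used <- lapply(spec$planted, function(p) slots[[p$slot]])
  rec_atoms <- lapply(used, function(s) s$atoms)
  base <- do.call(rbind, c(rec_atoms, list(lig)))
  .assert_planted_margins(spec$planted)

  with_seed(spec$seed, {
    if (spec$n_decoy_waters > 0) {
      solute_xyz <- as.matrix(base[, c("x", "y", "z")])
      decoys <- list()
      wi <- 0L
      while (wi < spec$n_decoy_waters) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pos <- dir * stats::runif(1, 12, 16)
        alld <- sqrt(rowSums(sweep(solute_xyz, 2, pos)^2))
        if (min(alld) < 6) next
        wi <- wi + 1L
        hdir <- stats::rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
        decoys[[wi]] <- fragment(
          "SOL", 300L + wi, c("OW", "HW1", "HW2"), c("O", "H", "H"),
          rbind(pos, pos + 0.96 * hdir, pos - 0.96 * hdir), chain = "W")
      }
      base <- rbind(base, do.call(rbind, decoys))
    }
    base <- rbind(base, fragment("NA", 401L, "NA", "NA",
                                 rbind(c(20, 20, 20)), chain = "I"),
                  fragment("NA", 402L, "NA", "NA",
                           rbind(c(-20, -20, -20)), chain = "I"))
    base <- base[order(match(base$chain, c("A", "L", "W", "I")),
                       base$resid), ]
    base$serial <- seq_len(nrow(base))
    rownames(base) <- NULL

    frames <- vector("list", spec$n_frames)
    for (fi in seq_len(spec$n_frames)) {
      a <- base
      for (p in spec$planted) {
        if (fi %in% p$frames) next
        s <- slots[[p$slot]]
        move <- a$resid %in% unique(s$atoms$resid) &
          a$chain %in% unique(s$atoms$chain)
        shift <- 12 * s$away / sqrt(sum(s$away^2))
        a$x[move] <- a$x[move] + shift[1]
        a$y[move] <- a$y[move] + shift[2]
        a$z[move] <- a$z[move] + shift[3]
      }
      R <- quat_to_rotation(stats::rnorm(4))
      t_vec <- stats::runif(3, -5, 5)
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, t_vec, `+`)
      if (spec$noise_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$noise_sigma),
                            ncol = 3)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      frames[[fi]] <- new_frame(a, index = fi, ligand_resnames = "EST")
    }
    traj <- new_trajectory(frames)
    attr(traj, "planted") <- planted_multiset(spec)
    attr(traj, "remarks") <-
      c(sprintf("fixture seed %d n_frames %d", spec$seed, spec$n_frames),
        vapply(spec$planted, function(p)
          sprintf("planted %s frames %s", p$slot,
                  paste(p$frames, collapse = ",")), ""))
    traj
  })
}

#' Expected (class, frame) multiset of a fixture spec
#' @param spec a [fixture_spec()].
#' @return data.frame with columns `iclass`, `frame`, sorted.
#' @export
planted_multiset <- function(spec) {
  if (!length(spec$planted))
    return(data.frame(iclass = character(0), frame = integer(0)))
  df <- do.call(rbind, lapply(spec$planted, function(p)
    data.frame(iclass = p$iclass, frame = p$frames)))
  df <- df[order(df$iclass, df$frame), ]
  rownames(df) <- NULL
  df
}

# Build-time guard: planted geometry must clear every threshold by >= 10 %.
# The slot geometries are fixed, so this is a literal numeric re-check of
# the construction against the default config.
.assert_planted_margins <- function(planted) {
  cfg <- interaction_config()
  for (p in planted) {
    ok <- switch(p$slot,
      `hbond/O` = 2.90 <= 0.9 * cfg$hbond_da_max,
      `hbond/N` = 2.90 <= 0.9 * cfg$hbond_da_max,
      `water_bridge/O` = ,
      `water_bridge/N` = 3.0 <= 0.9 * cfg$waterbridge_dist_max &&
        3.0 >= 1.1 * cfg$waterbridge_dist_min &&
        105 >= 1.1 * cfg$waterbridge_omega_min &&
        105 <= 0.9 * cfg$waterbridge_omega_max,
      `pistack/parallel` = 4.5 <= 0.9 * cfg$pistack_center_max,
      `hydrophobic/C` = 3.5 <= 0.9 * cfg$hydrophobic_max,
      FALSE)
    if (!isTRUE(ok))
      stop("infeasible planting: slot ", p$slot,
           " cannot satisfy thresholds with the required margin")
  }
  invisible(TRUE)
}

#' Rigid-body trajectory from a base frame
#'
#' Frame i applies transform i (rotation + translation) to the base frame,
#' plus optional per-atom Gaussian noise. With zero noise the
#' superposed RMSD to frame 1 is zero for every frame.
#'
#' @param base_frame an `md_frame`.
#' @param transforms list of `list(rotation = 3x3, translation = 3-vector)`;
#'   `NULL` generates `n_frames` random rigid transforms from `seed`.
#' @param n_frames used when `transforms` is `NULL`.
#' @param noise_sigma Gaussian noise sd in A.
#' @param seed RNG seed for generated transforms and noise.
#' @return an `md_trajectory`.
#' @export
make_rigid_trajectory <- function(base_frame, transforms = NULL,
                                  n_frames = length(transforms),
                                  noise_sigma = 0, seed = 1L) {
  with_seed(seed, {
    if (is.null(transforms)) {
      transforms <- replicate(n_frames, list(
        rotation = quat_to_rotation(stats::rnorm(4)),
        translation = stats::runif(3, -5, 5)), simplify = FALSE)
    }
    xyz0 <- coords_matrix(base_frame)
    frames <- lapply(seq_along(transforms), function(i) {
      tr <- transforms[[i]]
      xyz <- apply_transform(xyz0, tr$rotation, tr$translation)
      if (noise_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                            ncol = 3)
      fr <- base_frame
      fr$roles <- NULL
      fr$index <- i
      fr$atoms$x <- xyz[, 1]; fr$atoms$y <- xyz[, 2]; fr$atoms$z <- xyz[, 3]
      fr
    })
    new_trajectory(frames)
  })
}

#' Receptor-only helix fixture with planted base-pair hydrogen bonds
#'
#' `n_pairs` residue pairs, each contributing exactly two near-linear
#' N-H...O hydrogen bonds at 2.9 A (a Watson-Crick-like double-bond
#' geometry), stacked 6 A apart -- the test bed for intramolecular H-bond
#' counting. `separation` pushes the two strands apart to break all bonds.
#'
#' @param n_pairs number of base pairs.
#' @param separation extra distance (A) inserted between the paired
#'   residues (default 0: all bonds formed).
#' @return an `md_frame`.
#' @export
make_helix_frame <- function(n_pairs = 6, separation = 0) {
  rows <- list()
  for (k in seq_len(n_pairs)) {
    z <- 6 * (k - 1)
    sep <- separation
    rows[[length(rows) + 1]] <- fragment(
      "DA", 2L * k - 1L, c("N1", "H1", "O1"), c("N", "H", "O"),
      rbind(c(0, 0, z), c(1, 0, z), c(0, 3, z)))
    rows[[length(rows) + 1]] <- fragment(
      "DT", 2L * k, c("O2", "N2", "H2"), c("O", "N", "H"),
      rbind(c(2.9 + sep, 0, z), c(2.9 + sep, 3, z), c(1.9 + sep, 3, z)))
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_frame(atoms, ligand_resnames = "EST")
}

#' Read a fixture spec from JSON
#'
#' Schema: `{"seed": int, "n_frames": int, "noise_sigma": num,
#' "n_decoy_waters": int, "planted": [{"iclass": str, "frames": [ints],
#' "chem": str|null}, ...]}`.
#'
#' @param path JSON file.
#' @return a [fixture_spec()].
#' @export
read_fixture_spec <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  planted <- lapply(js$planted %||% list(), function(p)
    plant(p$iclass, unlist(p$frames), p$chem %||% NULL))
  fixture_spec(seed = js$seed %||% 1L, n_frames = js$n_frames %||% 1L,
               planted = planted, noise_sigma = js$noise_sigma %||% 0,
               n_decoy_waters = js$n_decoy_waters %||% 0L)
}
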