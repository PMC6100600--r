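# Test helpers: tiny frame builders and independent brute-force oracles.
# The oracles deliberately re-derive every quantity from the raw geometry
# with plain loops, sharing only the role flags with the implementation.

mini_frame <- function(atoms, ligand_resnames = "EST") {
  atoms$serial <- seq_len(nrow(atoms))
  new_frame(atoms, ligand_resnames = ligand_resnames)
}

frag <- function(resname, resid, names, elements, coords, chain = "A") {
  df <- as.data.frame(coords)
  colnames(df) <- c("x", "y", "z")
  df$name <- names; df$element <- elements
  df$resname <- resname; df$resid <- resid; df$chain <- chain
  df
}

xyz_of <- function(frame, i) unlist(frame$atoms[i, c("x", "y", "z")])

deg_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# ---- brute-force H-bond oracle: enumerate all (D, H, A) triples, apply the
# two thresholds, then reduce each donor hydrogen to its nearest acceptor.
brute_hbonds <- function(frame, config, between = c("ligand", "receptor")) {
  fl <- frame$roles$flags
  part <- frame$partition
  a <- frame$atoms
  same <- identical(between[1], between[2])
  triples <- NULL
  sides <- if (same) list(between) else list(between, rev(between))
  for (sd in sides) {
    donors <- intersect(part[[sd[1]]], which(fl$donor_heavy))
    acceptors <- intersect(part[[sd[2]]], which(fl$acceptor))
    for (dd in donors) for (h in which(frame$roles$h_parent == dd)) {
      for (aa in acceptors) {
        if (aa == dd) next
        if (same && a$resid[aa] == a$resid[dd] &&
            a$chain[aa] == a$chain[dd]) next
        dda <- sqrt(sum((xyz_of(frame, dd) - xyz_of(frame, aa))^2))
        ang <- deg_angle(xyz_of(frame, dd), xyz_of(frame, h),
                         xyz_of(frame, aa))
        if (dda <= config$hbond_da_max && ang >= config$hbond_angle_min)
          triples <- rbind(triples,
                           data.frame(d = dd, h = h, a = aa, dda = dda,
                                      serial_a = a$serial[aa]))
      }
    }
  }
  if (is.null(triples)) return(triples)
  keep <- do.call(rbind, lapply(split(triples, paste(triples$d, triples$h)),
                                function(g) {
    g <- g[order(g$dda, g$serial_a), ]
    g[1, ]
  }))
  keep[order(keep$d, keep$h), c("d", "h", "a", "dda")]
}

# ---- brute-force water-bridge oracle over all (D, H, W, A) quadruples.
brute_water_bridges <- function(frame, config) {
  fl <- frame$roles$flags
  part <- frame$partition
  a <- frame$atoms
  out <- NULL
  waters <- which(fl$water_o)
  for (sd in list(c("ligand", "receptor"), c("receptor", "ligand"))) {
    donors <- intersect(part[[sd[1]]], which(fl$donor_heavy))
    acceptors <- intersect(part[[sd[2]]], which(fl$acceptor))
    for (dd in donors) for (h in which(frame$roles$h_parent == dd)) {
      for (w in waters) {
        d1 <- sqrt(sum((xyz_of(frame, dd) - xyz_of(frame, w))^2))
        if (d1 < config$waterbridge_dist_min ||
            d1 > config$waterbridge_dist_max) next
        theta <- deg_angle(xyz_of(frame, dd), xyz_of(frame, h),
                           xyz_of(frame, w))
        if (theta < config$waterbridge_theta_min) next
        for (aa in acceptors) {
          d2 <- sqrt(sum((xyz_of(frame, aa) - xyz_of(frame, w))^2))
          if (d2 < config$waterbridge_dist_min ||
              d2 > config$waterbridge_dist_max) next
          omega <- deg_angle(xyz_of(frame, aa), xyz_of(frame, w),
                             xyz_of(frame, h))
          if (omega < config$waterbridge_omega_min ||
              omega > config$waterbridge_omega_max) next
          out <- rbind(out, data.frame(d = dd, h = h, w = w, a = aa,
                                       donor_side = sd[1]))
        }
      }
    }
  }
  out
}

# ---- brute-force hydrophobic oracle: all C-C pairs, group-by minimum.
brute_hydrophobic <- function(frame, config) {
  fl <- frame$roles$flags
  part <- frame$partition
  a <- frame$atoms
  lc <- intersect(part$ligand, which(fl$hydrophobic_c))
  rc <- intersect(part$receptor, which(fl$hydrophobic_c))
  pairs <- NULL
  for (li in lc) for (ri in rc) {
    dd <- sqrt(sum((xyz_of(frame, li) - xyz_of(frame, ri))^2))
    if (dd <= config$hydrophobic_max)
      pairs <- rbind(pairs, data.frame(
        key = paste(a$chain[ri], a$resid[ri], a$name[li], sep = "/"),
        li = li, ri = ri, d = dd))
  }
  if (is.null(pairs)) return(pairs)
  red <- do.call(rbind, lapply(split(pairs, pairs$key), function(g)
    g[which.min(g$d), ]))
  red[order(red$key), ]
}

# ---- brute-force pi-stacking oracle via an independent plane fit (PCA).
brute_pistack <- function(frame, config) {
  rings <- frame$roles$rings
  part <- frame$partition
  rec <- Filter(function(r) r$atoms[1] %in% part$receptor, rings)
  lig <- Filter(function(r) r$atoms[1] %in% part$ligand, rings)
  plane <- function(idx) {
    m <- as.matrix(frame$atoms[idx, c("x", "y", "z")])
    p <- stats::prcomp(m, center = TRUE)
    list(c = colMeans(m), n = p$rotation[, 3])
  }
  out <- NULL
  for (rr in rec) for (lr in lig) {
    p1 <- plane(rr$atoms); p2 <- plane(lr$atoms)
    dc <- sqrt(sum((p1$c - p2$c)^2))
    if (dc > config$pistack_center_max) next
    v <- p2$c - p1$c
    off <- min(sqrt(max(0, sum(v^2) - sum(v * p1$n)^2)),
               sqrt(max(0, sum(v^2) - sum(v * p2$n)^2)))
    if (off > config$pistack_offset_max) next
    ang <- acos(min(1, abs(sum(p1$n * p2$n)))) * 180 / pi
    type <- if (ang <= config$pistack_parallel_angle_max) "parallel"
      else if (ang >= config$pistack_tshape_angle_min &&
               ang <= config$pistack_tshape_angle_max) "T-shaped"
      else NA
    if (is.na(type)) next
    out <- rbind(out, data.frame(rec = rr$id, lig = lr$id, type = type,
                                 dc = dc))
  }
  out
}

# ---- random polar "soup" in a 10 A box: donors, acceptors, carbons and a
# few waters, split between ligand and receptor partitions.
random_polar_frame <- function(seed, n_groups = 12, n_waters = 4,
                               box = 10) {
  set.seed(seed)
  rows <- list()
  rid <- 0L
  for (g in seq_len(n_groups)) {
    rid <- rid + 1L
    is_lig <- g <= ceiling(n_groups / 3)
    center <- runif(3, 0, box)
    kind <- sample(c("OH", "O", "NH", "C"), 1)
    resname <- if (is_lig) "EST" else sample(c("DG", "DC"), 1)
    chain <- if (is_lig) "L" else "A"
    at <- switch(kind,
      OH = {
        hdir <- rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
        frag(resname, rid, c("O1", "HO1"), c("O", "H"),
             rbind(center, center + 0.96 * hdir), chain)
      },
      O = frag(resname, rid, "O1", "O", rbind(center), chain),
      NH = {
        hdir <- rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
        frag(resname, rid, c("N1", "HN1"), c("N", "H"),
             rbind(center, center + 1.0 * hdir), chain)
      },
      C = frag(resname, rid, "C1", "C", rbind(center), chain))
    rows[[length(rows) + 1]] <- at
  }
  for (w in seq_len(n_waters)) {
    rid <- rid + 1L
    center <- runif(3, 0, box)
    hdir <- rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
    rows[[length(rows) + 1]] <- frag(
      "SOL", rid, c("OW", "HW1", "HW2"), c("O", "H", "H"),
      rbind(center, center + 0.96 * hdir, center - 0.96 * hdir), "W")
  }
  fr <- mini_frame(do.call(rbind, rows))
  assign_roles(fr, interaction_config())
}

# Random rigid transform helpers for invariance tests.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_frame <- function(frame, R, t_vec) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t_vec, `+`)
  frame$atoms$x <- xyz[, 1]; frame$atoms$y <- xyz[, 2]
  frame$atoms$z <- xyz[, 3]
  frame$roles <- NULL
  frame
}

# Synthesize typed interaction records with prescribed per-anchor counts,
# for aggregation arithmetic driven by printed count tables.
records_from_counts <- function(counts) {
  # counts: data.frame(iclass, lig_atom, chem_type, n)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    if (n == 0) return(NULL)
    data.frame(frame = seq_len(n), iclass = counts$iclass[i], chain = "A",
               resid = 26L, resname = "DC", rec_atom = "O2",
               lig_atom = counts$lig_atom[i], water_id = NA_integer_,
               d1 = 2.9, d2 = NA_real_, a1 = 170, a2 = NA_real_,
               chem_type = counts$chem_type[i], donor_side = "ligand",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
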