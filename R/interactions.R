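# Per-frame geometric detection of the four interaction classes.

.record_cols <- c("frame", "iclass", "chain", "resid", "resname", "rec_atom",
                  "lig_atom", "water_id", "d1", "d2", "a1", "a2",
                  "chem_type", "donor_side")

empty_records <- function() {
  data.frame(frame = integer(0), iclass = character(0), chain = character(0),
             resid = integer(0), resname = character(0),
             rec_atom = character(0), lig_atom = character(0),
             water_id = integer(0), d1 = numeric(0), d2 = numeric(0),
             a1 = numeric(0), a2 = numeric(0), chem_type = character(0),
             donor_side = character(0), stringsAsFactors = FALSE)
}

new_record <- function(frame_index, iclass, chain, resid, resname, rec_atom,
                       lig_atom, water_id = NA_integer_, d1 = NA_real_,
                       d2 = NA_real_, a1 = NA_real_, a2 = NA_real_,
                       chem_type = NA_character_, donor_side = NA_character_) {
  data.frame(frame = frame_index, iclass = iclass, chain = chain,
             resid = resid, resname = resname, rec_atom = rec_atom,
             lig_atom = lig_atom, water_id = water_id, d1 = d1, d2 = d2,
             a1 = a1, a2 = a2, chem_type = chem_type,
             donor_side = donor_side, stringsAsFactors = FALSE)
}

bind_records <- function(lst) {
  lst <- lst[vapply(lst, NROW, 0L) > 0]
  if (!length(lst)) return(empty_records())
  do.call(rbind, lst)
}

.ensure_roles <- function(frame, config) {
  if (is.null(frame$roles)) assign_roles(frame, config) else frame
}

#' Detect hydrogen bonds in one frame
#'
#' A hydrogen bond is a (donor heavy atom, hydrogen, acceptor) triple with
#' donor-acceptor distance at most `hbond_da_max` and D-H...A angle at least
#' `hbond_angle_min` (angle test skipped in lenient-hydrogen mode). Each
#' donor hydrogen is paired with at most its nearest qualifying acceptor
#' (ties broken by lower atom serial), which prevents double counting in the
#' downstream frequency tables. Both partitions may donate.
#'
#' The chemical type label concatenates the donor and acceptor elements,
#' e.g. `"O–H⋯O"` or `"N–H⋯O"`.
#'
#' @param frame an `md_frame` (roles are assigned on the fly if absent).
#' @param config an [interaction_config()].
#' @param between character pair naming the two partitions to search, e.g.
#'   `c("ligand", "receptor")`. With two identical partition names,
#'   intramolecular bonds are detected and same-residue pairs are excluded.
#' @return a record data.frame (one row per bond) with distances in Angstrom
#'   (`d1` = D-A) and angles in degrees (`a1` = D-H...A).
#' @export
detect_hbonds <- function(frame, config = interaction_config(),
                          between = c("ligand", "receptor")) {
  frame <- .ensure_roles(frame, config)
  part <- frame$partition
  side1 <- part[[between[1]]]
  side2 <- part[[between[2]]]
  if (!length(side1) || !length(side2))
    stop("empty partition(s) for H-bond detection: ",
         paste(between, collapse = ", "))
  same <- identical(between[1], between[2])
  out <- list()
  sides <- if (same) list(c(1, 2)) else list(c(1, 2), c(2, 1))
  for (sd in sides) {
    donors_from <- if (sd[1] == 1) side1 else side2
    acceptors_from <- if (sd[2] == 1) side1 else side2
    out[[length(out) + 1]] <-
      .hbond_scan(frame, config, donors_from, acceptors_from,
                  donor_side = if (same) between[1] else between[sd[1]],
                  between = between, exclude_same_residue = same)
  }
  recs <- bind_records(out)
  order_records(recs)
}

.hbond_scan <- function(frame, config, donor_idx, acceptor_idx, donor_side,
                        between, exclude_same_residue = FALSE) {
  a <- frame$atoms
  fl <- frame$roles$flags
  lenient <- frame$roles$mode == "lenient"
  donors <- intersect(donor_idx, which(fl$donor_heavy))
  acceptors <- intersect(acceptor_idx, which(fl$acceptor))
  if (!length(donors) || !length(acceptors)) return(empty_records())
  xyz <- coords_matrix(frame)
  h_parent <- frame$roles$h_parent
  out <- list()
  for (dd in donors) {
    hs <- if (lenient) NA_integer_ else which(h_parent == dd)
    for (h in hs) {
      best <- NULL
      for (aa in acceptors) {
        if (aa == dd) next
        if (exclude_same_residue &&
            a$resid[aa] == a$resid[dd] && a$chain[aa] == a$chain[dd]) next
        dda <- vdist(xyz[dd, ], xyz[aa, ])
        if (dda > config$hbond_da_max) next
        ang <- if (lenient) NA_real_ else vangle(xyz[dd, ], xyz[h, ], xyz[aa, ])
        if (!lenient && ang < config$hbond_angle_min) next
        if (is.null(best) || dda < best$d ||
            (dda == best$d && a$serial[aa] < a$serial[best$idx])) {
          best <- list(idx = aa, d = dda, ang = ang)
        }
      }
      if (is.null(best)) next
      aa <- best$idx
      # receptor-side atom goes in rec_atom, ligand-side in lig_atom; for
      # intramolecular scans rec_atom = acceptor, lig_atom = donor
      donor_is_receptor <- dd %in% frame$partition$receptor
      if (identical(sort(between), c("ligand", "receptor")) && !
          identical(between[1], between[2])) {
        rec_i <- if (donor_is_receptor) dd else aa
        lig_i <- if (donor_is_receptor) aa else dd
      } else {
        rec_i <- aa; lig_i <- dd
      }
      chem <- if (lenient) {
        sprintf("%s⋯%s", a$element[dd], a$element[aa])
      } else {
        sprintf("%s–H⋯%s", a$element[dd], a$element[aa])
      }
      out[[length(out) + 1]] <- new_record(
        frame$index, "hbond", a$chain[rec_i], a$resid[rec_i],
        a$resname[rec_i], a$name[rec_i], a$name[lig_i],
        d1 = best$d, a1 = best$ang, chem_type = chem,
        donor_side = donor_side)
    }
  }
  bind_records(out)
}

#' Detect water-mediated hydrogen-bond bridges
#'
#' A water bridge connects a ligand polar atom and a receptor polar atom
#' through a pivot water oxygen: one side donates a hydrogen bond to the
#' water, the water relays it to the acceptor on the other side. Geometric
#' criteria (PLIP convention): both heavy-atom legs within
#' `[waterbridge_dist_min, waterbridge_dist_max]`; theta, the D-H...Ow angle
#' at the donor hydrogen, at least `waterbridge_theta_min`; omega, the angle
#' at the water oxygen between the acceptor and the donor hydrogen, inside
#' `[waterbridge_omega_min, waterbridge_omega_max]`.
#'
#' The chemical type concatenates donor element, water and acceptor element,
#' e.g. `"O–H⋯O–H⋯O"` (ligand hydroxyl donating) or
#' `"N–H⋯O–H⋯O"` (base amine donating).
#'
#' @inheritParams detect_hbonds
#' @return record data.frame; `d1` = donor-water leg, `d2` = water-acceptor
#'   leg (Angstrom), `a1` = theta, `a2` = omega (degrees), `water_id` = the
#'   pivot water residue id.
#' @export
detect_water_bridges <- function(frame, config = interaction_config()) {
  frame <- .ensure_roles(frame, config)
  part <- frame$partition
  if (!length(part$water)) return(empty_records())
  a <- frame$atoms
  fl <- frame$roles$flags
  lenient <- frame$roles$mode == "lenient"
  xyz <- coords_matrix(frame)
  h_parent <- frame$roles$h_parent
  waters <- which(fl$water_o)
  out <- list()
  for (sd in list(c("ligand", "receptor"), c("receptor", "ligand"))) {
    donors <- intersect(part[[sd[1]]], which(fl$donor_heavy))
    acceptors <- intersect(part[[sd[2]]], which(fl$acceptor))
    for (dd in donors) {
      hs <- if (lenient) NA_integer_ else which(h_parent == dd)
      for (w in waters) {
        d1 <- vdist(xyz[dd, ], xyz[w, ])
        if (d1 < config$waterbridge_dist_min ||
            d1 > config$waterbridge_dist_max) next
        for (h in hs) {
          theta <- if (lenient) NA_real_ else
            vangle(xyz[dd, ], xyz[h, ], xyz[w, ])
          if (!lenient && theta < config$waterbridge_theta_min) next
          for (aa in acceptors) {
            d2 <- vdist(xyz[aa, ], xyz[w, ])
            if (d2 < config$waterbridge_dist_min ||
                d2 > config$waterbridge_dist_max) next
            omega <- if (lenient) NA_real_ else
              vangle(xyz[aa, ], xyz[w, ], xyz[h, ])
            if (!lenient && (omega < config$waterbridge_omega_min ||
                             omega > config$waterbridge_omega_max)) next
            rec_i <- if (sd[1] == "receptor") dd else aa
            lig_i <- if (sd[1] == "receptor") aa else dd
            chem <- if (lenient) {
              sprintf("%s⋯O⋯%s", a$element[dd], a$element[aa])
            } else {
              sprintf("%s–H⋯O–H⋯%s",
                      a$element[dd], a$element[aa])
            }
            out[[length(out) + 1]] <- new_record(
              frame$index, "water_bridge", a$chain[rec_i], a$resid[rec_i],
              a$resname[rec_i], a$name[rec_i], a$name[lig_i],
              water_id = a$resid[w], d1 = d1, d2 = d2, a1 = theta,
              a2 = omega, chem_type = chem, donor_side = sd[1])
          }
        }
      }
    }
  }
  order_records(bind_records(out))
}

#' Least-squares plane through a ring
#'
#' @param xyz numeric matrix (>= 3 rows) of atom coordinates in Angstrom.
#' @return list with `centroid` (unweighted mean) and `normal` (unit
#'   least-squares plane normal, sign-canonicalized toward +z, ties broken
#'   toward +x then +y). Collinear input is an error.
#' @export
fit_ring_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("need at least 3 atoms to fit a plane")
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) stop("collinear atoms: no unique plane")
  normal <- sv$v[, 3]
  tol <- 1e-10
  flip <- if (abs(normal[3]) > tol) normal[3] < 0
          else if (abs(normal[1]) > tol) normal[1] < 0
          else normal[2] < 0
  if (flip) normal <- -normal
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Detect pi-stacking between ligand and receptor aromatic rings
#'
#' Every (receptor ring, ligand ring) pair is tested on three criteria:
#' centroid distance at most `pistack_center_max`, lateral offset (the
#' smaller of the two in-plane projections of one centroid onto the other
#' ring's plane) at most `pistack_offset_max`, and interplanar angle either
#' at most `pistack_parallel_angle_max` (`chem_type = "parallel"`) or inside
#' the T-shape window (`chem_type = "T-shaped"`).
#'
#' @inheritParams detect_hbonds
#' @return record data.frame; `d1` = centroid distance, `d2` = offset
#'   (Angstrom), `a1` = interplanar angle (degrees); `lig_atom` carries the
#'   ligand ring identifier.
#' @export
detect_pistacking <- function(frame, config = interaction_config()) {
  frame <- .ensure_roles(frame, config)
  rings <- frame$roles$rings
  if (!length(rings)) return(empty_records())
  part <- frame$partition
  rec_rings <- Filter(function(r) r$atoms[1] %in% part$receptor, rings)
  lig_rings <- Filter(function(r) r$atoms[1] %in% part$ligand, rings)
  if (!length(rec_rings) || !length(lig_rings)) return(empty_records())
  xyz <- coords_matrix(frame)
  out <- list()
  for (rr in rec_rings) {
    pr <- fit_ring_plane(xyz[rr$atoms, , drop = FALSE])
    for (lr in lig_rings) {
      pl <- fit_ring_plane(xyz[lr$atoms, , drop = FALSE])
      dc <- vdist(pr$centroid, pl$centroid)
      if (dc > config$pistack_center_max) next
      v <- pl$centroid - pr$centroid
      off1 <- sqrt(max(0, sum(v^2) - sum(v * pr$normal)^2))
      off2 <- sqrt(max(0, sum(v^2) - sum(v * pl$normal)^2))
      offset <- min(off1, off2)
      if (offset > config$pistack_offset_max) next
      cosang <- abs(sum(pr$normal * pl$normal))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      type <- if (ang <= config$pistack_parallel_angle_max) "parallel"
        else if (ang >= config$pistack_tshape_angle_min &&
                 ang <= config$pistack_tshape_angle_max) "T-shaped"
        else NA_character_
      if (is.na(type)) next
      out[[length(out) + 1]] <- new_record(
        frame$index, "pistack", rr$chain, rr$resid, rr$resname,
        rr$id, lr$id, d1 = dc, d2 = offset, a1 = ang, chem_type = type,
        donor_side = NA_character_)
    }
  }
  order_records(bind_records(out))
}

#' Detect hydrophobic contacts
#'
#' Candidate pairs are (ligand hydrophobic carbon, receptor hydrophobic
#' carbon) within `hydrophobic_max`; candidates are then reduced to at most
#' one record per (receptor residue, ligand atom), keeping the pair at
#' minimum distance.
#'
#' @inheritParams detect_hbonds
#' @return record data.frame with `d1` = the minimum C-C distance.
#' @export
detect_hydrophobic <- function(frame, config = interaction_config()) {
  frame <- .ensure_roles(frame, config)
  part <- frame$partition
  fl <- frame$roles$flags
  lc <- intersect(part$ligand, which(fl$hydrophobic_c))
  rc <- intersect(part$receptor, which(fl$hydrophobic_c))
  if (!length(lc) || !length(rc)) return(empty_records())
  a <- frame$atoms
  xyz <- coords_matrix(frame)
  best <- list()  # key: receptor residue x ligand atom
  for (li in lc) {
    for (ri in rc) {
      dd <- vdist(xyz[li, ], xyz[ri, ])
      if (dd > config$hydrophobic_max) next
      key <- paste(a$chain[ri], a$resid[ri], a$name[li], sep = "/")
      if (is.null(best[[key]]) || dd < best[[key]]$d)
        best[[key]] <- list(li = li, ri = ri, d = dd)
    }
  }
  out <- lapply(best, function(b) new_record(
    frame$index, "hydrophobic", a$chain[b$ri], a$resid[b$ri],
    a$resname[b$ri], a$name[b$ri], a$name[b$li], d1 = b$d))
  order_records(bind_records(unname(out)))
}

#' Profile a whole trajectory
#'
#' Runs all four detectors (ligand vs receptor, with water pivots for the
#' bridges) on every frame and concatenates the records in deterministic
#' order (frame, class, residue id, atom name). Atom roles are assigned once
#' on frame 1 and reused, so flags are identical across frames of one
#' trajectory; ring planes are refit per frame from the coordinates.
#'
#' @param traj an `md_trajectory`.
#' @param config an [interaction_config()].
#' @return a record data.frame covering the whole trajectory.
#' @export
profile_trajectory <- function(traj, config = interaction_config()) {
  stopifnot(inherits(traj, "md_trajectory"))
  frame1 <- assign_roles(traj$frames[[1]], config)
  roles <- frame1$roles
  out <- vector("list", length(traj$frames))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    fr$roles <- roles
    # ring geometry is frame-dependent; membership is topology-stable
    out[[i]] <- bind_records(list(
      detect_hbonds(fr, config, c("ligand", "receptor")),
      detect_water_bridges(fr, config),
      detect_pistacking(fr, config),
      detect_hydrophobic(fr, config)))
  }
  recs <- bind_records(out)
  order_records(recs)
}

order_records <- function(recs) {
  if (!NROW(recs)) return(recs)
  recs <- recs[order(recs$frame, recs$iclass, recs$resid, recs$rec_atom,
                     recs$lig_atom, !is.na(recs$water_id), recs$water_id), ]
  rownames(recs) <- NULL
  recs
}

#' Read / write interaction records as TSV
#'
#' Fixed column order: frame, iclass, chain, resid, resname, rec_atom,
#' lig_atom, water_id, d1, d2, a1, a2, chem_type, donor_side.
#'
#' @param records a record data.frame.
#' @param path TSV file path.
#' @return `write_records` returns `path` invisibly; `read_records` the
#'   restored data.frame.
#' @export
write_records <- function(records, path) {
  stopifnot(all(.record_cols %in% names(records)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(records[, .record_cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (!identical(header, .record_cols))
    stop("records file does not match the expected schema")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    encoding = "UTF-8",
                    colClasses = c(frame = "integer",
                                   iclass = "character",
                                   chain = "character",
                                   resid = "integer",
                                   resname = "character",
                                   rec_atom = "character",
                                   lig_atom = "character",
                                   water_id = "integer",
                                   d1 = "numeric", d2 = "numeric",
                                   a1 = "numeric", a2 = "numeric",
                                   chem_type = "character",
                                   donor_side = "character"))
}
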