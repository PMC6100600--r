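# Atom-role typing: donors, acceptors, hydrophobic carbons, aromatic rings.

# Ring templates for the standard nucleic-acid bases. Purines carry both the
# six-membered and the five-membered ring; pyrimidines one six-ring.
.base_ring_templates <- local({
  pyr6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
  pur5 <- c("C4", "C5", "N7", "C8", "N9")
  pyr <- list(pyr6)
  pur <- list(pyr6, pur5)
  list(DA = pur, DG = pur, A = pur, G = pur, ADE = pur, GUA = pur,
       DC = pyr, DT = pyr, DU = pyr, C = pyr, T = pyr, U = pyr,
       CYT = pyr, THY = pyr, URA = pyr)
})

#' Assign functional atom roles to a frame
#'
#' Computes, from the frame geometry, the role flags every detector needs:
#' hydrogen-bond donors (N/O with at least one covalently bonded hydrogen),
#' acceptors (any N/O), hydrophobic carbons (C bonded only to C or H),
#' aromatic-ring membership, and water oxygen/hydrogen flags. Covalent bonds
#' are inferred from distance (heavy-heavy <= 1.9 A, X-H <= 1.25 A by
#' default). Rings come from residue templates for standard bases and from a
#' generic planar 5/6-cycle search on the ligand bond graph.
#'
#' In strict-hydrogen mode (the default, matching all-atom MD output) an
#' error is raised when the receptor and ligand carry no hydrogens at all;
#' the lenient mode types every N/O as both donor and acceptor.
#'
#' @param frame an `md_frame`.
#' @param config an [interaction_config()].
#' @return the frame with a populated `roles` field (logical flag table,
#'   hydrogen-to-parent map, bond list and detected rings).
#' @export
assign_roles <- function(frame, config = interaction_config()) {
  a <- frame$atoms
  n <- nrow(a)
  el <- a$element
  is_h <- el == "H"
  part <- frame$partition
  solute <- c(part$receptor, part$ligand)
  if (config$strict_hydrogens && length(solute) && !any(is_h[solute]))
    stop("strict hydrogen mode: no hydrogens present in receptor/ligand; ",
         "use strict_hydrogens = FALSE for heavy-atom-only input")

  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  # covalent bond inference, restricted within a residue's neighborhood is
  # unnecessary at fixture scale; pure distance rule per design
  heavy <- !is_h
  bonded <- matrix(FALSE, n, n)
  bonded[heavy, heavy] <- d[heavy, heavy, drop = FALSE] <= config$covalent_heavy_max
  hh <- d <= config$covalent_h_max
  bonded[is_h, ] <- hh[is_h, , drop = FALSE]
  bonded[, is_h] <- hh[, is_h, drop = FALSE]
  bonded[is_h, is_h] <- FALSE  # no H-H bonds

  h_parent <- rep(NA_integer_, n)
  for (i in which(is_h)) {
    nb <- which(bonded[i, ] & heavy)
    if (length(nb)) h_parent[i] <- nb[which.min(d[i, nb])]
  }

  in_water <- seq_len(n) %in% part$water
  has_h <- vapply(seq_len(n), function(i) any(h_parent == i, na.rm = TRUE),
                  TRUE)
  polar <- el %in% c("N", "O") & !in_water
  if (config$strict_hydrogens) {
    donor <- polar & has_h
  } else {
    donor <- polar
  }
  acceptor <- polar
  hydrophobic <- el == "C" & !in_water &
    vapply(seq_len(n), function(i) {
      nb <- which(bonded[i, ])
      length(nb) == 0 || all(el[nb] %in% c("C", "H"))
    }, TRUE)
  # hydrogens never carry heavy-atom roles
  donor[is_h] <- acceptor[is_h] <- hydrophobic[is_h] <- FALSE

  rings <- detect_rings(frame, bonded, config)
  aromatic <- rep(FALSE, n)
  for (r in rings) aromatic[r$atoms] <- TRUE

  roles <- list(
    flags = data.frame(
      donor_heavy = donor, acceptor = acceptor, hydrogen = is_h,
      hydrophobic_c = hydrophobic, aromatic = aromatic,
      water_o = in_water & el == "O", water_h = in_water & el == "H"),
    h_parent = h_parent,
    bonded = bonded,
    rings = rings,
    mode = if (config$strict_hydrogens) "strict" else "lenient")
  frame$roles <- roles
  frame
}

# Rings: residue templates first; generic planar-cycle fallback for ligand
# residues without a template.
detect_rings <- function(frame, bonded, config) {
  a <- frame$atoms
  rings <- list()
  reskeys <- unique(paste(a$chain, a$resid, sep = "/"))
  for (rk in reskeys) {
    idx <- which(paste(a$chain, a$resid, sep = "/") == rk)
    resname <- toupper(a$resname[idx[1]])
    tmpl <- .base_ring_templates[[resname]]
    found_template <- FALSE
    if (!is.null(tmpl)) {
      for (ring_names in tmpl) {
        ratoms <- idx[match(ring_names, a$name[idx])]
        if (!anyNA(ratoms)) {
          rings[[length(rings) + 1]] <- list(
            atoms = ratoms, resid = a$resid[idx[1]], resname = resname,
            chain = a$chain[idx[1]],
            id = sprintf("%s%d.r%d", resname, a$resid[idx[1]],
                         sum(vapply(rings, function(r) r$resid == a$resid[idx[1]] &&
                                      r$chain == a$chain[idx[1]], TRUE)) + 1))
          found_template <- TRUE
        }
      }
    }
    is_ligand_res <- idx[1] %in% frame$partition$ligand
    if (!found_template && is_ligand_res) {
      cycles <- find_planar_cycles(idx[a$element[idx] != "H"], bonded,
                                   coords_matrix(frame), config)
      for (k in seq_along(cycles)) {
        rings[[length(rings) + 1]] <- list(
          atoms = cycles[[k]], resid = a$resid[idx[1]], resname = resname,
          chain = a$chain[idx[1]],
          id = sprintf("ring%d", k))
      }
    }
  }
  rings
}

# Enumerate simple 5/6-cycles in the bond graph among `idx`, keep planar ones.
find_planar_cycles <- function(idx, bonded, xyz, config) {
  if (length(idx) < 5) return(list())
  adj <- lapply(idx, function(i) idx[bonded[i, idx]])
  names(adj) <- as.character(idx)
  cycles <- list()
  seen <- character(0)
  # DFS from each atom, paths up to length 6, closing back to the start
  for (s in idx) {
    stack <- list(s)
    paths <- list(c(s))
    while (length(paths)) {
      p <- paths[[1]]; paths <- paths[-1]
      last <- p[length(p)]
      for (nb in adj[[as.character(last)]]) {
        if (nb == s && length(p) %in% c(5, 6)) {
          key <- paste(sort(p), collapse = "-")
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            cycles[[length(cycles) + 1]] <- sort(p)
          }
        } else if (!(nb %in% p) && nb > s && length(p) < 6) {
          paths[[length(paths) + 1]] <- c(p, nb)
        }
      }
    }
  }
  keep <- list()
  for (cy in cycles) {
    # drop cycles that are unions of smaller ones (chords present)
    deg <- vapply(cy, function(i) sum(bonded[i, cy]), 0)
    if (any(deg != 2)) next
    fit <- try(fit_ring_plane(xyz[cy, , drop = FALSE]), silent = TRUE)
    if (inherits(fit, "try-error")) next
    dev <- xyz[cy, , drop = FALSE]
    dev <- sweep(dev, 2, fit$centroid)
    rms <- sqrt(mean((dev %*% fit$normal)^2))
    if (rms <= config$ring_planarity_rms_max)
      keep[[length(keep) + 1]] <- cy
  }
  keep
}
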