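# Trajectory-level stability analytics: Rg, RMSD, RMSF, H-bond counts.

new_stat_series <- function(name, frame_index, value, time_ps = NULL) {
  df <- data.frame(frame = frame_index, value = value)
  if (!is.null(time_ps)) df$time_ps <- time_ps
  structure(df, class = c("stat_series", "data.frame"),
            series_name = name,
            summary = c(mean = mean(value), sd = stats::sd(value),
                        min = min(value), max = max(value)))
}

#' @export
print.stat_series <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("%s series over %d frames: mean %.3f +/- %.3f (min %.3f, max %.3f)\n",
              attr(x, "series_name"), nrow(x), s["mean"],
              if (is.na(s["sd"])) 0 else s["sd"], s["min"], s["max"]))
  invisible(x)
}

#' @export
plot.stat_series <- function(x, ...) {
  graphics::plot(x$frame, x$value, type = "l", xlab = "frame",
                 ylab = attr(x, "series_name"), ...)
  invisible(x)
}

# Default analysis selection: receptor heavy atoms.
.receptor_heavy <- function(frame) {
  idx <- frame$partition$receptor
  idx[frame$atoms$element[idx] != "H"]
}

#' Radius of gyration of a selection
#'
#' \eqn{Rg = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}} with atomic
#' masses from the element table (GROMACS `gyrate` convention), or unit
#' masses when `mass_weighted = FALSE`.
#'
#' @param frame an `md_frame`.
#' @param selection atom indices (default: receptor heavy atoms).
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL, mass_weighted = TRUE) {
  if (is.null(selection)) selection <- .receptor_heavy(frame)
  if (!length(selection)) stop("empty selection")
  xyz <- coords_matrix(frame, selection)
  m <- if (mass_weighted) element_mass(frame$atoms$element[selection])
       else rep(1, length(selection))
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

#' Rg time series over a trajectory
#'
#' @param traj an `md_trajectory`.
#' @inheritParams radius_of_gyration
#' @return a `stat_series` of per-frame Rg values (Angstrom).
#' @export
rg_series <- function(traj, selection = NULL, mass_weighted = TRUE) {
  vals <- vapply(traj$frames, radius_of_gyration, 0.0,
                 selection = selection, mass_weighted = mass_weighted)
  new_stat_series("Rg", seq_along(traj$frames), vals)
}

#' Kabsch superposition
#'
#' Least-RMSD rigid-body fit (proper rotation only, via SVD with a
#' determinant correction) of `mobile` onto `reference` over a selection.
#'
#' @param mobile,reference numeric n x 3 coordinate matrices.
#' @param selection row indices used for the fit (default: all rows).
#' @return list with the 3x3 `rotation`, the `translation` vector (apply as
#'   `xyz %*% t(R) + t`), and the post-fit `rmsd` over the selection (A).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("coordinate sets differ in size")
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("need at least 3 atoms for superposition")
  x <- mobile[selection, , drop = FALSE]
  y <- reference[selection, , drop = FALSE]
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sv <- svd(crossprod(xc, yc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) selection")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cy - as.vector(R %*% cx)
  fitted <- xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

apply_transform <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

#' Per-frame RMSD series
#'
#' Kabsch-fit RMSD of every frame against a reference frame (default frame
#' 1, i.e. the starting structure), or -- in paired mode -- against the same
#' frame index of a second trajectory.
#'
#' @param traj an `md_trajectory`.
#' @param reference_frame index of the reference frame.
#' @param selection atom indices entering fit and RMSD (default receptor
#'   heavy atoms).
#' @param fit superpose before measuring (default `TRUE`); `FALSE` gives the
#'   raw coordinate RMSD.
#' @param paired optional second trajectory with identical topology; frame i
#'   is then compared against frame i of `paired`.
#' @return a `stat_series` of RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = NULL,
                        fit = TRUE, paired = NULL) {
  if (is.null(selection)) selection <- .receptor_heavy(traj$frames[[1]])
  if (!is.null(paired)) {
    if (!identical(traj$topology_hash, paired$topology_hash))
      stop("paired trajectories differ in topology")
    if (length(paired) != length(traj))
      stop("paired trajectories differ in frame count")
  } else {
    if (reference_frame < 1 || reference_frame > length(traj))
      stop("invalid reference frame")
    ref <- coords_matrix(traj$frames[[reference_frame]])
  }
  vals <- vapply(seq_along(traj$frames), function(i) {
    mob <- coords_matrix(traj$frames[[i]])
    target <- if (is.null(paired)) ref else coords_matrix(paired$frames[[i]])
    if (fit) {
      kabsch_superpose(mob, target, selection)$rmsd
    } else {
      sqrt(mean(rowSums((mob[selection, , drop = FALSE] -
                           target[selection, , drop = FALSE])^2)))
    }
  }, 0.0)
  new_stat_series("RMSD", seq_along(traj$frames), vals)
}

#' Per-atom RMSF profile with region means
#'
#' RMSF of atom i is the root-mean-square deviation of its position from its
#' trajectory-mean position. Frames are first superposed (receptor heavy
#' atoms by default): one pass fits every frame onto frame 1, the mean
#' structure is computed, every frame is refit onto that mean, and the final
#' mean is the RMSF reference. Region means are reported both as the mean
#' over member atoms and as the mean of per-residue means.
#'
#' @param traj an `md_trajectory` with at least 2 frames.
#' @param selection atoms to report (default: receptor heavy atoms).
#' @param regions optional named list of residue-id vectors, e.g.
#'   `list(stem = c(6:11, 26:31))`.
#' @param fit superpose frames before measuring (default `TRUE`).
#' @param fit_selection atoms used for the superposition (default: receptor
#'   heavy atoms, so a ligand can be reported without entering the fit).
#' @return object of class `rmsf_profile`: `per_atom` data.frame (atom
#'   index, residue, name, rmsf) and `per_region` data.frame (label, n
#'   atoms, mean over atoms, mean of per-residue means).
#' @export
rmsf_profile <- function(traj, selection = NULL, regions = NULL, fit = TRUE,
                         fit_selection = NULL) {
  if (length(traj) < 2) stop("RMSF needs at least 2 frames")
  f1 <- traj$frames[[1]]
  if (is.null(selection)) selection <- .receptor_heavy(f1)
  if (is.null(fit_selection)) fit_selection <- .receptor_heavy(f1)
  coords <- lapply(traj$frames, coords_matrix)
  if (fit) {
    ref <- coords[[1]]
    fit_once <- function(coords, ref) lapply(coords, function(m) {
      k <- kabsch_superpose(m, ref, fit_selection)
      apply_transform(m, k$rotation, k$translation)
    })
    coords <- fit_once(coords, ref)
    mean_xyz <- Reduce(`+`, coords) / length(coords)
    coords <- fit_once(coords, mean_xyz)
  }
  mean_xyz <- Reduce(`+`, coords) / length(coords)
  dev2 <- Reduce(`+`, lapply(coords, function(m) rowSums((m - mean_xyz)^2)))
  rmsf_all <- sqrt(dev2 / length(coords))
  per_atom <- data.frame(
    atom = selection,
    name = f1$atoms$name[selection],
    resid = f1$atoms$resid[selection],
    resname = f1$atoms$resname[selection],
    rmsf = rmsf_all[selection])
  per_region <- NULL
  if (!is.null(regions)) {
    rows <- lapply(names(regions), function(lab) {
      sel <- per_atom[per_atom$resid %in% regions[[lab]], ]
      if (!nrow(sel)) stop("region '", lab, "' matches no atoms")
      res_means <- tapply(sel$rmsf, sel$resid, mean)
      data.frame(region = lab, n_atoms = nrow(sel),
                 mean_rmsf = mean(sel$rmsf),
                 mean_rmsf_residue = mean(res_means))
    })
    per_region <- do.call(rbind, rows)
    rownames(per_region) <- NULL
  }
  structure(list(per_atom = per_atom, per_region = per_region),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("RMSF profile over", nrow(x$per_atom), "atoms; mean",
      sprintf("%.3f A\n", mean(x$per_atom$rmsf)))
  if (!is.null(x$per_region)) {
    print(transform(x$per_region,
                    mean_rmsf = round_half_up(mean_rmsf, 2),
                    mean_rmsf_residue = round_half_up(mean_rmsf_residue, 2)))
  }
  invisible(x)
}

#' Intramolecular hydrogen-bond count per frame
#'
#' Counts receptor-receptor hydrogen bonds per frame with a GROMACS-like
#' preset (D-A <= 3.5 A, near-linear angle), excluding pairs within one
#' residue -- the standard stability readout accompanying Rg and RMSD.
#'
#' @param traj an `md_trajectory`.
#' @param config preset used for counting; defaults to
#'   `interaction_config("gromacs")`.
#' @return a `stat_series` of per-frame counts.
#' @export
intramolecular_hbond_series <- function(traj,
                                        config = interaction_config("gromacs")) {
  frame1 <- assign_roles(traj$frames[[1]], config)
  roles <- frame1$roles
  vals <- vapply(seq_along(traj$frames), function(i) {
    fr <- traj$frames[[i]]
    fr$roles <- roles
    nrow(detect_hbonds(fr, config, c("receptor", "receptor")))
  }, 0L)
  new_stat_series("HBondCount", seq_along(traj$frames), as.numeric(vals))
}

#' Export a stat series as TSV (frame, time_ps, value)
#' @param series a `stat_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- data.frame(frame = series$frame,
                   time_ps = series$time_ps %||% NA_real_,
                   value = series$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
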