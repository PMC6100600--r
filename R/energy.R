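# Gas-phase molecular-mechanics interaction energy decomposition.
# GROMACS units throughout: nm, kJ/mol, elementary charge. Coordinates in
# Angstrom are converted at the module boundary (x0.1) -- stated explicitly
# to rule out a 10x error class.

.coulomb_f <- 138.935485  # kJ mol^-1 nm e^-2

#' Coulomb pair energy
#'
#' \eqn{E = f q_1 q_2 / (\epsilon_r r)} with
#' \eqn{f = 138.935485} kJ mol^-1 nm e^-2.
#'
#' @param q1,q2 partial charges (e).
#' @param r distance (nm), > 0.
#' @param dielectric relative dielectric constant.
#' @return energy in kJ/mol.
#' @export
coulomb_pair <- function(q1, q2, r, dielectric = 1) {
  if (any(r <= 0)) stop("r must be > 0")
  .coulomb_f * q1 * q2 / (dielectric * r)
}

#' Lennard-Jones pair energy
#'
#' \eqn{E = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}; zero at
#' \eqn{r = \sigma}, minimum \eqn{-\epsilon} at \eqn{r = 2^{1/6}\sigma}.
#'
#' @param sigma LJ sigma (nm), > 0.
#' @param epsilon LJ well depth (kJ/mol), >= 0.
#' @param r distance (nm), > 0.
#' @return energy in kJ/mol.
#' @export
lj_pair <- function(sigma, epsilon, r) {
  if (any(r <= 0)) stop("r must be > 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Read a per-atom parameter table (TSV)
#'
#' Columns: `name` (atom name), `resname`, `charge` (e), `sigma` (nm),
#' `epsilon` (kJ/mol). Atoms are matched by (resname, name).
#'
#' @param path TSV file.
#' @return object of class `param_table`.
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  param_table(df)
}

#' @param df data.frame with the columns listed above.
#' @rdname read_param_table
#' @export
param_table <- function(df) {
  need <- c("name", "resname", "charge", "sigma", "epsilon")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("parameter table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(df$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(df$sigma <= 0)) stop("sigma must be > 0")
  if (anyDuplicated(paste(df$resname, df$name)))
    stop("duplicate (resname, name) entries in parameter table")
  structure(df[, need], class = c("param_table", "data.frame"))
}

#' Write a parameter table as TSV
#' @param params a `param_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.match_params <- function(atoms, idx, params) {
  key <- paste(atoms$resname[idx], atoms$name[idx])
  pos <- match(key, paste(params$resname, params$name))
  if (anyNA(pos)) {
    stop("missing parameters for atoms: ",
         paste(unique(key[is.na(pos)]), collapse = ", "),
         " (parameters are never defaulted silently)")
  }
  params[pos, ]
}

#' Per-residue ligand-receptor MM energy decomposition
#'
#' For every frame, sums Coulomb and Lennard-Jones energies over all
#' (ligand atom, receptor atom) pairs, grouped by receptor residue; each
#' pair energy is assigned wholly to its receptor residue. Lorentz-Berthelot
#' combination rules (\eqn{\sigma_{ij} = (\sigma_i+\sigma_j)/2},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}). Reported per residue
#' and in total as the trajectory mean with its standard error. Only the
#' gas-phase MM terms are computed; the polar (Poisson-Boltzmann) and
#' non-polar (SASA) solvation terms of a full MM/PBSA binding energy are
#' deliberately not part of this decomposition and are carried as explicit
#' "not computed" markers.
#'
#' @param traj an `md_trajectory`.
#' @param params a [param_table()] covering every ligand and receptor atom.
#' @param cutoff optional hard distance cutoff in nm (`NULL` = none).
#' @param dielectric relative dielectric constant for the Coulomb term.
#' @return object of class `energy_decomposition` with `per_residue`
#'   (mean +/- sem per receptor residue), `totals`, `per_frame`, and
#'   `polar_solv`/`nonpolar_solv` markers (always `NA`, out of scope).
#' @export
decompose_energy <- function(traj, params, cutoff = NULL, dielectric = 1) {
  stopifnot(inherits(traj, "md_trajectory"))
  f1 <- traj$frames[[1]]
  lig <- f1$partition$ligand
  rec <- f1$partition$receptor
  if (!length(lig) || !length(rec))
    stop("energy decomposition needs non-empty ligand and receptor")
  pl <- .match_params(f1$atoms, lig, params)
  pr <- .match_params(f1$atoms, rec, params)
  # pair-constant matrices (receptor x ligand)
  qq <- outer(pr$charge, pl$charge)
  sig <- outer(pr$sigma, pl$sigma, function(a, b) (a + b) / 2)
  eps <- outer(pr$epsilon, pl$epsilon, function(a, b) sqrt(a * b))
  resids <- f1$atoms$resid[rec]
  res_levels <- sort(unique(resids))
  n_frames <- length(traj$frames)
  evdw_rf <- matrix(0, length(res_levels), n_frames,
                    dimnames = list(res_levels, NULL))
  eele_rf <- evdw_rf
  for (fi in seq_len(n_frames)) {
    fr <- traj$frames[[fi]]
    xr <- coords_matrix(fr, rec) * 0.1  # Angstrom -> nm
    xl <- coords_matrix(fr, lig) * 0.1
    d2 <- outer(rowSums(xr^2), rowSums(xl^2), `+`) - 2 * xr %*% t(xl)
    r <- sqrt(pmax(d2, 1e-12))
    mask <- if (is.null(cutoff)) 1 else (r <= cutoff) * 1
    sr6 <- (sig / r)^6
    evdw <- 4 * eps * (sr6^2 - sr6) * mask
    eele <- .coulomb_f * qq / (dielectric * r) * mask
    evdw_rf[, fi] <- rowsum(rowSums(evdw), resids)[, 1]
    eele_rf[, fi] <- rowsum(rowSums(eele), resids)[, 1]
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  per_residue <- data.frame(
    resid = res_levels,
    resname = f1$atoms$resname[rec][match(res_levels, resids)],
    e_vdw = rowMeans(evdw_rf), e_vdw_sem = apply(evdw_rf, 1, sem),
    e_ele = rowMeans(eele_rf), e_ele_sem = apply(eele_rf, 1, sem))
  per_residue$e_total <- per_residue$e_vdw + per_residue$e_ele
  per_frame <- data.frame(frame = seq_len(n_frames),
                          e_vdw = colSums(evdw_rf),
                          e_ele = colSums(eele_rf))
  per_frame$e_total <- per_frame$e_vdw + per_frame$e_ele
  totals <- list(e_vdw = mean(per_frame$e_vdw),
                 e_vdw_sem = sem(per_frame$e_vdw),
                 e_ele = mean(per_frame$e_ele),
                 e_ele_sem = sem(per_frame$e_ele),
                 e_total = mean(per_frame$e_total),
                 e_total_sem = sem(per_frame$e_total))
  structure(list(per_residue = per_residue, totals = totals,
                 per_frame = per_frame,
                 polar_solv = NA_real_, nonpolar_solv = NA_real_,
                 cutoff = cutoff, dielectric = dielectric),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Gas-phase MM interaction energy over %d frame(s):\n",
              nrow(x$per_frame)))
  cat(sprintf("  E_vdw  = %10.3f +/- %.3f kJ/mol\n", t$e_vdw, t$e_vdw_sem))
  cat(sprintf("  E_ele  = %10.3f +/- %.3f kJ/mol\n", t$e_ele, t$e_ele_sem))
  cat(sprintf("  E_MM   = %10.3f +/- %.3f kJ/mol\n", t$e_total,
              t$e_total_sem))
  cat("  polar/non-polar solvation: not computed (MM terms only)\n")
  invisible(x)
}

#' Export the per-residue energy report as TSV
#' @param decomposition an `energy_decomposition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energy_report <- function(decomposition, path) {
  utils::write.table(decomposition$per_residue, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
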