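# model_io: multi-model PDB trajectories and the Frame/Trajectory containers.

.default_water_resnames <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "SPC")
.ion_elements <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "BR", "I")

#' Construct a trajectory frame
#'
#' A frame is one time step of a trajectory: an ordered atom table plus the
#' partition of atom indices into receptor / ligand / water / ion. The
#' partition is assigned from residue names (waters and ligand) and an
#' element heuristic for monatomic ions; everything else is receptor.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`. Missing `element` entries
#'   are inferred from the atom name.
#' @param index 1-based frame number.
#' @param time_ps optional time stamp in picoseconds.
#' @param ligand_resnames,water_resnames residue names identifying the
#'   ligand and water partitions.
#' @return an object of class `md_frame`.
#' @export
new_frame <- function(atoms, index = 1L, time_ps = NA_real_,
                      ligand_resnames = "EST",
                      water_resnames = .default_water_resnames) {
  required <- c("serial", "name", "resname", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("frame has zero atoms")
  atoms$resid <- as.integer(atoms$resid)
  atoms$serial <- as.integer(atoms$serial)
  if (is.null(atoms$element)) atoms$element <- NA_character_
  noel <- is.na(atoms$element) | !nzchar(trimws(atoms$element))
  if (any(noel)) atoms$element[noel] <- infer_element(atoms$name[noel])
  atoms$element <- toupper(trimws(atoms$element))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in frame")
  frame <- structure(
    list(index = as.integer(index), time_ps = time_ps,
         atoms = atoms[, c("serial", "name", "element", "resname",
                           "resid", "chain", "x", "y", "z")],
         partition = NULL, roles = NULL),
    class = "md_frame")
  frame$partition <- partition_atoms(frame$atoms, ligand_resnames,
                                     water_resnames)
  frame
}

partition_atoms <- function(atoms, ligand_resnames, water_resnames) {
  n <- nrow(atoms)
  resname <- toupper(atoms$resname)
  is_water <- resname %in% toupper(water_resnames)
  is_ligand <- !is_water & resname %in% toupper(ligand_resnames)
  # monatomic-ion heuristic: a one-atom residue whose element is a common ion
  reskey <- paste(atoms$chain, atoms$resid, resname)
  res_size <- table(reskey)
  is_ion <- !is_water & !is_ligand &
    res_size[reskey] == 1 & atoms$element %in% .ion_elements
  is_receptor <- !is_water & !is_ligand & !is_ion
  part <- list(receptor = which(unname(is_receptor)),
               ligand = which(unname(is_ligand)),
               water = which(unname(is_water)),
               ion = which(unname(is_ion)))
  stopifnot(sum(lengths(part)) == n)
  part
}

# Element inference from PDB atom names when columns 77-78 are absent.
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("CL", "BR", "MG", "ZN", "MN", "FE")] <-
    two[two %in% c("CL", "BR", "MG", "ZN", "MN", "FE")]
  el[nm %in% c("NA", "NA+")] <- "NA"
  # GROMACS-style water hydrogens HW1/HW2, H5' etc. start with H; digits-first
  # names like 1H5' shift the element to position 2
  digit_first <- grepl("^[0-9]", nm)
  el[digit_first] <- substr(nm[digit_first], 2, 2)
  el
}

#' Construct a trajectory from frames
#'
#' @param frames list of `md_frame` objects sharing one topology (atom names,
#'   residues and order identical in every frame).
#' @return object of class `md_trajectory` with a `topology_hash` field; any
#'   frame whose topology differs from frame 1 is an error.
#' @export
new_trajectory <- function(frames) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  keys <- vapply(frames, topology_key, "")
  if (any(keys != keys[1]))
    stop("frames differ in topology (atom names/residues/order)")
  for (i in seq_along(frames)) frames[[i]]$index <- i
  structure(list(frames = frames, topology_hash = keys[1]),
            class = "md_trajectory")
}

topology_key <- function(frame) {
  a <- frame$atoms
  paste(a$name, a$resname, a$resid, a$chain, sep = ":", collapse = "|")
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

#' @export
print.md_trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat("MD trajectory:", length(x$frames), "frame(s),",
      nrow(f1$atoms), "atoms/frame\n")
  cat("  partition: receptor", length(f1$partition$receptor),
      "| ligand", length(f1$partition$ligand),
      "| water", length(f1$partition$water),
      "| ion", length(f1$partition$ion), "\n")
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat("MD frame", x$index, "with", nrow(x$atoms), "atoms\n")
  invisible(x)
}

coords_matrix <- function(frame, idx = NULL) {
  m <- as.matrix(frame$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Read a multi-model PDB trajectory
#'
#' Reads MODEL/ENDMDL blocks (or a single implicit model) through
#' [bio3d::read.pdb()] and assembles an `md_trajectory`. Elements come from
#' PDB columns 77-78 when present, else are inferred from atom names. The
#' receptor / ligand / water / ion partition is assigned per residue name.
#'
#' @param path PDB file.
#' @param ligand_resnames,water_resnames residue names for the ligand and
#'   water partitions.
#' @return an `md_trajectory`.
#' @export
read_pdb_trajectory <- function(path, ligand_resnames = "EST",
                                water_resnames = .default_water_resnames) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  n_model <- sum(startsWith(lines, "MODEL"))
  if (n_model > 1) {
    # equal atom counts per MODEL block is a hard precondition
    counts <- integer(0)
    cur <- NA_integer_
    for (ln in lines) {
      if (startsWith(ln, "MODEL")) cur <- 0L
      else if (startsWith(ln, "ENDMDL")) { counts <- c(counts, cur); cur <- NA_integer_ }
      else if (!is.na(cur) && (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")))
        cur <- cur + 1L
    }
    if (length(unique(counts)) > 1)
      stop("MODEL blocks have differing atom counts: ",
           paste(unique(counts), collapse = ", "))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = n_model > 1,
                                          verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("PDB file contains zero atoms")
  atoms0 <- data.frame(
    serial = at$eleno, name = at$elety, element = at$elesy,
    resname = at$resid, resid = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    a <- atoms0
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
    new_frame(a, index = i, ligand_resnames = ligand_resnames,
              water_resnames = water_resnames)
  })
  traj <- new_trajectory(frames)
  attr(traj, "source") <- path
  traj
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame in standard fixed-column PDB
#' format (coordinates as 8.3 fixed point, element symbols in columns
#' 77-78), re-readable by [read_pdb_trajectory()].
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @param remarks optional character vector written as REMARK records.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path, remarks = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!length(traj$frames)) stop("empty trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(remarks)) remarks <- attr(traj, "remarks")
  for (r in remarks) writeLines(sprintf("REMARK   6 %s", r), con)
  hetres <- c("EST", .default_water_resnames, "LIG")
  for (fr in traj$frames) {
    writeLines(sprintf("MODEL     %4d", fr$index), con)
    a <- fr$atoms
    if (any(nchar(a$name) > 4)) stop("atom names longer than 4 characters")
    if (any(abs(c(a$x, a$y, a$z)) >= 10000))
      stop("coordinates overflow the PDB 8.3 field")
    rectype <- ifelse(toupper(a$resname) %in% hetres, "HETATM", "ATOM  ")
    # column-29 alignment rule: 1-3 char names start in column 14
    name_fmt <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                       sprintf("%-4s", a$name))
    writeLines(sprintf("%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rectype, a$serial %% 100000, name_fmt, a$resname,
                       a$chain, a$resid %% 10000, a$x, a$y, a$z, 1, 0,
                       a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
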