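# Aggregation of per-frame interaction records into frequency reports.

.specific_classes <- c("hbond", "water_bridge", "pistack")
.all_classes <- c("hbond", "pistack", "water_bridge", "hydrophobic")

#' Ligand anchor map
#'
#' Maps ligand atom names (and ring identifiers, for pi-stacking) to anchor
#' labels -- the named functional-group positions to which interactions are
#' attributed. Atoms without an entry fall back to `default`.
#'
#' @param map named character vector, e.g.
#'   `c(O3 = "3", HO3 = "3", O17 = "17-b", ring1 = "A-ring")`.
#' @param default label for unmapped atoms.
#' @return object of class `anchor_map`.
#' @export
anchor_map <- function(map, default = "other") {
  stopifnot(is.character(map), !is.null(names(map)))
  if (anyDuplicated(names(map))) stop("duplicate atom names in anchor map")
  structure(list(map = map, default = default), class = "anchor_map")
}

#' Default anchors for the two-hydroxyl ligand mimic shipped in the fixture
#' generator: the "3" and "17-b" hydroxyl positions plus the aromatic
#' "A-ring".
#' @rdname anchor_map
#' @export
default_anchors <- function() {
  anchor_map(c(O3 = "3", HO3 = "3", O17 = "17-β", HO17 = "17-β",
               ring1 = "A-ring"))
}

anchor_of <- function(lig_atom, anchors) {
  out <- anchors$map[lig_atom]
  out[is.na(out)] <- anchors$default
  unname(out)
}

.check_frames <- function(records, n_frames) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (NROW(records) && any(records$frame > n_frames | records$frame < 1))
    stop("records reference frames outside 1..n_frames")
}

base_label <- function(records) paste0(records$resname, records$resid)

#' Per-base interaction frequency table
#'
#' For each receptor base and interaction class, the percentage of frames
#' in which at least one record of that class involves that base
#' (frame-presence semantics, as used for relative-frequency tables over a
#' simulation). The `total` column is the percentage of frames with at
#' least one record of any class for that base -- a union over frames, not
#' the sum of the class columns. `semantics = "records"` instead reports
#' each base's share of the class's records.
#'
#' @param records interaction record data.frame.
#' @param n_frames number of frames in the profiled trajectory.
#' @param semantics `"frames"` (default) or `"records"`.
#' @return data.frame with one row per base and one column per class, plus
#'   `total`; percentages unrounded (round at presentation).
#' @export
per_base_table <- function(records, n_frames,
                           semantics = c("frames", "records")) {
  semantics <- match.arg(semantics)
  .check_frames(records, n_frames)
  out <- data.frame(base = character(0), resid = integer(0),
                    hbond = numeric(0), pistack = numeric(0),
                    water_bridge = numeric(0), hydrophobic = numeric(0),
                    total = numeric(0), stringsAsFactors = FALSE)
  if (!NROW(records)) return(out)
  records$base <- base_label(records)
  bases <- unique(records[order(records$resid), c("base", "resid")])
  for (r in seq_len(nrow(bases))) {
    sub <- records[records$base == bases$base[r], ]
    vals <- vapply(.all_classes, function(cl) {
      cls <- sub[sub$iclass == cl, ]
      if (semantics == "frames") {
        100 * length(unique(cls$frame)) / n_frames
      } else {
        tot <- sum(records$iclass == cl)
        if (tot == 0) 0 else 100 * nrow(cls) / tot
      }
    }, 0.0)
    total <- if (semantics == "frames") {
      100 * length(unique(sub$frame)) / n_frames
    } else {
      100 * nrow(sub) / nrow(records)
    }
    out <- rbind(out, data.frame(
      base = bases$base[r], resid = bases$resid[r],
      hbond = vals[["hbond"]], pistack = vals[["pistack"]],
      water_bridge = vals[["water_bridge"]],
      hydrophobic = vals[["hydrophobic"]], total = total,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Per-anchor interaction count table
#'
#' Absolute record counts of hydrogen bonds and water bridges (by default)
#' attributed to each ligand anchor, with relative percentages within each
#' class column and a combined total column -- the layout of a
#' per-position interaction summary. Pi-stacking records are attributed via
#' the ligand ring identifier when included in `classes`.
#'
#' @param records interaction record data.frame.
#' @param anchors an [anchor_map()].
#' @param classes interaction classes to tabulate.
#' @return data.frame with columns `anchor`, `<class>_n`, `<class>_rel`,
#'   `total_n`, `total_rel`; percentages unrounded. Class relative columns
#'   each sum to 100 whenever any record of that class exists.
#' @export
per_anchor_table <- function(records, anchors = default_anchors(),
                             classes = c("hbond", "water_bridge")) {
  if (NROW(records)) {
    records <- records[records$iclass %in% classes, ]
  }
  if (!NROW(records)) {
    out <- data.frame(anchor = character(0), stringsAsFactors = FALSE)
    for (cl in classes) { out[[paste0(cl, "_n")]] <- integer(0)
                          out[[paste0(cl, "_rel")]] <- numeric(0) }
    out$total_n <- integer(0); out$total_rel <- numeric(0)
    return(out)
  }
  records$anchor <- anchor_of(records$lig_atom, anchors)
  anchor_levels <- unique(c(intersect(unname(anchors$map), records$anchor),
                            records$anchor))
  out <- data.frame(anchor = anchor_levels, stringsAsFactors = FALSE)
  grand <- nrow(records)
  for (cl in classes) {
    n_cl <- vapply(anchor_levels, function(an)
      sum(records$iclass == cl & records$anchor == an), 0L)
    tot_cl <- sum(n_cl)
    out[[paste0(cl, "_n")]] <- n_cl
    out[[paste0(cl, "_rel")]] <- if (tot_cl) 100 * n_cl / tot_cl else
      rep(0, length(n_cl))
  }
  out$total_n <- vapply(anchor_levels, function(an)
    sum(records$anchor == an), 0L)
  out$total_rel <- 100 * out$total_n / grand
  rownames(out) <- NULL
  out
}

#' Combination shares of specific interaction classes
#'
#' Labels every frame with the subset of specific classes present in it and
#' reports the percentage of frames per subset and per cardinality
#' (exactly one / two / three classes), plus the unbound share. Hydrophobic
#' contacts are non-specific and excluded by default.
#'
#' @param records interaction record data.frame.
#' @param n_frames number of frames profiled.
#' @param classes subset of `c("hbond", "water_bridge", "pistack")`.
#' @return object of class `combo_shares`: list with `subsets` (named
#'   percentages, names like `"hbond+pistack"`), `by_cardinality`,
#'   `unbound`, and `n_frames`.
#' @export
combination_shares <- function(records, n_frames,
                               classes = .specific_classes) {
  stopifnot(all(classes %in% .specific_classes))
  .check_frames(records, n_frames)
  labels <- character(n_frames)
  if (NROW(records)) {
    sub <- records[records$iclass %in% classes, ]
    for (f in unique(sub$frame)) {
      present <- sort(unique(sub$iclass[sub$frame == f]))
      labels[f] <- paste(present, collapse = "+")
    }
  }
  nonempty <- labels[nzchar(labels)]
  subsets <- if (length(nonempty)) {
    100 * table(nonempty) / n_frames
  } else table(character(0))
  card <- if (length(subsets)) {
    vapply(strsplit(names(subsets), "+", fixed = TRUE), length, 0L)
  } else integer(0)
  by_card <- vapply(seq_along(classes), function(k)
    sum(subsets[card == k]), 0.0)
  names(by_card) <- c("one", "two", "three")[seq_along(classes)]
  structure(list(
    subsets = stats::setNames(as.numeric(subsets), names(subsets)),
    by_cardinality = by_card,
    unbound = 100 * sum(!nzchar(labels)) / n_frames,
    n_frames = n_frames, classes = classes), class = "combo_shares")
}

#' @export
print.combo_shares <- function(x, ...) {
  cat("Frame shares by interaction-class combination (",
      x$n_frames, " frames):\n", sep = "")
  for (nm in names(sort(x$subsets, decreasing = TRUE)))
    cat(sprintf("  %-28s %6.2f %%\n", nm, round_half_up(x$subsets[[nm]], 2)))
  cat(sprintf("  %-28s %6.2f %%\n", "unbound", round_half_up(x$unbound, 2)))
  cat("By cardinality:",
      paste(sprintf("%s %.2f%%", names(x$by_cardinality),
                    round_half_up(x$by_cardinality, 2)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Bound fraction of the trajectory
#'
#' Percentage of frames with at least one record of any listed class;
#' specific classes only by default, so the unbound share is
#' `100 - bound_fraction`.
#'
#' @inheritParams combination_shares
#' @return a percentage in `[0, 100]`.
#' @export
bound_fraction <- function(records, n_frames, classes = .specific_classes) {
  .check_frames(records, n_frames)
  if (!NROW(records)) return(0)
  sub <- records[records$iclass %in% classes, ]
  100 * length(unique(sub$frame)) / n_frames
}

#' Chemical-type distribution per anchor and class
#'
#' Counts and percentages of records by chemical type label (e.g.
#' `"O–H⋯O–H⋯O"` vs `"N–H⋯O–H⋯O"`) within each
#' (anchor, class) cell.
#'
#' @param records interaction record data.frame.
#' @param anchors an [anchor_map()].
#' @return data.frame with columns `anchor`, `iclass`, `chem_type`, `n`,
#'   `rel` (percent within anchor x class).
#' @export
chem_type_distribution <- function(records, anchors = default_anchors()) {
  if (!NROW(records))
    return(data.frame(anchor = character(0), iclass = character(0),
                      chem_type = character(0), n = integer(0),
                      rel = numeric(0), stringsAsFactors = FALSE))
  records$anchor <- anchor_of(records$lig_atom, anchors)
  agg <- stats::aggregate(list(n = records$frame),
                          by = list(anchor = records$anchor,
                                    iclass = records$iclass,
                                    chem_type = records$chem_type),
                          FUN = length)
  cell <- paste(agg$anchor, agg$iclass)
  cell_tot <- tapply(agg$n, cell, sum)
  agg$rel <- 100 * agg$n / as.numeric(cell_tot[cell])
  agg <- agg[order(agg$anchor, agg$iclass, -agg$n), ]
  rownames(agg) <- NULL
  agg
}

#' Format a report table for presentation
#'
#' Applies half-up rounding to 2 decimals to every numeric column --
#' rounding happens only here, never inside the aggregation math.
#'
#' @param table a report data.frame.
#' @param digits decimal places.
#' @return the data.frame with rounded numeric columns.
#' @export
format_report <- function(table, digits = 2) {
  num <- vapply(table, is.numeric, TRUE) &
    !vapply(table, is.integer, TRUE)
  table[num] <- lapply(table[num], round_half_up, digits = digits)
  table
}
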