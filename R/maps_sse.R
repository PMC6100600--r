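# Minimum inter-residue distance maps and secondary-structure annotation.

#' Minimum inter-residue distance map
#'
#' Entry (i, j) is the minimum pairwise atom distance between residues i and
#' j, over heavy atoms (`metric = "heavy"`, default) or all atoms including
#' hydrogens (`metric = "all"`). Receptor residues are ordered by residue
#' id; the ligand is appended as the final label when included.
#'
#' @param frame an `md_frame` with at least 2 residues.
#' @param include_ligand append a ligand row/column (default `TRUE` when a
#'   ligand partition is present).
#' @param metric `"heavy"` or `"all"`.
#' @return object of class `distance_map`: list with `labels`, `resids`,
#'   symmetric `matrix` (A, zero diagonal) and `metric`.
#' @export
distance_map <- function(frame, include_ligand = NULL,
                         metric = c("heavy", "all")) {
  metric <- match.arg(metric)
  a <- frame$atoms
  part <- frame$partition
  if (is.null(include_ligand)) include_ligand <- length(part$ligand) > 0
  keep_h <- metric == "all"
  groups <- list()
  rec <- part$receptor
  for (rid in sort(unique(a$resid[rec]))) {
    idx <- rec[a$resid[rec] == rid]
    if (!keep_h) idx <- idx[a$element[idx] != "H"]
    groups[[paste0(a$resname[idx[1]], rid)]] <- list(idx = idx, resid = rid)
  }
  if (include_ligand && length(part$ligand)) {
    idx <- part$ligand
    if (!keep_h) idx <- idx[a$element[idx] != "H"]
    groups[[a$resname[idx[1]]]] <- list(idx = idx,
                                        resid = a$resid[idx[1]])
  }
  if (length(groups) < 2) stop("need at least 2 residues for a distance map")
  xyz <- coords_matrix(frame)
  k <- length(groups)
  m <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      gi <- groups[[i]]$idx; gj <- groups[[j]]$idx
      dm <- sqrt(pmax(outer(rowSums(xyz[gi, , drop = FALSE]^2),
                            rowSums(xyz[gj, , drop = FALSE]^2), `+`) -
                        2 * xyz[gi, , drop = FALSE] %*%
                        t(xyz[gj, , drop = FALSE]), 0))
      m[i, j] <- m[j, i] <- min(dm)
    }
  }
  structure(list(labels = names(groups),
                 resids = vapply(groups, function(g) g$resid, 0L),
                 matrix = m, metric = metric),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("Distance map (", x$metric, "-atom metric) over ",
      length(x$labels), " residues; range ",
      sprintf("%.2f-%.2f A\n", min(x$matrix[upper.tri(x$matrix)]),
              max(x$matrix)), sep = "")
  invisible(x)
}

#' @export
plot.distance_map <- function(x, ...) {
  k <- length(x$labels)
  graphics::image(seq_len(k), seq_len(k), x$matrix,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(k), labels = x$labels, las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(k), labels = x$labels, las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Export a distance map as a TSV matrix
#' @param map a `distance_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_map <- function(map, path) {
  utils::write.table(map$matrix, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Parse a secondary structure into a base-pair list
#'
#' Accepts dot-bracket notation (`"((..))"`, nested brackets only) or an
#' explicit pair list (2-column matrix/data.frame of 1-based indices).
#' Both representations of equivalent structure yield the identical
#' canonical output: a 2-column integer matrix sorted by the first index,
#' with i < j in every row.
#'
#' @param spec dot-bracket string, or 2-column matrix/data.frame.
#' @param length optional sequence length for range validation of pair
#'   lists.
#' @return integer matrix with columns `i`, `j`.
#' @export
parse_secondary_structure <- function(spec, length = NULL) {
  if (is.character(spec) && length(spec) == 1) {
    chars <- strsplit(spec, "")[[1]]
    bad <- setdiff(chars, c("(", ")", "."))
    if (length(bad)) stop("invalid dot-bracket characters: ",
                          paste(unique(bad), collapse = " "))
    stack <- integer(0)
    pairs <- NULL
    for (k in seq_along(chars)) {
      if (chars[k] == "(") stack <- c(stack, k)
      else if (chars[k] == ")") {
        if (!length(stack)) stop("unbalanced brackets: unmatched ')' at ", k)
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced brackets: unmatched '('")
  } else {
    pairs <- as.matrix(spec)
    if (is.null(pairs) || (nrow(pairs) && ncol(pairs) != 2))
      stop("pair list must have two columns")
    storage.mode(pairs) <- "integer"
    if (nrow(pairs)) {
      pairs <- t(apply(pairs, 1, sort))
      if (any(pairs[, 1] == pairs[, 2])) stop("a base cannot pair with itself")
      if (anyDuplicated(as.vector(pairs)))
        stop("duplicated index in pair list")
      if (any(pairs < 1)) stop("pair indices must be 1-based positive")
      if (!is.null(length) && any(pairs > length))
        stop("pair index out of range for length ", length)
    }
  }
  if (is.null(pairs) || !nrow(pairs))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' Annotate secondary-structure elements from a pair list
#'
#' Assigns every residue one fine label: `tail5` / `tail3` (unpaired 5'/3'
#' ends), `stem` (paired, in a helix that encloses further pairs),
#' `hairpin-stem` (paired, closing a pair-free region), `hairpin-loop`
#' (unpaired inside a hairpin-closing stem), `interior-loop` (unpaired
#' between two stems, covering bulges), or `unpaired-other` (e.g.
#' multiloop). Coarse labels merge hairpin-stem and hairpin-loop into
#' "hairpin loop", matching the convention of region tables that count the
#' whole stem-loop as the hairpin.
#'
#' Crossing pairs (pseudoknots) are refused with an error rather than
#' silently flattened.
#'
#' @param pairs output of [parse_secondary_structure()].
#' @param length sequence length (number of residues).
#' @return object of class `sse_annotation`: `fine` and `coarse` label
#'   vectors (length `length`), the pair matrix, and the helix list.
#' @export
annotate_sse <- function(pairs, length) {
  pairs <- parse_secondary_structure(pairs, length = length)
  n <- as.integer(length)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs) - 1)) {
      for (s in (r + 1):nrow(pairs)) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        k <- pairs[s, 1]; l <- pairs[s, 2]
        crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
        if (crossing)
          stop("crossing base pairs (pseudoknot): (", i, ",", j, ") vs (",
               k, ",", l, ")")
      }
    }
  }
  partner <- rep(NA_integer_, n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  fine <- rep("unpaired-other", n)

  # helices: maximal stacks of pairs (i,j),(i+1,j-1),...
  helices <- list()
  if (nrow(pairs)) {
    pairkey <- paste(pairs[, 1], pairs[, 2])
    used <- rep(FALSE, nrow(pairs))
    ord <- order(pairs[, 1])
    for (r in ord) {
      if (used[r]) next
      run <- r
      repeat {
        nxt <- which(pairs[, 1] == pairs[run[length(run)], 1] + 1 &
                       pairs[, 2] == pairs[run[length(run)], 2] - 1)
        if (!length(nxt)) break
        run <- c(run, nxt)
      }
      used[run] <- TRUE
      inner <- pairs[run[length(run)], ]
      enclosed <- if (inner[2] - inner[1] > 1)
        (inner[1] + 1):(inner[2] - 1) else integer(0)
      is_hairpin <- !any(!is.na(partner[enclosed]))
      helices[[length(helices) + 1]] <-
        list(pairs = pairs[run, , drop = FALSE], hairpin = is_hairpin)
    }
  }
  for (h in helices) {
    lab <- if (h$hairpin) "hairpin-stem" else "stem"
    fine[as.vector(h$pairs)] <- lab
  }

  paired_pos <- which(!is.na(partner))
  if (length(paired_pos)) {
    first_p <- min(paired_pos); last_p <- max(paired_pos)
  } else {
    first_p <- Inf; last_p <- -Inf
  }
  for (k in which(is.na(partner))) {
    if (k < first_p) { fine[k] <- "tail5"; next }
    if (k > last_p) { fine[k] <- "tail3"; next }
    # innermost enclosing pair
    enc <- pairs[pairs[, 1] < k & pairs[, 2] > k, , drop = FALSE]
    if (!nrow(enc)) { fine[k] <- "unpaired-other"; next }
    span <- enc[, 2] - enc[, 1]
    inner <- enc[which.min(span), ]
    region <- (inner[1] + 1):(inner[2] - 1)
    inner_pairs <- pairs[pairs[, 1] %in% region & pairs[, 2] %in% region, ,
                         drop = FALSE]
    if (!nrow(inner_pairs)) {
      fine[k] <- "hairpin-loop"
    } else {
      # count distinct branch helices directly inside the enclosing pair
      branches <- inner_pairs
      outermost <- branches[!vapply(seq_len(nrow(branches)), function(b)
        any(branches[, 1] < branches[b, 1] & branches[, 2] > branches[b, 2]),
        TRUE), , drop = FALSE]
      fine[k] <- if (nrow(outermost) == 1) "interior-loop" else
        "unpaired-other"
    }
  }

  coarse_map <- c(tail5 = "5'-end", stem = "stem",
                  `interior-loop` = "interior loop",
                  `hairpin-stem` = "hairpin loop",
                  `hairpin-loop` = "hairpin loop", tail3 = "3'-end",
                  `unpaired-other` = "other")
  structure(list(fine = fine, coarse = unname(coarse_map[fine]),
                 pairs = pairs, helices = helices, length = n),
            class = "sse_annotation")
}

#' @export
print.sse_annotation <- function(x, ...) {
  cat("SSE annotation over", x$length, "residues,", nrow(x$pairs),
      "base pairs\n")
  for (lab in unique(x$coarse)) {
    ids <- which(x$coarse == lab)
    runs <- split(ids, cumsum(c(1, diff(ids) != 1)))
    rng <- vapply(runs, function(r) if (length(r) > 1)
      paste0(r[1], "-", r[length(r)]) else as.character(r[1]), "")
    cat(sprintf("  %-14s %s\n", lab, paste(rng, collapse = ", ")))
  }
  invisible(x)
}

#' Check which annotated base pairs are formed in 3D
#'
#' A pair counts as formed when its minimum inter-residue distance in the
#' map is at most `pair_threshold`.
#'
#' @param map a [distance_map()] covering the annotated residues.
#' @param annotation an [annotate_sse()] result.
#' @param pair_threshold distance threshold in Angstrom (default 3.0).
#' @return data.frame with columns `i`, `j`, `distance`, `formed`.
#' @export
verify_sse_formation <- function(map, annotation, pair_threshold = 3.0) {
  pairs <- annotation$pairs
  pos <- match(pairs, map$resids)
  if (anyNA(pos)) stop("distance map does not cover all annotated residues")
  dim(pos) <- dim(pairs)
  dist <- vapply(seq_len(nrow(pairs)), function(r)
    map$matrix[pos[r, 1], pos[r, 2]], 0.0)
  data.frame(i = pairs[, 1], j = pairs[, 2], distance = dist,
             formed = dist <= pair_threshold)
}
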