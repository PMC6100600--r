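#' Geometric thresholds for interaction detection
#'
#' Builds the configuration object consumed by every detector. Three named
#' presets ship with the package:
#'
#' * `"plip-default"`: the published PLIP default criteria -- donor-acceptor
#'   distance \eqn{\le} 4.1 A with D-H...A angle \eqn{\ge} 100 deg for
#'   hydrogen bonds; carbon-carbon distance \eqn{\le} 4.0 A for hydrophobic
#'   contacts; ring-centroid distance \eqn{\le} 5.5 A, lateral offset
#'   \eqn{\le} 2.0 A and plane angle \eqn{\le} 30 deg (parallel) or within
#'   60-90 deg (T-shaped) for pi-stacking; water-bridge leg distances within
#'   2.5-4.1 A with omega in 71-140 deg and theta \eqn{\ge} 100 deg.
#' * `"strict"`: textbook hydrogen-bond values (D-A \eqn{\le} 3.5 A, angle
#'   \eqn{\ge} 120 deg) for sensitivity checks; other classes unchanged.
#' * `"gromacs"`: the preset used for intramolecular hydrogen-bond counting
#'   (D-A \eqn{\le} 3.5 A, D-H...A angle \eqn{\ge} 150 deg).
#'
#' @param preset name of a threshold preset.
#' @param ... individual thresholds overriding the preset, by name (e.g.
#'   `hbond_da_max = 3.2`).
#' @param strict_hydrogens if `TRUE` (default), donor typing and angle tests
#'   require explicit hydrogens, as in an all-atom MD trajectory. The lenient
#'   mode (`FALSE`) types every N/O as donor and acceptor, skips angle tests
#'   and tags every downstream record with `mode = "lenient"`.
#' @return an object of class `interaction_config` (a named list).
#' @export
interaction_config <- function(preset = c("plip-default", "strict", "gromacs"),
                               ..., strict_hydrogens = TRUE) {
  preset <- match.arg(preset)
  cfg <- list(
    hbond_da_max = 4.1,
    hbond_angle_min = 100,
    hydrophobic_max = 4.0,
    pistack_center_max = 5.5,
    pistack_offset_max = 2.0,
    pistack_parallel_angle_max = 30,
    pistack_tshape_angle_min = 60,
    pistack_tshape_angle_max = 90,
    waterbridge_dist_min = 2.5,
    waterbridge_dist_max = 4.1,
    waterbridge_omega_min = 71,
    waterbridge_omega_max = 140,
    waterbridge_theta_min = 100,
    covalent_heavy_max = 1.9,
    covalent_h_max = 1.25,
    ring_planarity_rms_max = 0.2
  )
  if (preset == "strict") {
    cfg$hbond_da_max <- 3.5
    cfg$hbond_angle_min <- 120
  } else if (preset == "gromacs") {
    cfg$hbond_da_max <- 3.5
    cfg$hbond_angle_min <- 150
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg$preset <- preset
  cfg$strict_hydrogens <- isTRUE(strict_hydrogens)
  validate_interaction_config(cfg)
  structure(cfg, class = "interaction_config")
}

validate_interaction_config <- function(cfg) {
  dists <- c("hbond_da_max", "hydrophobic_max", "pistack_center_max",
             "pistack_offset_max", "waterbridge_dist_min",
             "waterbridge_dist_max", "covalent_heavy_max", "covalent_h_max")
  for (d in dists) {
    if (!is.numeric(cfg[[d]]) || cfg[[d]] <= 0)
      stop("config field ", d, " must be a positive distance")
  }
  angs <- c("hbond_angle_min", "pistack_parallel_angle_max",
            "pistack_tshape_angle_min", "pistack_tshape_angle_max",
            "waterbridge_omega_min", "waterbridge_omega_max",
            "waterbridge_theta_min")
  for (a in angs) {
    if (!is.numeric(cfg[[a]]) || cfg[[a]] < 0 || cfg[[a]] > 180)
      stop("config field ", a, " must lie in [0, 180] degrees")
  }
  if (cfg$waterbridge_dist_min >= cfg$waterbridge_dist_max)
    stop("waterbridge_dist_min must be < waterbridge_dist_max")
  if (cfg$waterbridge_omega_min >= cfg$waterbridge_omega_max)
    stop("waterbridge_omega_min must be < waterbridge_omega_max")
  if (cfg$pistack_tshape_angle_min >= cfg$pistack_tshape_angle_max)
    stop("pistack_tshape_angle_min must be < pistack_tshape_angle_max")
  invisible(cfg)
}

#' Serialize / restore an interaction configuration as JSON
#'
#' @param config an `interaction_config` object.
#' @param path file to write to / read from.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   restored `interaction_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "interaction_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- raw$preset %||% "plip-default"
  strict <- raw$strict_hydrogens %||% TRUE
  raw$preset <- NULL
  raw$strict_hydrogens <- NULL
  do.call(interaction_config,
          c(list(preset = preset, strict_hydrogens = strict), raw))
}

#' @export
print.interaction_config <- function(x, ...) {
  cat("Interaction detection config (preset: ", x$preset,
      if (!x$strict_hydrogens) ", lenient hydrogens", ")\n", sep = "")
  cat(sprintf("  H-bond:      D-A <= %.2f A, D-H...A >= %g deg\n",
              x$hbond_da_max, x$hbond_angle_min))
  cat(sprintf("  hydrophobic: C-C <= %.2f A\n", x$hydrophobic_max))
  cat(sprintf("  pi-stack:    centroid <= %.2f A, offset <= %.2f A, parallel <= %g deg, T-shape %g-%g deg\n",
              x$pistack_center_max, x$pistack_offset_max,
              x$pistack_parallel_angle_max, x$pistack_tshape_angle_min,
              x$pistack_tshape_angle_max))
  cat(sprintf("  water bridge: legs %.2f-%.2f A, omega %g-%g deg, theta >= %g deg\n",
              x$waterbridge_dist_min, x$waterbridge_dist_max,
              x$waterbridge_omega_min, x$waterbridge_omega_max,
              x$waterbridge_theta_min))
  invisible(x)
}

config_hash <- function(config) {
  fields <- unclass(config)
  fields <- fields[order(names(fields))]
  fnv1a32(paste(names(fields), vapply(fields, format, ""), sep = "=",
                collapse = ";"))
}
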