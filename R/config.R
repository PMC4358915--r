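#' Read a plain-text key-value configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; values that
#' parse as numbers become numeric, whitespace-separated numbers become
#' numeric vectors.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(val, "[[:space:]]+")[[1]]))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Write a key-value configuration
#'
#' @param config Named list of scalars or numeric vectors.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' Recognized keys (all optional, defaults are the study values):
#' particle `charge`, `lj_well_depth`, `lj_rmin_half`, `mass`; geometry
#' `box_x_lo`, `box_x_hi`, `box_y_lo`, `box_y_hi`, `corral_boundary_x`,
#' `membrane_offset`, `planar_force_constant`, `wall_force_constant`;
#' integrator `friction`, `temperature`, `timestep`, `seed`.
#'
#' @param config Named list from [read_config()].
#' @return List with `particles`, `geometry`, `params`.
#' @export
system_from_config <- function(config) {
  pick <- function(f, keys) {
    args <- config[intersect(keys, names(config))]
    do.call(f, args)
  }
  list(particles = pick(particle_spec,
                        c("charge", "lj_well_depth", "lj_rmin_half",
                          "mass")),
       geometry = pick(system_geometry,
                       c("box_x_lo", "box_x_hi", "box_y_lo", "box_y_hi",
                         "corral_boundary_x", "diffusion_plane_z",
                         "membrane_offset", "planar_force_constant",
                         "wall_force_constant")),
       params = pick(integrator_params,
                     c("friction", "temperature", "timestep", "seed")))
}
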