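#' Regular 3D grid potential
#'
#' Scalar field on a regular lattice, used for the core-repulsion map
#' (kcal/mol) and the static electrostatic map (kcal/(mol e)).  Energies and
#' forces are obtained by 3rd-order (quadratic) B-spline interpolation,
#' which has a continuous analytic gradient and reproduces constant and
#' linear fields exactly.
#'
#' @param origin Length-3: coordinates of node (1,1,1), A.
#' @param spacing Length-3 (or scalar) node spacing, A.
#' @param values 3D array (nx, ny, nz) of node values.
#' @param clamp Boundary policy: `TRUE` clamps evaluation points outside the
#'   interpolable interior to the nearest interior value (core-map policy,
#'   zero gradient on the clamped axis); `FALSE` raises an error there
#'   (electrostatic-map policy).
#' @param bbox `"none"`, `"auto"`, or a length-6 numeric
#'   (xlo, xhi, ylo, yhi, zlo, zhi).  `"auto"` computes the bounding box of
#'   non-zero values (plus the spline margin); evaluation outside it
#'   short-circuits to exactly zero, which is valid because the field is
#'   zero there.
#' @return An object of class `grid_potential`.
#' @export
grid_potential <- function(origin, spacing, values, clamp = TRUE,
                           bbox = "none") {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(origin) == 3, length(spacing) == 3, all(spacing > 0),
            is.array(values), length(dim(values)) == 3,
            all(dim(values) >= 3))
  g <- structure(list(origin = as.numeric(origin),
                      spacing = as.numeric(spacing),
                      counts = dim(values),
                      values = values, clamp = clamp, bbox = NULL),
                 class = "grid_potential")
  if (identical(bbox, "auto")) {
    g$bbox <- .grid_auto_bbox(g)
  } else if (is.numeric(bbox)) {
    stopifnot(length(bbox) == 6)
    g$bbox <- as.numeric(bbox)
  }
  g
}

.grid_auto_bbox <- function(g) {
  nz <- which(g$values != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(c(Inf, -Inf, Inf, -Inf, Inf, -Inf))
  lo <- apply(nz, 2, min) - 1 - 2   # spline margin, 0-based
  hi <- apply(nz, 2, max) - 1 + 2
  c(g$origin[1] + c(lo[1], hi[1]) * g$spacing[1],
    g$origin[2] + c(lo[2], hi[2]) * g$spacing[2],
    g$origin[3] + c(lo[3], hi[3]) * g$spacing[3])
}

.grid_clist <- function(g) {
  if (is.null(g)) return(NULL)
  stopifnot(inherits(g, "grid_potential"))
  list(origin = g$origin, spacing = g$spacing,
       counts = as.integer(g$counts), values = as.numeric(g$values),
       clamp = g$clamp, bbox = g$bbox)
}

#' Grid node coordinates along each axis
#' @param g A [grid_potential()].
#' @return List with numeric vectors `x`, `y`, `z`.
#' @export
grid_axes <- function(g) {
  list(x = g$origin[1] + (seq_len(g$counts[1]) - 1) * g$spacing[1],
       y = g$origin[2] + (seq_len(g$counts[2]) - 1) * g$spacing[2],
       z = g$origin[3] + (seq_len(g$counts[3]) - 1) * g$spacing[3])
}

#' Interpolated grid value and gradient
#'
#' Quadratic B-spline interpolation of the field and its analytic gradient
#' at arbitrary points.
#'
#' @param points N x 3 matrix (or length-3 vector) of coordinates, A.
#' @param g A [grid_potential()].
#' @return List with `value` (length N, grid units) and `gradient`
#'   (N x 3, grid units per A).
#' @export
grid_value_and_force <- function(points, g) {
  points <- .as_pos_matrix(points)
  grid_eval_cpp(.grid_clist(g), points)
}

#' Shift a grid between the membrane and simulation frames
#'
#' Maps built in the membrane frame (lipid phosphate plane at z = 0) are
#' shifted down by `membrane_offset` for use in the simulation frame, where
#' the diffusion plane sits at z = 0.
#'
#' @param g A [grid_potential()].
#' @param dz Shift added to the grid origin z, A (e.g.
#'   `-geometry$membrane_offset`).
#' @return The shifted grid.
#' @export
shift_grid_frame <- function(g, dz) {
  g$origin[3] <- g$origin[3] + dz
  if (!is.null(g$bbox)) g$bbox[5:6] <- g$bbox[5:6] + dz
  g
}

#' Write a grid in OpenDX scalar-field format
#'
#' Plain-text OpenDX regular scalar field (origin, deltas, counts, data with
#' the last index varying fastest).  Round-trips exactly with [read_dx()].
#'
#' @param g A [grid_potential()].
#' @param path Output file.
#' @export
write_dx <- function(g, path) {
  n <- g$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by corralsim",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.17g %.17g %.17g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.17g 0 0", g$spacing[1]),
    sprintf("delta 0 %.17g 0", g$spacing[2]),
    sprintf("delta 0 0 %.17g", g$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  v <- as.numeric(aperm(g$values, c(3, 2, 1)))  # z fastest in DX order
  nfull <- (length(v) %/% 3) * 3
  if (nfull > 0) {
    m <- matrix(v[seq_len(nfull)], nrow = 3)
    writeLines(sprintf("%.17g %.17g %.17g", m[1, ], m[2, ], m[3, ]), con)
  }
  if (nfull < length(v))
    writeLines(paste(sprintf("%.17g", v[(nfull + 1):length(v)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' @param path File written by [write_dx()] or another OpenDX writer using
#'   the regular-grid scalar layout.
#' @param clamp,bbox Passed to [grid_potential()].
#' @return A [grid_potential()].
#' @export
read_dx <- function(path, clamp = TRUE, bbox = "none") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(sub(".*counts +", "", gp), " +")[[1]])
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(sub("^origin +", "", org), " +")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  dm <- do.call(rbind, lapply(dl, function(s)
    as.numeric(strsplit(sub("^delta +", "", s), " +")[[1]])))
  spacing <- c(dm[1, 1], dm[2, 2], dm[3, 3])
  i0 <- grep("data follows", lines)[1]
  iend <- grep("^attribute|^object \"", lines)
  iend <- min(iend[iend > i0], length(lines) + 1)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(iend - 1)]),
                                     " +")))
  stopifnot(length(vals) == prod(counts))
  a <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  grid_potential(origin, spacing, a, clamp = clamp, bbox = bbox)
}
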