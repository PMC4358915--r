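#' Rod-like fence specification
#'
#' A row of spheres along the Y axis at X = 0.  Steric fences are uncharged,
#' sit on the diffusion plane, and carry a single centred gap of length
#' `opening_length`; electrostatic fences are unbroken, elevated by
#' `height` above the diffusion plane, and carry `sphere_charge` per
#' sphere.
#'
#' @param fence_length Total fence length L along Y, A.
#' @param opening_length Gap length L_open, A (0 <= L_open <= L).
#' @param sphere_charge Charge per sphere q, e.
#' @param height Height h above the diffusion plane, A.
#' @param sphere_radius Sphere radius, A (default the lipid-sphere radius).
#' @param sphere_spacing Centre-to-centre spacing, A (default contact).
#' @return An object of class `rod_fence_spec`.
#' @export
rod_fence_spec <- function(fence_length = 1000, opening_length = 0,
                           sphere_charge = 0, height = 0,
                           sphere_radius = 5.4,
                           sphere_spacing = 2 * sphere_radius) {
  stopifnot(opening_length >= 0, fence_length > 0,
            sphere_radius > 0, sphere_spacing > 0, height >= 0)
  if (opening_length > fence_length)
    stop("opening_length may not exceed fence_length")
  structure(list(fence_length = fence_length,
                 opening_length = opening_length,
                 sphere_charge = sphere_charge, height = height,
                 sphere_radius = sphere_radius,
                 sphere_spacing = sphere_spacing),
            class = "rod_fence_spec")
}

# spheres covering one blocked segment [lo, hi] along y
.segment_spheres <- function(lo, hi, spacing) {
  len <- hi - lo
  if (len <= 0) return(numeric(0))
  n <- ceiling(len / spacing)
  lo + (seq_len(n) - 0.5) * len / n
}

#' Build a steric rod fence
#'
#' Contact-spaced uncharged spheres on the diffusion plane along Y at
#' X = 0, with a single contiguous opening of length `opening_length`
#' centred at Y = 0.  `opening_length = fence_length` yields an empty fence
#' (free diffusion).
#'
#' @param spec A [rod_fence_spec()] with `sphere_charge = 0` and
#'   `height = 0`.
#' @return Data frame with columns `x`, `y`, `z`, `radius`, `charge`
#'   (simulation frame: z = 0 on the diffusion plane).
#' @export
build_steric_rod <- function(spec = rod_fence_spec()) {
  stopifnot(inherits(spec, "rod_fence_spec"))
  if (spec$sphere_charge != 0 || spec$height != 0)
    stop("steric rods are uncharged and sit on the diffusion plane")
  L <- spec$fence_length; Lo <- spec$opening_length
  y <- if (Lo == 0) .segment_spheres(-L / 2, L / 2, spec$sphere_spacing)
       else c(.segment_spheres(-L / 2, -Lo / 2, spec$sphere_spacing),
              .segment_spheres(Lo / 2, L / 2, spec$sphere_spacing))
  data.frame(x = rep(0, length(y)), y = y, z = rep(0, length(y)),
             radius = rep(spec$sphere_radius, length(y)),
             charge = rep(0, length(y)))
}

#' Build an electrostatic rod fence
#'
#' An unbroken row of charged spheres elevated `height` A above the
#' diffusion plane.  These fences act only through the electrostatic map;
#' they are raised to eliminate steric interactions and therefore
#' contribute no core-repulsion map.
#'
#' @param spec A [rod_fence_spec()] with `opening_length = 0`.
#' @return Data frame with columns `x`, `y`, `z`, `radius`, `charge`
#'   (simulation frame: z = height).
#' @export
build_electrostatic_rod <- function(spec) {
  stopifnot(inherits(spec, "rod_fence_spec"), spec$height >= 0)
  if (spec$opening_length != 0)
    stop("electrostatic rods have no opening")
  y <- .segment_spheres(-spec$fence_length / 2, spec$fence_length / 2,
                        spec$sphere_spacing)
  data.frame(x = rep(0, length(y)), y = y,
             z = rep(spec$height, length(y)),
             radius = rep(spec$sphere_radius, length(y)),
             charge = rep(spec$sphere_charge, length(y)))
}

#' Replicate a filament subunit along the fence axis
#'
#' Copy i (i = 0 .. n-1) of the subunit is rotated by `i * rotation`
#' degrees about the fence axis (a line parallel to Y through
#' `axis_point`) and translated by `i * translation` A along Y.  Each copy
#' is a rigid-body transform of the monomer.  Helical parameters used for
#' the filaments are 166.4 degrees / 27.6 A (actin-like), and pure
#' translations of 253.2 A and 338.7 A for the septin-like biological
#' units.
#'
#' @param coords Data frame with at least `x`, `y`, `z` (other columns are
#'   duplicated unchanged, plus a `subunit` index column is added).
#' @param n_subunits Number of copies.
#' @param rotation Rotation per subunit, degrees.
#' @param translation Translation per subunit along Y, A.
#' @param axis_point Length-2 (x, z) position of the helical axis.
#' @return Data frame of `n_subunits` transformed copies.
#' @export
replicate_filament <- function(coords, n_subunits, rotation = 0,
                               translation, axis_point = c(0, 0)) {
  stopifnot(nrow(coords) > 0, n_subunits >= 1)
  out <- vector("list", n_subunits)
  for (i in seq_len(n_subunits) - 1) {
    th <- i * rotation * pi / 180
    dx <- coords$x - axis_point[1]
    dz <- coords$z - axis_point[2]
    ci <- coords
    ci$x <- axis_point[1] + cos(th) * dx + sin(th) * dz
    ci$z <- axis_point[2] - sin(th) * dx + cos(th) * dz
    ci$y <- coords$y + i * translation
    ci$subunit <- i + 1L
    out[[i + 1]] <- ci
  }
  do.call(rbind, out)
}

#' Bury a filament to a target minimum height
#'
#' Translates the coordinates in Z so that the lowest atom sits at `z_min`
#' in the membrane frame (lipid phosphate plane at Z = 0; negative `z_min`
#' buries the filament into the headgroup/membrane region).  X and Y are
#' unchanged; applying twice is idempotent.
#'
#' @param coords Data frame with `x`, `y`, `z`.
#' @param z_min Target minimum Z, A.
#' @return The translated data frame.
#' @export
bury_filament <- function(coords, z_min) {
  coords$z <- coords$z + (z_min - min(coords$z))
  coords
}

#' Formal charge and radius tables for residues
#'
#' Formal charges: ASP/GLU -1, LYS/ARG +1, HIS 0, everything else 0.
#' Radii are per-residue effective bead radii (A) used for the dielectric
#' and core-repulsion construction of coarse protein models.
#'
#' @return A data frame with columns `resid`, `charge`, `radius`.
#' @export
residue_charge_table <- function() {
  data.frame(
    resid = c("ASP", "GLU", "LYS", "ARG", "HIS", "GLY", "ALA", "SER",
              "THR", "CYS", "VAL", "LEU", "ILE", "MET", "PRO", "PHE",
              "TYR", "TRP", "ASN", "GLN"),
    charge = c(-1, -1, 1, 1, 0, rep(0, 15)),
    radius = c(3.0, 3.2, 3.4, 3.6, 3.3, 2.4, 2.6, 2.7, 2.9, 2.9, 3.0,
               3.2, 3.2, 3.3, 2.9, 3.4, 3.5, 3.7, 3.0, 3.2),
    stringsAsFactors = FALSE)
}

#' Load a coordinate file for fence construction
#'
#' Reads a PDB file (via bio3d) and assigns per-residue formal charges and
#' radii from [residue_charge_table()].  The charge of each residue is
#' placed on its representative atom (CA if present, else the first atom
#' of the residue).
#'
#' @param path PDB file.
#' @param charge_table Override for [residue_charge_table()].
#' @return Data frame with columns `x`, `y`, `z`, `radius`, `charge`,
#'   `resid`, `resno`, `elety`.
#' @export
load_structure <- function(path, charge_table = residue_charge_table()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  unknown <- setdiff(unique(at$resid), charge_table$resid)
  if (length(unknown) > 0)
    stop("unknown residues (no charge/radius entry): ",
         paste(unknown, collapse = ", "))
  m <- match(at$resid, charge_table$resid)
  out <- data.frame(x = at$x, y = at$y, z = at$z,
                    radius = charge_table$radius[m],
                    charge = 0,
                    resid = at$resid, resno = at$resno, elety = at$elety,
                    stringsAsFactors = FALSE)
  for (rn in unique(at$resno)) {
    rows <- which(at$resno == rn)
    rep_at <- rows[match("CA", at$elety[rows])]
    if (is.na(rep_at)) rep_at <- rows[1]
    out$charge[rep_at] <- charge_table$charge[m[rep_at]]
  }
  out
}

#' Write fence coordinates as a PDB file
#'
#' @param coords Data frame with `x`, `y`, `z` and optionally `resid`,
#'   `resno`, `elety`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(coords, path) {
  n <- nrow(coords)
  resid <- if (is.null(coords$resid)) rep("GLY", n) else coords$resid
  resno <- if (is.null(coords$resno)) seq_len(n) else coords$resno
  elety <- if (is.null(coords$elety)) rep("CA", n) else coords$elety
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords[, c("x", "y", "z")])),
                   resid = resid, resno = resno, elety = elety)
  invisible(path)
}
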