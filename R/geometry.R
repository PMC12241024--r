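#' Two-layer annular tissue stack
#'
#' The intestinal wall pair clamped in a circular stapler is idealised as two
#' bonded annular disks: the upper layer contacts the anvil, the lower layer
#' the staple cartridge. Default radii correspond to a 34 mm-class device
#' contact annulus (configurable; not device measurements).
#'
#' @param t_upper,t_lower layer thicknesses, mm.
#' @param r_inner,r_outer annulus radii, mm.
#' @return object of class `tissue_stack`.
#' @export
tissue_stack <- function(t_upper, t_lower, r_inner = 10, r_outer = 16) {
  stopifnot(is.numeric(t_upper), is.numeric(t_lower))
  if (!(t_upper > 0 && t_lower > 0))
    stop("layer thicknesses must be positive")
  if (!(r_inner > 0 && r_outer > r_inner))
    stop("require 0 < r_inner < r_outer")
  structure(list(t_upper = t_upper, t_lower = t_lower,
                 r_inner = r_inner, r_outer = r_outer,
                 total = t_upper + t_lower),
            class = "tissue_stack")
}

#' Annular contact footprint of a platen
#'
#' The proprietary anvil/cartridge contact faces are replaced by an
#' axisymmetric surrogate: a set of non-overlapping annular bands, each with
#' an `area_fraction` in (0, 1] representing machined relief (staple holes,
#' cutting-washer clearance) inside the band.
#'
#' @param side `"anvil"` or `"cartridge"`.
#' @param bands data.frame with columns `r_in`, `r_out`, `area_fraction`.
#' @param stack optional [tissue_stack()] used to validate band radii.
#' @return object of class `contact_footprint`.
#' @export
contact_footprint <- function(side = c("anvil", "cartridge"), bands,
                              stack = NULL) {
  side <- match.arg(side)
  bands <- as.data.frame(bands)
  stopifnot(all(c("r_in", "r_out", "area_fraction") %in% names(bands)))
  if (nrow(bands)) {
    bands <- bands[order(bands$r_in), , drop = FALSE]
    if (any(bands$r_out <= bands$r_in))
      stop("each band needs r_out > r_in")
    if (any(bands$area_fraction <= 0 | bands$area_fraction > 1))
      stop("area_fraction must lie in (0, 1]")
    if (nrow(bands) > 1 &&
        any(bands$r_in[-1] < bands$r_out[-nrow(bands)] - 1e-9))
      stop("bands must not overlap")
    if (!is.null(stack)) {
      if (min(bands$r_in) < stack$r_inner - 1e-9 ||
          max(bands$r_out) > stack$r_outer + 1e-9)
        stop("footprint bands must lie within [r_inner, r_outer] of the stack")
    }
  }
  structure(list(side = side, bands = bands), class = "contact_footprint")
}

#' Effective contact area of a footprint
#'
#' \eqn{\sum_b \pi (r_{out}^2 - r_{in}^2) \cdot f_b} in mm^2.
#'
#' @param fp a [contact_footprint()].
#' @return area, mm^2 (0 for an empty band list).
#' @export
effective_area <- function(fp) {
  stopifnot(inherits(fp, "contact_footprint"))
  b <- fp$bands
  if (!nrow(b)) return(0)
  sum(pi * (b$r_out^2 - b$r_in^2) * b$area_fraction)
}

#' Default anvil and cartridge footprints
#'
#' Tunable surrogate for the unpublished contact faces. Both platens carry
#' two annular contact lands (separated by the cutting-blade clearance)
#' that stop short of the tissue edges, so compressed tissue can escape
#' inward and outward past the device - without this relief the nearly
#' incompressible wall would be hydrostatically locked and stresses would
#' not be on the physical scale. The cartridge must additionally reserve
#' space for the staple holes and the moving blade, so its lands are
#' narrower: its effective area is about 64% of the anvil's. That ordering
#' (`area(cartridge) < area(anvil)`) is what makes the cartridge-side
#' tissue the more severely stressed layer.
#'
#' Band positions scale with the annulus width; fractions encode machined
#' relief inside each land.
#'
#' @param stack a [tissue_stack()].
#' @return list with elements `anvil` and `cartridge`.
#' @export
default_footprints <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  ri <- stack$r_inner
  w <- stack$r_outer - ri
  anvil <- contact_footprint("anvil",
    data.frame(r_in  = ri + c(1, 3.5) / 6 * w,
               r_out = ri + c(3, 5) / 6 * w,
               area_fraction = 0.9), stack)
  cart <- contact_footprint("cartridge",
    data.frame(r_in  = ri + c(1.55, 3.85) / 6 * w,
               r_out = ri + c(2.65, 4.95) / 6 * w,
               area_fraction = 0.9), stack)
  list(anvil = anvil, cartridge = cart)
}

#' Structured axisymmetric mesh of a tissue stack
#'
#' Builds a structured grid of 4-node quadrilaterals in the (r, z) plane,
#' z being the compression axis (the device axis). The layer interface at
#' `z = t_lower` is node-conforming, which realises the bonded
#' tissue-tissue contact. Each element carries a reference volume
#' \eqn{2\pi \bar r A} (Pappus) and a `layer` tag.
#'
#' @param stack a [tissue_stack()].
#' @param element_size target edge length, mm; must not exceed the thinner
#'   layer. At least two element rows per layer are always generated.
#' @return object of class `axisym_mesh`: `nodes` (n x 2 matrix, columns
#'   r and z), `elems` (ne x 4 node indices, counterclockwise), `layer`
#'   (character per element), `vol_ref` (mm^3 per element), plus the grid
#'   dimensions.
#' @export
build_mesh <- function(stack, element_size) {
  stopifnot(inherits(stack, "tissue_stack"))
  if (!(element_size > 0))
    stop("element_size must be positive")
  if (element_size > min(stack$t_upper, stack$t_lower) + 1e-12)
    stop(sprintf(paste("element_size %.3g mm exceeds the thinner layer",
                       "(%.3g mm); refine the mesh"),
                 element_size, min(stack$t_upper, stack$t_lower)))
  nr <- max(2L, ceiling((stack$r_outer - stack$r_inner) / element_size))
  nz_lo <- max(2L, ceiling(stack$t_lower / element_size))
  nz_up <- max(2L, ceiling(stack$t_upper / element_size))
  r <- seq(stack$r_inner, stack$r_outer, length.out = nr + 1L)
  z <- c(seq(0, stack$t_lower, length.out = nz_lo + 1L),
         seq(stack$t_lower, stack$total, length.out = nz_up + 1L)[-1])
  nzn <- length(z)
  nodes <- cbind(r = rep(r, times = nzn), z = rep(z, each = nr + 1L))
  nid <- function(i, j) (j - 1L) * (nr + 1L) + i  # i radial, j axial index
  ne <- nr * (nzn - 1L)
  elems <- matrix(0L, ne, 4L)
  layer <- character(ne)
  k <- 0L
  for (j in seq_len(nzn - 1L)) {
    for (i in seq_len(nr)) {
      k <- k + 1L
      elems[k, ] <- c(nid(i, j), nid(i + 1L, j),
                      nid(i + 1L, j + 1L), nid(i, j + 1L))
      layer[k] <- if (j <= nz_lo) "lower" else "upper"
    }
  }
  rbar <- (nodes[elems[, 1], 1] + nodes[elems[, 2], 1]) / 2
  area <- (nodes[elems[, 2], 1] - nodes[elems[, 1], 1]) *
    (nodes[elems[, 4], 2] - nodes[elems[, 1], 2])
  vol_ref <- 2 * pi * rbar * area
  structure(list(nodes = nodes, elems = elems, layer = layer,
                 vol_ref = vol_ref, stack = stack,
                 element_size = element_size,
                 nr = nr, nz_lower = nz_lo, nz_upper = nz_up),
            class = "axisym_mesh")
}

#' Total reference volume of a mesh
#' @param mesh an [axisym_mesh][build_mesh()].
#' @return volume, mm^3.
#' @export
mesh_volume <- function(mesh) sum(mesh$vol_ref)

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric mesh: %d nodes, %d quad elements (size %.3g mm)\n",
    nrow(x$nodes), nrow(x$elems), x$element_size))
  cat(sprintf("  volume %.4g mm^3 (analytic %.4g mm^3)\n", mesh_volume(x),
              pi * (x$stack$r_outer^2 - x$stack$r_inner^2) * x$stack$total))
  invisible(x)
}
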