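#' Retinal geometry of the archer fish eye
#'
#' Container for the geometric quantities that determine how large a visual
#' target appears on the retina and how many neurons it can drive: a pinhole
#' (single-nodal-point) eye model plus photoreceptor and ganglion-cell layer
#' statistics.
#'
#' @param target_size Target diameter (mm). Default 45 mm (a 4.5 cm disc).
#' @param viewing_distance Distance from eye to target (mm). Default 300 mm.
#' @param eye_diameter Eye diameter (mm); the pinhole focal length. Default 4.
#' @param photoreceptor_diameter Photoreceptor diameter (um). Default 6.
#' @param ganglion_density Ganglion cell density (cells/mm^2). Default 4500.
#' @param rf_radius Ganglion cell receptive field radius (um). Default 100.
#'
#' @return An object of class `eye_geometry`.
#' @export
#' @examples
#' g <- eye_geometry()
#' retinal_image_size(g)
eye_geometry <- function(target_size = 45, viewing_distance = 300,
                         eye_diameter = 4, photoreceptor_diameter = 6,
                         ganglion_density = 4500, rf_radius = 100) {
  vals <- c(target_size = target_size, viewing_distance = viewing_distance,
            eye_diameter = eye_diameter,
            photoreceptor_diameter = photoreceptor_diameter,
            ganglion_density = ganglion_density, rf_radius = rf_radius)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all eye_geometry fields must be finite and strictly positive")
  structure(as.list(vals), class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat("Eye geometry (pinhole model)\n")
  cat(sprintf("  target %.3g mm at %.3g mm; eye diameter %.3g mm\n",
              x$target_size, x$viewing_distance, x$eye_diameter))
  cat(sprintf("  photoreceptor diameter %.3g um; RGC density %.3g /mm^2; RF radius %.3g um\n",
              x$photoreceptor_diameter, x$ganglion_density, x$rf_radius))
  invisible(x)
}

#' Size of the target's image on the retina
#'
#' Pinhole projection: `target_size * eye_diameter / viewing_distance`.
#' With the defaults (45 mm target, 300 mm away, 4 mm eye) the image spans
#' 0.60 mm.
#'
#' @param g An [eye_geometry()].
#' @return Image diameter on the retina (mm).
#' @export
retinal_image_size <- function(g) {
  stopifnot(inherits(g, "eye_geometry"))
  g$target_size * g$eye_diameter / g$viewing_distance
}

#' Number of photoreceptors stimulated by the target image
#'
#' Divides the image disc area by a per-receptor footprint: square packing
#' uses `d^2`, circular packing `pi * d^2 / 4`. Square packing is the default
#' because a hexagonal-to-square mosaic footprint is the standard
#' back-of-envelope convention for receptor counting.
#'
#' @param image_diameter Image diameter on the retina (mm).
#' @param rc_diameter Photoreceptor diameter (um).
#' @param packing `"square"` or `"circular"`.
#' @return Expected count of stimulated photoreceptors.
#' @export
photoreceptors_stimulated <- function(image_diameter, rc_diameter,
                                      packing = c("square", "circular")) {
  packing <- match.arg(packing)
  if (image_diameter <= 0 || rc_diameter <= 0)
    stop("sizes must be strictly positive")
  area_um2 <- pi * (image_diameter * 1000 / 2)^2
  footprint <- if (packing == "square") rc_diameter^2 else pi * rc_diameter^2 / 4
  area_um2 / footprint
}

#' Number of ganglion cells whose receptive fields see the target
#'
#' `centres_inside` counts cells whose RF centre lies inside the image disc
#' (`density * pi * r_img^2`); `partial_overlap` also counts cells whose RF
#' merely touches the disc, enlarging the radius by one RF radius
#' (`density * pi * (r_img + rf_radius)^2`).
#'
#' @param image_diameter Image diameter on the retina (mm).
#' @param density Ganglion cell density (cells/mm^2).
#' @param rf_radius Receptive field radius (um).
#' @param mode `"centres_inside"` or `"partial_overlap"`.
#' @return Expected ganglion cell count.
#' @export
ganglion_cells_covering <- function(image_diameter, density, rf_radius,
                                    mode = c("centres_inside", "partial_overlap")) {
  mode <- match.arg(mode)
  if (image_diameter <= 0 || rf_radius < 0 || density < 0)
    stop("inputs must be positive (density may be zero)")
  r_mm <- image_diameter / 2
  if (mode == "partial_overlap") r_mm <- r_mm + rf_radius / 1000
  density * pi * r_mm^2
}
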