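#' Chip geometry: perfusion channel with a recessed microwell
#'
#' Rectangular perfusion channel with a rectangular microwell recessed in
#' its floor and a circular spheroid inside the well. The channel floor is
#' at y = 0 (the well opens upward into it), the channel top at
#' y = channel_height, and the well spans negative y down to
#' -well_height. The well bottom is the acoustically actuated wall, where
#' the piezoelectric transducer sits in the physical device.
#'
#' The spheroid is placed concentric with the well by default: the device
#' layout is symmetric and nutrient flux arrives from the channel above, so
#' a centred placement reproduces the bottom-weighted necrotic core.
#'
#' All lengths are given in micrometres.
#'
#' @param channel_length,channel_height channel dimensions (um)
#' @param well_width,well_height microwell dimensions (um)
#' @param spheroid_diameter spheroid diameter (um); 0 gives a well with no
#'   spheroid hole
#' @param well_center_x axial position of the well centre (um); default
#'   channel mid-length
#' @param spheroid_center length-2 vector (x, y) in um; default the well
#'   centre
#' @param out_of_plane_depth depth used to convert volumetric flow rate to
#'   the 2D model (um); default 1000
#' @return object of class \code{chip_geometry}
#' @export
chip_geometry <- function(channel_length = 2000, channel_height = 1000,
                          well_width = 450, well_height = 380,
                          spheroid_diameter = 300,
                          well_center_x = channel_length / 2,
                          spheroid_center = c(well_center_x, -well_height / 2),
                          out_of_plane_depth = 1000) {
  dims <- c(channel_length = channel_length, channel_height = channel_height,
            well_width = well_width, well_height = well_height,
            out_of_plane_depth = out_of_plane_depth)
  for (nm in names(dims)) {
    if (!is.finite(dims[[nm]]) || dims[[nm]] <= 0) {
      stop(sprintf("invariant violated: %s must be > 0", nm))
    }
  }
  if (spheroid_diameter < 0) stop("invariant violated: spheroid_diameter must be >= 0")
  r <- spheroid_diameter / 2
  if (spheroid_diameter > 0) {
    if (spheroid_diameter >= well_width) {
      stop("invariant violated: spheroid_diameter must be < well_width")
    }
    if (spheroid_diameter >= well_height) {
      stop("invariant violated: spheroid_diameter must be < well_height")
    }
    wx0 <- well_center_x - well_width / 2
    wx1 <- well_center_x + well_width / 2
    cx <- spheroid_center[1]; cy <- spheroid_center[2]
    inside_well <- (cx - r > wx0) && (cx + r < wx1) &&
      (cy - r > -well_height) && (cy + r < 0)
    if (!inside_well) {
      stop("invariant violated: spheroid must lie strictly inside the well")
    }
  }
  out <- list(channel_length = channel_length, channel_height = channel_height,
              well_width = well_width, well_height = well_height,
              spheroid_diameter = spheroid_diameter,
              well_center_x = well_center_x,
              spheroid_center = spheroid_center,
              out_of_plane_depth = out_of_plane_depth)
  class(out) <- "chip_geometry"
  out
}

#' Build the tagged planar chip domain
#'
#' Turns a validated \code{chip_geometry} into a planar domain description
#' used by the mesh generator: channel rectangle, well rectangle recessed in
#' the channel floor, circular spheroid hole, and the boundary tag layout
#' (inlet, outlet, channel_walls, well_walls, actuated_wall at the well
#' bottom, spheroid_interface).
#'
#' @param params a \code{chip_geometry}
#' @return object of class \code{planar_domain} with kind "chip";
#'   coordinates stored in metres
#' @export
build_chip_geometry <- function(params) {
  stopifnot(inherits(params, "chip_geometry"))
  um <- 1e-6
  g <- params
  r <- g$spheroid_diameter / 2
  dom <- list(
    kind = "chip",
    L = g$channel_length * um, Hc = g$channel_height * um,
    wx0 = (g$well_center_x - g$well_width / 2) * um,
    wx1 = (g$well_center_x + g$well_width / 2) * um,
    wy0 = -g$well_height * um,
    sph_c = g$spheroid_center * um,
    sph_r = r * um,
    depth = g$out_of_plane_depth * um,
    geometry = g)
  dom$area <- dom$L * dom$Hc + (dom$wx1 - dom$wx0) * (-dom$wy0) -
    pi * dom$sph_r^2
  dom$spheroid_area <- pi * dom$sph_r^2
  dom$tags <- c("inlet", "outlet", "channel_walls", "well_walls",
                "actuated_wall", "spheroid_interface")
  class(dom) <- "planar_domain"
  dom
}

#' Build the rectangular validation-cavity domain
#'
#' W x H rectangle used by the streaming benchmark: both side walls are
#' actuated in their normal direction; top and bottom are rigid isothermal
#' walls; the cavity is closed (no inlet/outlet). Its horizontal half-wave
#' resonance sits at \eqn{c_a/(2W)}.
#'
#' @param W,H cavity width and height (um)
#' @return object of class \code{planar_domain} with kind "rect"
#' @export
build_validation_geometry <- function(W = 380, H = 160) {
  if (!(W > 0 && H > 0)) stop("W and H must be > 0")
  um <- 1e-6
  dom <- list(kind = "rect", W = W * um, H = H * um,
              area = W * H * um^2,
              side_tags = list(left = "actuated_wall", right = "actuated_wall",
                               bottom = "rigid_wall", top = "rigid_wall"))
  dom$tags <- unique(unlist(dom$side_tags))
  class(dom) <- "planar_domain"
  dom
}
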