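#' Calibrated single-channel fluorescence image
#'
#' A `channel_image` wraps one channel of a 2D fluorescence image as a numeric
#' matrix of non-negative intensities together with its physical pixel size.
#' Rows index y (top-left origin), columns index x; pixel `[i, j]` covers the
#' half-open square `[(j-1)*s, j*s) x [(i-1)*s, i*s)` micrometres, where `s`
#' is `pixel_size_um`.
#'
#' @param pixels Numeric matrix of intensities, all `>= 0`.
#' @param pixel_size_um Physical size of one pixel in micrometres (`> 0`).
#' @param channel Channel label, e.g. `"receptor"` or `"GAD65"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um = 0.1, channel = "unnamed") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("image intensities must be non-negative and non-missing", call. = FALSE)
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = as.character(channel)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s': %d x %d px, %.3g um/px, range [%.3g, %.3g]>\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

is_channel_image <- function(x) inherits(x, "channel_image")

check_same_shape <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("images must have identical dimensions", call. = FALSE)
  if (!isTRUE(all.equal(a$pixel_size_um, b$pixel_size_um)))
    stop("images must share the same pixel size", call. = FALSE)
  invisible(TRUE)
}

#' Rectangular or polygonal region of interest
#'
#' Regions of interest mirror the measurement units used in dendritic imaging:
#' whole cell, soma, or a 10-micrometre dendrite segment. The geometry is a
#' polygon in pixel coordinates (0-based, x right / y down); pixel membership
#' is decided at pixel centres.
#'
#' @param vertices Two-column matrix of polygon vertices `(x, y)` in 0-based
#'   pixel coordinates.
#' @param role One of `"whole_cell"`, `"soma"`, `"dendrite_segment"`,
#'   `"extrasynaptic_segment"`.
#' @param nominal_length_um Nominal segment length; dendrite segments default
#'   to 10 micrometres.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(vertices, role = c("dendrite_segment", "whole_cell",
                                        "soma", "extrasynaptic_segment"),
                     nominal_length_um = NULL) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("`vertices` must be a polygon with >= 3 (x, y) rows", call. = FALSE)
  if (is.null(nominal_length_um))
    nominal_length_um <- if (role %in% c("dendrite_segment",
                                         "extrasynaptic_segment")) 10 else NA_real_
  structure(list(vertices = vertices, role = role,
                 nominal_length_um = nominal_length_um),
            class = "roi_spec")
}

#' Axis-aligned rectangular ROI helper
#'
#' @param x0,y0,x1,y1 Corner coordinates in 0-based pixel units.
#' @inheritParams roi_spec
#' @return An `roi_spec` polygon covering the rectangle.
#' @export
roi_rect <- function(x0, y0, x1, y1, role = "dendrite_segment",
                     nominal_length_um = NULL) {
  roi_spec(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
           role = role, nominal_length_um = nominal_length_um)
}

# Linear indices of pixels whose centres fall inside the ROI polygon.
roi_pixel_index <- function(roi, dim_px) {
  stopifnot(inherits(roi, "roi_spec"))
  nr <- dim_px[1]; nc <- dim_px[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)   # x centre, 0-based units
  cy <- rep(seq_len(nr) - 0.5, times = nc)  # y centre
  bnd <- rbind(roi$vertices, roi$vertices[1, ])  # closed loop
  inside <- mgcv::in.out(bnd, cbind(cx, cy))
  which(inside)
}
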