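# Region vocabulary: the four extended ETDRS quadrants, the 1500 um central
# ring (reported separately, never merged into a quadrant), and everything
# beyond the 45-degree field circle.
.REGIONS <- c("superior", "temporal", "nasal", "inferior",
              "central_ring", "outside_field")
.QUADRANTS <- .REGIONS[1:4]
.LESION_TYPES <- c("MA", "HEM")

#' Region labels used by the modified ETDRS grid
#'
#' @param quadrants_only if `TRUE`, return only the four quadrant labels.
#' @return character vector of region labels, in canonical order.
#' @export
#' @examples
#' region_labels()
#' region_labels(quadrants_only = TRUE)
region_labels <- function(quadrants_only = FALSE) {
  if (quadrants_only) .QUADRANTS else .REGIONS
}

#' Fundus frame: image geometry and retinal landmarks
#'
#' Describes one macula-centered fundus photograph: pixel dimensions, fovea
#' and optic-disc centers, field of view, micrometre-per-pixel scale and eye
#' laterality. Coordinates are 0-based, x rightward, y downward (image
#' convention); "superior" on the retina is therefore smaller y. The
#' convention throughout is a non-mirrored macula-centered photograph, in
#' which the optic disc lies on the nasal side of the fovea: a disc on the
#' image-right of the fovea means a right eye.
#'
#' @param width_px,height_px image dimensions in pixels (positive integers).
#' @param fovea_x,fovea_y fovea center, pixels, inside the image.
#' @param disc_x,disc_y optic-disc center, pixels, inside the image.
#' @param fov_deg field of view in degrees (default 45).
#' @param um_per_px micrometres of retina per pixel; derived from
#'   `fov_deg`, `width_px` and `retina_um_per_deg` when `NULL`.
#' @param retina_um_per_deg retinal scale used for the derived conversion,
#'   default 288 um per degree of visual angle.
#' @param laterality `"left"`, `"right"`, or `NULL` to infer from the disc
#'   position via [infer_laterality()].
#' @param image_id optional identifier carried through tables.
#' @return an object of class `fundus_frame`.
#' @seealso [etdrs_grid()], [assign_region()]
#' @export
#' @examples
#' fr <- fundus_frame(1440, 960, fovea_x = 720, fovea_y = 480,
#'                    disc_x = 1220, disc_y = 480)
#' fr$laterality
#' fr$um_per_px
fundus_frame <- function(width_px, height_px, fovea_x, fovea_y,
                         disc_x, disc_y, fov_deg = 45, um_per_px = NULL,
                         retina_um_per_deg = 288, laterality = NULL,
                         image_id = NA_character_) {
  stopifnot(length(width_px) == 1, length(height_px) == 1)
  if (width_px <= 0 || height_px <= 0)
    stop("image dimensions must be positive")
  if (fov_deg <= 0) stop("fov_deg must be positive")
  inside <- function(x, y) x >= 0 && x <= width_px - 1 && y >= 0 && y <= height_px - 1
  if (!inside(fovea_x, fovea_y)) stop("fovea must lie inside the image")
  if (!inside(disc_x, disc_y)) stop("optic disc must lie inside the image")
  if (is.null(um_per_px))
    um_per_px <- um_per_px(width_px, fov_deg = fov_deg,
                           retina_um_per_deg = retina_um_per_deg)
  if (um_per_px <= 0) stop("um_per_px must be positive")
  fr <- structure(list(
    image_id = image_id,
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    fovea_x = fovea_x, fovea_y = fovea_y,
    disc_x = disc_x, disc_y = disc_y,
    fov_deg = fov_deg, um_per_px = um_per_px
  ), class = "fundus_frame")
  fr$laterality <- if (is.null(laterality)) infer_laterality(fr) else
    match.arg(laterality, c("left", "right"))
  fr
}

#' @export
print.fundus_frame <- function(x, ...) {
  cat(sprintf("<fundus_frame %s> %dx%d px, %s eye, fovea (%.1f, %.1f), disc (%.1f, %.1f), %.2f um/px\n",
              x$image_id, x$width_px, x$height_px, x$laterality,
              x$fovea_x, x$fovea_y, x$disc_x, x$disc_y, x$um_per_px))
  invisible(x)
}

#' Micrometres of retina per pixel
#'
#' Converts the field of view of a fundus photograph into a linear retinal
#' scale, assuming a fixed number of micrometres of retina per degree of
#' visual angle (288 um/deg for an emmetropic adult eye): the scale is
#' `fov_deg * retina_um_per_deg / width_px`.
#'
#' @param frame a [fundus_frame()], or the image width in pixels.
#' @param fov_deg field of view in degrees; ignored when `frame` is a
#'   `fundus_frame` (its own value is used).
#' @param retina_um_per_deg micrometres of retina per degree, default 288.
#' @return scale in micrometres per pixel.
#' @export
#' @examples
#' um_per_px(1440)        # 45 deg * 288 um/deg / 1440 px = 9 um/px
#' um_per_px(2880)        # 4.5
um_per_px <- function(frame, fov_deg = 45, retina_um_per_deg = 288) {
  if (inherits(frame, "fundus_frame")) {
    width_px <- frame$width_px
    fov_deg <- frame$fov_deg
  } else {
    width_px <- frame
  }
  if (width_px <= 0 || fov_deg <= 0 || retina_um_per_deg <= 0)
    stop("width, field of view and retinal scale must all be positive")
  fov_deg * retina_um_per_deg / width_px
}

#' Infer eye laterality from the optic-disc position
#'
#' In a non-mirrored macula-centered photograph the optic disc is nasal to
#' the fovea, so a disc on the image-right of the fovea implies a right eye
#' and a disc on the image-left a left eye.
#'
#' @param frame a [fundus_frame()].
#' @return `"left"` or `"right"`.
#' @export
#' @examples
#' fr <- fundus_frame(1440, 960, 720, 480, 1050, 470)
#' infer_laterality(fr)   # "right"
infer_laterality <- function(frame) {
  if (frame$disc_x == frame$fovea_x)
    stop("degenerate landmarks: disc and fovea share the same x coordinate, laterality undecidable")
  if (frame$disc_x > frame$fovea_x) "right" else "left"
}

#' Modified ETDRS grid
#'
#' Builds the lesion-counting grid: centered on the fovea, a central ring of
#' 1500 um diameter (radius 750 um) reported on its own, and four quadrants
#' produced by the standard ETDRS diagonal division (boundary rays at 45,
#' 135, 225 and 315 degrees from the horizontal through the fovea), extended
#' to the periphery of the 45-degree field. The field is modelled as the
#' inscribed circle of the image: radius `min(width, height) / 2` pixels
#' around the image center; points beyond it are `outside_field`.
#'
#' @param frame a [fundus_frame()]; the grid is centered on its fovea.
#' @param central_ring_radius_um radius of the central ring in micrometres
#'   (default 750, i.e. the 1500 um diameter foveal ring).
#' @return an object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(frame, central_ring_radius_um = 750) {
  if (central_ring_radius_um <= 0)
    stop("central_ring_radius_um must be positive")
  structure(list(
    center_x = frame$fovea_x, center_y = frame$fovea_y,
    central_ring_radius_um = central_ring_radius_um,
    field_center_x = (frame$width_px - 1) / 2,
    field_center_y = (frame$height_px - 1) / 2,
    field_radius_px = min(frame$width_px, frame$height_px) / 2
  ), class = "etdrs_grid")
}

#' Assign retinal points to grid regions
#'
#' Labels each point with exactly one region of the modified ETDRS grid.
#' Points closer than the central-ring radius to the fovea are
#' `central_ring`; points beyond the field circle are `outside_field`; all
#' others fall in the wedge containing their angle from the fovea. With
#' theta the counter-clockwise angle from the rightward horizontal
#' (retinal convention, superior up), the superior wedge spans
#' (45, 135] degrees and the inferior wedge (225, 315]; the two horizontal
#' wedges are labelled temporal and nasal by laterality (temporal is the
#' side opposite the optic disc). A point exactly on a 45-degree boundary
#' ray therefore belongs to the wedge clockwise of the ray — the intervals
#' are half-open (a, b] — which makes the assignment total and
#' deterministic.
#'
#' @param x_px,y_px point coordinates (pixels, image convention); vectors
#'   of equal length are accepted.
#' @param frame a [fundus_frame()] (supplies scale and laterality).
#' @param grid an [etdrs_grid()]; defaults to the grid of `frame`.
#' @return factor with levels `region_labels()`, one label per point.
#' @export
#' @examples
#' fr <- fundus_frame(1440, 960, 720, 480, 1220, 480)  # right eye, 9 um/px
#' assign_region(720, 480 - 222, fr)   # 2000 um above fovea -> superior
#' assign_region(720, 480, fr)         # fovea itself -> central_ring
#' assign_region(720 - 222, 480, fr)   # 2000 um to image-left -> temporal
assign_region <- function(x_px, y_px, frame, grid = etdrs_grid(frame)) {
  stopifnot(length(x_px) == length(y_px))
  dx <- x_px - grid$center_x
  dy <- y_px - grid$center_y
  r_um <- sqrt(dx^2 + dy^2) * frame$um_per_px
  fx <- x_px - grid$field_center_x
  fy <- y_px - grid$field_center_y
  outside <- sqrt(fx^2 + fy^2) > grid$field_radius_px

  # y grows downward on the image, so flip its sign to get the retinal
  # (superior-up) angle; theta in [0, 360).
  theta <- (atan2(-dy, dx) * 180 / pi) %% 360
  # wedge index over half-open intervals (a, b]: 0 = right horizontal,
  # 1 = superior, 2 = left horizontal, 3 = inferior.
  wedge <- findInterval(theta, c(45, 135, 225, 315), left.open = TRUE) %% 4

  right_eye <- frame$laterality == "right"
  # disc side is nasal: right eye -> right wedge nasal, left wedge temporal.
  horiz_right <- if (right_eye) "nasal" else "temporal"
  horiz_left <- if (right_eye) "temporal" else "nasal"

  out <- character(length(x_px))
  out[wedge == 0] <- horiz_right
  out[wedge == 1] <- "superior"
  out[wedge == 2] <- horiz_left
  out[wedge == 3] <- "inferior"
  out[outside] <- "outside_field"
  out[r_um < grid$central_ring_radius_um] <- "central_ring"
  factor(out, levels = .REGIONS)
}

#' Count lesions per grid region
#'
#' Tallies microaneurysms and hemorrhages in each region of the modified
#' ETDRS grid for one image. Every mark receives exactly one region, so the
#' column sums over all six regions equal the number of input marks of each
#' type.
#'
#' @param marks data frame of lesion marks with columns `lesion_type`
#'   (`"MA"` or `"HEM"`), `x_px`, `y_px`.
#' @param frame a [fundus_frame()].
#' @param grid an [etdrs_grid()]; defaults to the grid of `frame`.
#' @return data frame of class `quadrant_counts` with columns `image_id`,
#'   `region`, `n_MA`, `n_HEM`, one row per region in canonical order.
#' @export
#' @examples
#' fr <- fundus_frame(1440, 960, 720, 480, 1220, 480)
#' marks <- data.frame(lesion_type = c("MA", "MA", "HEM"),
#'                     x_px = c(720, 730, 720), y_px = c(200, 210, 700))
#' count_by_region(marks, fr)
count_by_region <- function(marks, frame, grid = etdrs_grid(frame)) {
  validate_marks(marks, require_diameter = FALSE)
  if (nrow(marks) == 0) {
    region <- factor(.REGIONS, levels = .REGIONS)
    tab <- matrix(0L, nrow = length(.REGIONS), ncol = 2,
                  dimnames = list(.REGIONS, .LESION_TYPES))
  } else {
    region <- assign_region(marks$x_px, marks$y_px, frame, grid)
    tab <- table(region, factor(marks$lesion_type, levels = .LESION_TYPES))
  }
  out <- data.frame(
    image_id = frame$image_id,
    region = factor(.REGIONS, levels = .REGIONS),
    n_MA = as.integer(tab[.REGIONS, "MA"]),
    n_HEM = as.integer(tab[.REGIONS, "HEM"]),
    row.names = NULL
  )
  class(out) <- c("quadrant_counts", class(out))
  out
}

# shared validation for mark tables
validate_marks <- function(marks, require_diameter = TRUE) {
  if (!is.data.frame(marks)) stop("marks must be a data frame")
  needed <- c("lesion_type", "x_px", "y_px")
  if (require_diameter) needed <- c(needed, "diameter_um")
  missing_cols <- setdiff(needed, names(marks))
  if (length(missing_cols))
    stop("marks table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(marks)) {
    bad <- !(marks$lesion_type %in% .LESION_TYPES)
    if (any(bad))
      stop("unknown lesion type(s) at row(s) ",
           paste(which(bad), collapse = ", "),
           ": ", paste(unique(marks$lesion_type[bad]), collapse = ", "))
    if (!is.numeric(marks$x_px) || !is.numeric(marks$y_px))
      stop("mark coordinates must be numeric")
  }
  invisible(marks)
}
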