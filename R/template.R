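#' Region vocabulary of the arm template, distal first
#'
#' Fixed order used for deterministic tie-breaking in region assignment.
#' @export
arm_regions <- c("thumb", "d2_d3", "d4_d5", "palm", "wrist",
                 "forearm", "elbow", "upper_arm")

# Fill an axis-aligned ellipse into an integer label matrix. cx/cy in pixel
# units (x = column, y = row, row 1 at the top).
fill_ellipse <- function(labels, cx, cy, rx, ry, value, only_empty = TRUE) {
  nr <- nrow(labels); nc <- ncol(labels)
  cols <- max(1L, floor(cx - rx)):min(nc, ceiling(cx + rx))
  rows <- max(1L, floor(cy - ry)):min(nr, ceiling(cy + ry))
  if (!length(cols) || !length(rows)) return(labels)
  xg <- (matrix(cols, nrow = length(rows), ncol = length(cols), byrow = TRUE) - 0.5 - cx) / rx
  yg <- (matrix(rows, nrow = length(rows), ncol = length(cols)) - 0.5 - cy) / ry
  inside <- xg^2 + yg^2 <= 1
  block <- labels[rows, cols, drop = FALSE]
  sel <- inside & (!only_empty | block == 0L)
  block[sel] <- value
  labels[rows, cols] <- block
  labels
}

fill_rect <- function(labels, x0, x1, y0, y1, value, only_empty = TRUE) {
  cols <- max(1L, x0):min(ncol(labels), x1)
  rows <- max(1L, y0):min(nrow(labels), y1)
  block <- labels[rows, cols, drop = FALSE]
  sel <- if (only_empty) block == 0L else block == block
  block[sel] <- value
  labels[rows, cols] <- block
  labels
}

#' Build the calibrated arm template
#'
#' A schematic raster of the (right) arm segmented into eight labeled regions
#' (thumb, digits 2–3, digits 4–5, palm, wrist, forearm, elbow, upper arm) on
#' which percept drawings are analyzed. Two calibration constants anchor the
#' raster to physical units, each applied to its own quantity:
#' * distances use the average hand length of 189 mm, measured between the
#'   middle-fingertip and wrist-center landmarks, giving `mm_per_px`;
#' * areas use the average palmar area of 75 cm2, giving `cm2_per_px` from the
#'   palm region's pixel count.
#'
#' @param mm_per_px Nominal raster resolution (default 0.5 mm per pixel); the
#'   template geometry is generated at this scale and the landmark-derived
#'   calibration reproduces it exactly.
#' @return A `percept_template`: `labels` (integer matrix, 0 = background,
#'   `i` = `arm_regions[i]`), `regions`, `mm_per_px`, `cm2_per_px`,
#'   `hand_length_mm`, `palm_area_cm2`, `landmarks` (fingertip and wrist, px),
#'   `template_id`.
#' @export
arm_template <- function(mm_per_px = 0.5) {
  px <- function(mm) round(mm / mm_per_px)
  width <- px(120); height <- px(540)
  labels <- matrix(0L, nrow = height, ncol = width)
  # landmark geometry: middle fingertip at y = 5 mm, wrist line 189 mm below
  tip <- c(x = px(55), y = px(5))
  wrist_y <- unname(tip["y"]) + px(189)
  # fingers: D2-D3 (index+middle), D4-D5 (ring+little), thumb at the side
  labels <- fill_rect(labels, px(38), px(70), px(5), px(78), 2L)   # d2_d3
  labels <- fill_rect(labels, px(72), px(100), px(15), px(78), 3L) # d4_d5
  labels <- fill_ellipse(labels, px(18), px(98), px(14), px(30), 1L) # thumb
  # palm: ellipse sized near 75 cm2 (exact area comes from calibration)
  labels <- fill_ellipse(labels, px(62), px(135), px(43), px(56), 4L)
  labels <- fill_rect(labels, px(35), px(92), px(192), px(212), 5L)  # wrist
  labels <- fill_rect(labels, px(38), px(88), px(213), px(330), 6L)  # forearm
  labels <- fill_ellipse(labels, px(62), px(352), px(26), px(24), 7L) # elbow
  labels <- fill_rect(labels, px(40), px(86), px(377), px(530), 8L)  # upper arm
  wrist <- c(x = px(62), y = wrist_y)
  hand_len_px <- sqrt(sum((tip - c(wrist["x"], wrist["y"]))^2))
  palm_px <- sum(labels == 4L)
  structure(list(
    labels = labels, regions = arm_regions,
    mm_per_px = 189 / hand_len_px,
    cm2_per_px = 75 / palm_px,
    hand_length_mm = 189, palm_area_cm2 = 75,
    landmarks = list(fingertip_px = unname(tip), wrist_px = unname(wrist)),
    template_id = sprintf("arm-%gmm", mm_per_px)),
    class = "percept_template")
}

#' @export
print.percept_template <- function(x, ...) {
  cat(sprintf("<percept_template> %s: %d x %d px, %.3g mm/px, %.3g cm2/px\n",
              x$template_id, nrow(x$labels), ncol(x$labels),
              x$mm_per_px, x$cm2_per_px))
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a percept mask on a template
#'
#' @param template A [arm_template()] (or compatible) `percept_template`.
#' @param pixels Logical matrix with the template's dimensions; `TRUE` inside
#'   the drawn percept.
#' @param subject,electrode,amplitude_mA,week,repetition,laterality Metadata
#'   carried with the mask.
#' @return A `percept_mask`.
#' @export
percept_mask <- function(template, pixels, subject = NA, electrode = NA,
                         amplitude_mA = NA_real_, week = NA_integer_,
                         repetition = NA_integer_,
                         laterality = "ipsilateral") {
  stopifnot(inherits(template, "percept_template"), is.logical(pixels))
  if (!identical(dim(pixels), dim(template$labels)))
    abort("mask grid does not match its template.")
  if (!any(pixels)) abort("percept mask is empty.")
  structure(list(pixels = pixels, template = template,
                 meta = list(subject = subject, electrode = electrode,
                             amplitude_mA = amplitude_mA, week = week,
                             repetition = repetition,
                             laterality = laterality)),
            class = "percept_mask")
}

#' Elliptical percept mask helper
#'
#' Rasterizes a filled ellipse given in physical coordinates (mm from the
#' template's top-left corner) — the generator's primitive for synthetic
#' drawings.
#'
#' @inheritParams percept_mask
#' @param center_mm Numeric length-2, ellipse center `(x, y)` in mm.
#' @param radii_mm Numeric length-2, semi-axes in mm.
#' @param clip_to_labels Keep only pixels inside labeled regions; if the
#'   ellipse is partly outside, the mask is clipped and flagged via attribute
#'   `clipped`.
#' @return A `percept_mask`.
#' @export
ellipse_mask <- function(template, center_mm, radii_mm, clip_to_labels = TRUE,
                         ...) {
  s <- template$mm_per_px
  m <- matrix(FALSE, nrow = nrow(template$labels), ncol = ncol(template$labels))
  m <- fill_ellipse(matrix(0L, nrow(m), ncol(m)),
                    center_mm[1] / s, center_mm[2] / s,
                    max(radii_mm[1] / s, 0.5), max(radii_mm[2] / s, 0.5),
                    1L, only_empty = FALSE) == 1L
  n_raw <- sum(m)
  if (clip_to_labels) m <- m & (template$labels > 0L)
  if (!any(m))
    abort("ellipse mask lies entirely outside the labeled template.")
  msk <- percept_mask(template, m, ...)
  attr(msk, "clipped") <- sum(msk$pixels) < n_raw
  msk
}

#' @export
print.percept_mask <- function(x, ...) {
  cat(sprintf("<percept_mask> %d px (%.2f cm2), electrode %s, week %s\n",
              sum(x$pixels), mask_area_cm2(x),
              as.character(x$meta$electrode), as.character(x$meta$week)))
  invisible(x)
}

#' Write / read a percept mask as PNG with JSON sidecar
#'
#' The mask is stored as an 8-bit grayscale PNG (nonzero = inside the percept)
#' next to a JSON sidecar holding subject, electrode, week, repetition,
#' template id and the mm-per-pixel scale.
#'
#' @param mask A `percept_mask`.
#' @param path PNG file path (the sidecar gets extension `.json`).
#' @return `write_mask_png`: the path, invisibly. `read_mask_png`: a
#'   `percept_mask` (the template must be supplied; its id is checked against
#'   the sidecar).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask$pixels, 1, 0), target = path)
  sidecar <- c(mask$meta, list(template_id = mask$template$template_id,
                               mm_per_px = mask$template$mm_per_px))
  jsonlite::write_json(sidecar, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_mask_png
#' @param template Template to attach on read.
#' @export
read_mask_png <- function(path, template) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- jsonlite::read_json(sub("\\.png$", ".json", path),
                              simplifyVector = TRUE)
  if (!is.null(side$template_id) &&
      !identical(side$template_id, template$template_id))
    abort("sidecar template_id does not match the supplied template.")
  percept_mask(template, img > 0.5,
               subject = side$subject %||% NA,
               electrode = side$electrode %||% NA,
               amplitude_mA = side$amplitude_mA %||% NA_real_,
               week = side$week %||% NA_integer_,
               repetition = side$repetition %||% NA_integer_,
               laterality = side$laterality %||% "ipsilateral")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
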