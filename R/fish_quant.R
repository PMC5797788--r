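#' Maximum-intensity projection of a z-stack
#'
#' @param stack `[y, x, z]` numeric array (or a `tg_fish_stack`).
#' @return 2-D matrix of per-pixel maxima across z; pixel-size attributes
#'   are carried over.
#' @export
max_project <- function(stack) {
  if (inherits(stack, "tg_fish_stack")) stack <- stack$stack
  d <- dim(stack)
  if (is.null(d) || length(d) == 2) return(stack)
  if (d[3] < 1) stop("empty stack")
  img <- stack[, , 1]
  for (s in seq_len(d[3])[-1]) img <- pmax(img, stack[, , s])
  attr(img, "um_per_px") <- attr(stack, "um_per_px")
  img
}

#' Puncta-counting parameters
#'
#' @param threshold binarization threshold on the 8-bit scale, or `NULL`
#'   for the automatic choice: robust background (median) plus 4 robust
#'   standard deviations (MAD-based) of the rescaled image.
#' @param min_area minimum connected-component area (pixels).
#' @return object of class `tg_puncta_params`.
#' @export
puncta_params <- function(threshold = NULL, min_area = 4L) {
  if (!is.null(threshold) && (threshold < 0 || threshold > 255))
    stop("threshold must be in [0, 255]")
  structure(list(threshold = threshold, min_area = as.integer(min_area)),
            class = "tg_puncta_params")
}

#' Count mRNA puncta in a projected image
#'
#' Mirrors the particle-analysis recipe: linear min-max rescale to 8 bits,
#' inversion, a fixed threshold highlighting individual puncta, 8-connected
#' component labelling, and a minimum-area filter. Two puncta closer than
#' about twice the PSF sigma merge into one component and are counted once.
#'
#' @param image 2-D numeric matrix.
#' @param params a [puncta_params()].
#' @return list with `count`, a `centroids` data.frame (x, y in pixels,
#'   `area`), and the `threshold` used (reported because the original
#'   procedure adjusted it manually per image).
#' @export
count_puncta <- function(image, params = puncta_params()) {
  rng <- range(image)
  if (diff(rng) <= 0) {
    warning("constant image; no puncta")
    return(list(count = 0L,
                centroids = data.frame(x = numeric(0), y = numeric(0),
                                       area = integer(0)),
                threshold = NA_real_, params = params))
  }
  img8 <- (image - rng[1]) / diff(rng) * 255
  inv <- 255 - img8  # fidelity to the described recipe; counting is on the
                     # bright-punctum side of the same threshold
  thr <- params$threshold
  if (is.null(thr))  # robust background + 4 sd, floored at one gray level
    thr <- median(img8) + 4 * max(mad(img8), 1)
  fg <- img8 >= thr  # equivalently inv <= 255 - thr
  lab <- .cpp_label8(fg)
  if (max(lab) == 0L)
    return(list(count = 0L,
                centroids = data.frame(x = numeric(0), y = numeric(0),
                                       area = integer(0)),
                threshold = thr, params = params))
  area <- tabulate(lab)
  keep <- which(area >= params$min_area)
  idx <- which(lab > 0L, arr.ind = TRUE)
  v <- lab[lab > 0L]
  cx <- tapply(idx[, 2], v, mean)[as.character(keep)]
  cy <- tapply(idx[, 1], v, mean)[as.character(keep)]
  list(count = length(keep),
       centroids = data.frame(x = as.numeric(cx), y = as.numeric(cy),
                              area = area[keep]),
       threshold = thr, params = params)
}

#' Line-ROI specification for laminar profiles
#'
#' A line of `length_um` sampled every `step_um`, with `n_lines` parallel
#' placements spaced `spacing_um` apart (perpendicular to the line) whose
#' intensities are averaged. Reported positions can be anchored so that a
#' landmark (the middle molecular layer) sits at a fixed position —
#' 150 um on 300-um lines, 125 um on 250-um lines — aligning cases with
#' different cell-layer widths.
#'
#' @param origin_px c(x, y) pixel coordinates of the line start (position
#'   0 um) of the central placement.
#' @param angle_deg line direction in degrees (0 = +x).
#' @param length_um,step_um line length and sampling step (um).
#' @param n_lines,spacing_um parallel placements and their spacing (um).
#' @param anchor_um position (um along the line) to report the landmark at,
#'   or `NULL` to report raw distances from the origin.
#' @param landmark_um raw position of the landmark along the line (um),
#'   used with `anchor_um`.
#' @return object of class `tg_line_roi`.
#' @export
line_roi_spec <- function(origin_px, angle_deg = 0, length_um = 300,
                          step_um = 10, n_lines = 10L, spacing_um = 10,
                          anchor_um = NULL, landmark_um = NULL) {
  if (length_um %% step_um != 0) stop("length_um must be a multiple of step_um")
  if (n_lines < 1L) stop("need at least one placement")
  structure(list(origin_px = origin_px, angle_deg = angle_deg,
                 length_um = length_um, step_um = step_um,
                 n_lines = as.integer(n_lines), spacing_um = spacing_um,
                 anchor_um = anchor_um, landmark_um = landmark_um),
            class = "tg_line_roi")
}

# bilinear interpolation at continuous pixel coordinates (x, y)
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 1 | x > nc | y < 1 | y > nr)) stop("ROI exits the image")
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

#' Laminar line profile
#'
#' Samples intensity (bilinear interpolation) every `step_um` along each
#' parallel line placement and averages placements at each position.
#'
#' @param image 2-D matrix.
#' @param roi a [line_roi_spec()].
#' @param um_per_px pixel size; defaults to the image attribute.
#' @return data.frame(`position_um`, `intensity`); positions are shifted so
#'   the landmark sits at `anchor_um` when both are given.
#' @export
lamina_profile <- function(image, roi, um_per_px = attr(image, "um_per_px")) {
  if (is.null(um_per_px)) stop("um_per_px is required")
  th <- roi$angle_deg * pi / 180
  d <- c(cos(th), sin(th))          # along-line unit vector
  p <- c(-sin(th), cos(th))         # perpendicular unit vector
  s_um <- seq(0, roi$length_um, by = roi$step_um)
  offs <- (seq_len(roi$n_lines) - (roi$n_lines + 1) / 2) * roi$spacing_um
  prof <- matrix(0, nrow = length(s_um), ncol = roi$n_lines)
  for (j in seq_len(roi$n_lines)) {
    x <- roi$origin_px[1] + (s_um * d[1] + offs[j] * p[1]) / um_per_px
    y <- roi$origin_px[2] + (s_um * d[2] + offs[j] * p[2]) / um_per_px
    prof[, j] <- bilinear(image, x, y)
  }
  pos <- s_um
  if (!is.null(roi$anchor_um) && !is.null(roi$landmark_um))
    pos <- s_um - roi$landmark_um + roi$anchor_um
  data.frame(position_um = pos, intensity = rowMeans(prof))
}

#' Region specification for decay-ratio measurement
#'
#' @param center_px c(x, y) region center in pixels, or `NULL` for the
#'   image center.
#' @param region_diam_um blockade-region diameter (um).
#' @param core_diam_um excluded damaged-core diameter (um).
#' @return object of class `tg_region_spec`.
#' @export
region_spec <- function(center_px = NULL, region_diam_um = 400,
                        core_diam_um = 150) {
  if (core_diam_um >= region_diam_um)
    stop("excluded core must be smaller than the region")
  structure(list(center_px = center_px, region_diam_um = region_diam_um,
                 core_diam_um = core_diam_um), class = "tg_region_spec")
}

#' Remaining-signal percentage inside the blockade region
#'
#' `100 * mean(region excluding core) / mean(outside region)`: the average
#' fluorescence in the transcription-block area, excluding the damaged
#' pipette-track core, as a percent of the surrounding field.
#'
#' @param image 2-D matrix.
#' @param region a [region_spec()].
#' @param um_per_px pixel size; defaults to the image attribute.
#' @return percentage (numeric scalar).
#' @export
region_remaining_fraction <- function(image, region = region_spec(),
                                      um_per_px = attr(image, "um_per_px")) {
  if (is.null(um_per_px)) stop("um_per_px is required")
  nr <- nrow(image); nc <- ncol(image)
  ctr <- if (is.null(region$center_px)) c((nc + 1) / 2, (nr + 1) / 2)
         else region$center_px
  d2 <- outer((seq_len(nr) - ctr[2])^2, (seq_len(nc) - ctr[1])^2, "+")
  r_reg <- (region$region_diam_um / 2 / um_per_px)^2
  r_core <- (region$core_diam_um / 2 / um_per_px)^2
  ring <- d2 <= r_reg & d2 > r_core
  outside <- d2 > r_reg
  if (!any(outside)) stop("region covers the entire field")
  if (!any(ring)) stop("empty measurement ring")
  100 * mean(image[ring]) / mean(image[outside])
}

#' Mean intensity over a rectangular ROI
#'
#' @param image 2-D matrix.
#' @param rect c(x0, y0, x1, y1) pixel bounds, inclusive.
#' @return arithmetic mean of the enclosed pixels.
#' @export
roi_mean_intensity <- function(image, rect) {
  rect <- as.integer(round(rect))
  if (rect[3] < rect[1] || rect[4] < rect[2]) stop("empty rectangle")
  if (rect[1] < 1 || rect[2] < 1 || rect[3] > ncol(image) ||
      rect[4] > nrow(image))
    stop("rectangle exceeds the image")
  mean(image[rect[2]:rect[4], rect[1]:rect[3]])
}
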