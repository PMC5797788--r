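#' Render a synthetic FISH z-stack
#'
#' Builds the per-slice noise-free signal (band backgrounds plus Gaussian
#' puncta distributed across z), scales the transcription-block region by
#' its remaining fraction, then applies Poisson shot noise and Gaussian read
#' noise. Ground truth (planted puncta per band, region fraction) is
#' returned alongside the stack.
#'
#' @param spec a [fish_image_spec()] or [fish_actd_spec()].
#' @param seed integer seed.
#' @return object of class `tg_fish_stack`: `stack` is a `[y, x, z]` array
#'   with `um_per_px` and `z_step_um` attributes, `truth` holds the planted
#'   puncta table and region fraction.
#' @export
render_fish_stack <- function(spec = fish_image_spec(), seed = 1L) {
  with_seed(seed, {
    n <- spec$npx
    nz <- spec$n_slices
    if (nz < 1L) stop("need at least one z slice")
    upp <- spec$um_per_px

    # background level along x, and band pixel extents
    lev_x <- rep(spec$base_level, n)
    band_px <- NULL
    if (!is.null(spec$bands)) {
      edges <- c(0, cumsum(spec$bands$width_um)) / upp
      band_px <- data.frame(name = spec$bands$name,
                            x0 = floor(edges[-length(edges)]) + 1,
                            x1 = pmin(n, floor(edges[-1])))
      for (i in seq_len(nrow(band_px)))
        lev_x[band_px$x0[i]:band_px$x1[i]] <-
          spec$base_level + spec$bands$level[i]
    } else {
      lev_x <- lev_x + spec$uniform_level
    }
    base2d <- matrix(rep(lev_x, each = n), nrow = n)  # [y, x]

    # plant puncta
    puncta <- data.frame(band = character(0), x = numeric(0), y = numeric(0),
                         z_um = numeric(0), amp = numeric(0))
    add_puncta <- function(band, x0_um, x1_um, density) {
      area <- (x1_um - x0_um) * spec$field_um
      np <- rpois(1, density * area)
      if (np == 0) return(NULL)
      data.frame(band = band,
                 x = runif(np, x0_um / upp, x1_um / upp),
                 y = runif(np, 0, n),
                 z_um = runif(np, 0, (nz - 1) * spec$z_step_um),
                 amp = spec$punct_amp * exp(rnorm(np, 0, spec$punct_amp_cv)))
    }
    if (!is.null(spec$bands)) {
      e <- c(0, cumsum(spec$bands$width_um))
      for (i in seq_len(nrow(spec$bands))) {
        p <- add_puncta(spec$bands$name[i], e[i], e[i + 1],
                        spec$bands$density_per_um2[i])
        if (!is.null(p)) puncta <- rbind(puncta, p)
      }
    } else if (spec$uniform_density > 0) {
      p <- add_puncta("field", 0, spec$field_um, spec$uniform_density)
      if (!is.null(p)) puncta <- rbind(puncta, p)
    }

    sig_px <- spec$psf_sigma_um / upp
    w <- ceiling(4 * sig_px)
    z_of <- (seq_len(nz) - 1) * spec$z_step_um
    stack <- array(rep(base2d, nz), dim = c(n, n, nz))
    if (nrow(puncta)) {
      for (i in seq_len(nrow(puncta))) {
        xc <- puncta$x[i]; yc <- puncta$y[i]
        xs <- max(1, floor(xc - w)):min(n, ceiling(xc + w))
        ys <- max(1, floor(yc - w)):min(n, ceiling(yc + w))
        if (!length(xs) || !length(ys)) next
        gx <- exp(-(xs - xc)^2 / (2 * sig_px^2))
        gy <- exp(-(ys - yc)^2 / (2 * sig_px^2))
        patch <- puncta$amp[i] * outer(gy, gx)
        wz <- exp(-(z_of - puncta$z_um[i])^2 / (2 * spec$psf_sigma_z_um^2))
        for (s in seq_len(nz))
          stack[ys, xs, s] <- stack[ys, xs, s] + wz[s] * patch
      }
    }

    truth_f <- NA_real_
    if (!is.null(spec$decay_region)) {
      dr <- spec$decay_region
      ctr <- if (is.null(dr$center_px)) c((n + 1) / 2, (n + 1) / 2) else dr$center_px
      r_px <- dr$region_diam_um / 2 / upp
      if (ctr[1] - r_px < 0 || ctr[1] + r_px > n + 1 ||
          ctr[2] - r_px < 0 || ctr[2] + r_px > n + 1)
        stop("decay region exceeds the field")
      d2 <- outer((seq_len(n) - ctr[2])^2, (seq_len(n) - ctr[1])^2, "+")
      inside <- d2 <= r_px^2
      for (s in seq_len(nz)) {
        sl <- stack[, , s]
        sl[inside] <- sl[inside] * dr$fraction
        stack[, , s] <- sl
      }
      truth_f <- dr$fraction
    }

    if (isTRUE(spec$shot_noise))
      stack <- array(rpois(length(stack), lambda = stack), dim = dim(stack))
    if (spec$read_noise_sd > 0)
      stack <- stack + rnorm(length(stack), 0, spec$read_noise_sd)
    stack <- pmax(stack, 0)
    attr(stack, "um_per_px") <- upp
    attr(stack, "z_step_um") <- spec$z_step_um

    structure(list(stack = stack,
                   truth = list(puncta = puncta, region_fraction = truth_f,
                                bands_px = band_px),
                   spec = spec, seed = seed),
              class = "tg_fish_stack")
  })
}

#' @export
print.tg_fish_stack <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Synthetic FISH stack: %d x %d px, %d slices (%.2f um/px, dz %.2f um)\n",
              d[2], d[1], d[3], attr(x$stack, "um_per_px"),
              attr(x$stack, "z_step_um")))
  cat(sprintf("  planted puncta: %d; region remaining fraction: %s\n",
              nrow(x$truth$puncta),
              ifelse(is.na(x$truth$region_fraction), "none",
                     format(x$truth$region_fraction))))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' The sidecar records pixel size and z spacing. Intensities are stored as
#' 32-bit floats scaled to `[0, 1]` by the recorded `scale`.
#'
#' @param stack `[y, x, z]` numeric array with `um_per_px`/`z_step_um`
#'   attributes.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly (for `write_stack_tiff`); the restored array
#'   for `read_stack_tiff`.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  sc <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(s) stack[, , s] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(um_per_px = attr(stack, "um_per_px"),
               z_step_um = attr(stack, "z_step_um"),
               n_slices = dim(stack)[3], scale = sc)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    meta$scale
  attr(stack, "um_per_px") <- meta$um_per_px
  attr(stack, "z_step_um") <- meta$z_step_um
  stack
}
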