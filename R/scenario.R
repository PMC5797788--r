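#' Integration scenario
#'
#' Parameters describing the transgene insertion to simulate and recover:
#' breakpoint coordinates (retained-flank convention: `left_bp` is the last
#' retained base of the left flank, `right_bp` the first retained base of the
#' right flank, so the deletion length is `right_bp - left_bp - 1`), tandem
#' copy count, junction microhomology lengths, zygosity and array
#' orientation. The defaults encode the characterized locus: breakpoints at
#' Chr12:78,137,441 and 78,139,250 (an 1,808-bp deletion), 4- and 5-bp
#' junction microhomologies, ~15 tandem copies, homozygous.
#'
#' The genome is modelled as desk-scale windows carrying global coordinate
#' offsets: an 80-kb chr12 window around the insertion, a 20-kb chr15 window
#' containing the endogenous Arc locus (Chr15:74,669,000-74,682,000), and an
#' 80-kb unique control window ("chr6") whose central 60 kb serve as the
#' depth-normalization locus.
#'
#' @param chrom chromosome label of the insertion.
#' @param left_bp,right_bp 1-based global breakpoint coordinates
#'   (retained-flank convention).
#' @param copies tandem transgene copies per transgenic locus.
#' @param h_left,h_right junction microhomology lengths (bp).
#' @param zygosity `"homozygous"`, `"hemizygous"` or `"wt"`.
#' @param orientation transgene array orientation relative to the chromosome.
#' @param chr12_start,chr12_len global start and length of the chr12 window.
#' @param chr15_start,chr15_len global start and length of the chr15 window.
#' @param arc_locus global interval (length-2 vector) of the Arc locus on chr15.
#' @param arc_orf_start global start of the 1,200-bp Arc ORF marker segment
#'   (copied verbatim into the transgene, reproducing its multi-mapping).
#' @param control_chrom,control_start,control_len the control window.
#' @param control_locus_len length of the unique control (normalizer) locus,
#'   centered in the control window.
#' @param transgene_len total transgene length (bp).
#' @param promoter_len,utr5_len,egfp_len,orf_len transgene component lengths;
#'   the 3'UTR takes the remainder.
#' @return an object of class `tg_scenario`.
#' @export
integration_scenario <- function(chrom = "chr12",
                                 left_bp = 78137441L,
                                 right_bp = 78139250L,
                                 copies = 15L,
                                 h_left = 4L,
                                 h_right = 5L,
                                 zygosity = c("homozygous", "hemizygous", "wt"),
                                 orientation = c("+", "-"),
                                 chr12_start = 78100001L, chr12_len = 80000L,
                                 chr15_start = 74665001L, chr15_len = 20000L,
                                 arc_locus = c(74669000L, 74682000L),
                                 arc_orf_start = 74674001L,
                                 control_chrom = "chr6",
                                 control_start = 125130001L, control_len = 80000L,
                                 control_locus_len = 60000L,
                                 transgene_len = 11829L,
                                 promoter_len = 7000L, utr5_len = 200L,
                                 egfp_len = 750L, orf_len = 1200L) {
  zygosity <- match.arg(zygosity)
  orientation <- match.arg(orientation)
  if (right_bp <= left_bp + 1L) stop("right_bp must exceed left_bp + 1")
  if (copies < 1L) stop("copies must be >= 1")
  if (h_left < 0L || h_right < 0L) stop("microhomology lengths must be >= 0")
  fixed <- promoter_len + utr5_len + egfp_len + orf_len
  if (transgene_len < fixed)
    stop("transgene_len smaller than the sum of its fixed components")
  if (left_bp <= chr12_start + h_left + 50L ||
      right_bp >= chr12_start + chr12_len - h_right - 50L)
    stop("breakpoints too close to the chr12 window edges")
  if (arc_locus[1] < chr15_start || arc_locus[2] > chr15_start + chr15_len - 1L)
    stop("arc_locus outside the chr15 window")
  if (arc_orf_start < arc_locus[1] || arc_orf_start + orf_len - 1L > arc_locus[2])
    stop("Arc ORF marker outside the Arc locus")
  structure(list(
    chrom = chrom, left_bp = as.integer(left_bp), right_bp = as.integer(right_bp),
    copies = as.integer(copies),
    h_left = as.integer(h_left), h_right = as.integer(h_right),
    zygosity = zygosity, orientation = orientation,
    chr12_start = as.integer(chr12_start), chr12_len = as.integer(chr12_len),
    chr15_start = as.integer(chr15_start), chr15_len = as.integer(chr15_len),
    arc_locus = as.integer(arc_locus), arc_orf_start = as.integer(arc_orf_start),
    control_chrom = control_chrom,
    control_start = as.integer(control_start),
    control_len = as.integer(control_len),
    control_locus_len = as.integer(control_locus_len),
    transgene_len = as.integer(transgene_len),
    promoter_len = as.integer(promoter_len), utr5_len = as.integer(utr5_len),
    egfp_len = as.integer(egfp_len), orf_len = as.integer(orf_len)
  ), class = "tg_scenario")
}

#' @export
print.tg_scenario <- function(x, ...) {
  del <- x$right_bp - x$left_bp - 1L
  cat("Transgene integration scenario\n")
  cat(sprintf("  %s:%s-%s (deletion %s bp), %d copies, h = %d/%d, %s, '%s'\n",
              x$chrom, format(x$left_bp, big.mark = ","),
              format(x$right_bp, big.mark = ","), format(del, big.mark = ","),
              x$copies, x$h_left, x$h_right, x$zygosity, x$orientation))
  invisible(x)
}

#' Deletion length implied by a scenario or call
#' @param left_bp,right_bp breakpoints in the retained-flank convention.
#' @return `right_bp - left_bp - 1`.
#' @export
deletion_length <- function(left_bp, right_bp) {
  as.integer(right_bp) - as.integer(left_bp) - 1L
}

#' Read-simulation parameters
#'
#' @param read_len read length in bp (150-bp paired-end by default).
#' @param insert_mean,insert_sd fragment-size distribution (bp).
#' @param coverage haploid-reference-equivalent sequencing depth (the study
#'   library was 13.5x); [simulate_read_pairs()] interprets it as mean depth
#'   over the supplied haplotype pool.
#' @param q_shape quality profile: per-base mean Phred quality is
#'   `q_max - q_drop * ((i-1)/(read_len-1))^2`, jittered with sd `q_sd` and
#'   clipped to `[2, 41]`. Substitution errors are drawn per base with
#'   probability `10^(-q/10)`.
#' @param q_max,q_drop,q_sd see `q_shape`.
#' @param adapter 3' adapter sequence read through when the fragment is
#'   shorter than the read.
#' @return object of class `tg_read_sim_params`.
#' @export
read_sim_params <- function(read_len = 150L, insert_mean = 350, insert_sd = 50,
                            coverage = 13.5, q_max = 37, q_drop = 7, q_sd = 2,
                            adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                            q_shape = NULL) {
  if (read_len < 36L) stop("read_len must be >= 36")
  if (coverage <= 0) stop("coverage must be positive")
  structure(list(read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, q_max = q_max, q_drop = q_drop,
                 q_sd = q_sd, adapter = adapter),
            class = "tg_read_sim_params")
}

#' qPCR plate specification
#'
#' SYBR-style relative quantification design: per-well Ct values follow
#' `Ct = baseline_ct - log_E(copies / 2) + noise`, where copies is the
#' diploid count of the target (Arc ORF: 2 for wildtype, 2 + C hemizygous,
#' 2 + 2C homozygous; control locus: always 2).
#'
#' @param efficiency amplification factor per cycle E, in (1, 2].
#' @param baseline_ct Ct of a 2-copy target.
#' @param replicates technical replicate wells per sample x target.
#' @param noise_sd replicate Ct standard deviation (cycles).
#' @param copies transgene copies per transgenic locus.
#' @param panel data.frame with columns `sample` and `genotype`
#'   (`wt`/`hemizygous`/`homozygous`); the default mirrors a
#'   4 WT / 4 hemizygous / 8 homozygous genotyping cohort.
#' @return object of class `tg_qpcr_spec`.
#' @export
qpcr_plate_spec <- function(efficiency = 2, baseline_ct = 22, replicates = 3L,
                            noise_sd = 0.05, copies = 15L, panel = NULL) {
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(panel)) {
    panel <- data.frame(
      sample = c(paste0("wt", 1:4), paste0("hemi", 1:4), paste0("homo", 1:8)),
      genotype = rep(c("wt", "hemizygous", "homozygous"), c(4, 4, 8)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample", "genotype") %in% names(panel)),
            all(panel$genotype %in% c("wt", "hemizygous", "homozygous")))
  structure(list(efficiency = efficiency, baseline_ct = baseline_ct,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 copies = as.integer(copies), panel = panel),
            class = "tg_qpcr_spec")
}

#' Decay-series specification
#'
#' First-order decay sampled at fixed times after transcriptional block:
#' `fraction = 2^(-t / t_half) * exp(noise)`.
#'
#' @param times sampling times in minutes since the block.
#' @param t_half true half-life in minutes.
#' @param log_noise_sd sd of the multiplicative log-normal noise.
#' @param replicates replicate observations per time point.
#' @return object of class `tg_decay_spec`.
#' @export
decay_series_spec <- function(times = c(15, 30, 45, 60), t_half = 45,
                              log_noise_sd = 0.1, replicates = 3L) {
  if (any(times < 0)) stop("times must be >= 0")
  if (t_half <= 0) stop("t_half must be positive")
  if (log_noise_sd < 0) stop("log_noise_sd must be >= 0")
  structure(list(times = times, t_half = t_half,
                 log_noise_sd = log_noise_sd, replicates = as.integer(replicates)),
            class = "tg_decay_spec")
}

#' FISH image-stack specification
#'
#' Geometry and signal model for a synthetic dentate-gyrus-like confocal
#' z-stack: laminar bands along x (granule cell layer and inner/middle/outer
#' molecular layers), diffraction-limited mRNA puncta rendered as 2-D
#' Gaussians spread across z slices, optional circular transcription-block
#' (Act-D) region whose signal is scaled by a remaining fraction `f` before
#' noise, and Poisson shot + Gaussian read noise.
#'
#' The default emulates the 63x puncta-counting field: a 204.8-um field
#' (read as side length), 4 slices 0.55 um apart (1.65 um total range).
#' [fish_actd_spec()] provides the wider 20x-style field used for decay-ratio
#' quantification.
#'
#' @param field_um field side length in um.
#' @param um_per_px pixel size in um.
#' @param n_slices,z_step_um z-stack geometry.
#' @param bands data.frame with columns `name`, `width_um`, `density_per_um2`
#'   (puncta surface density) and `level` (band background intensity), laid
#'   left to right along x; `NULL` for a uniform field.
#' @param base_level intensity added everywhere (out-of-band background).
#' @param uniform_level,uniform_density used when `bands` is `NULL`.
#' @param punct_amp peak amplitude of a punctum.
#' @param punct_amp_cv lognormal coefficient of variation of amplitudes.
#' @param psf_sigma_um lateral PSF sigma; `psf_sigma_z_um` the axial sigma
#'   used to distribute a punctum across slices.
#' @param shot_noise logical; apply Poisson resampling of intensities.
#' @param read_noise_sd sd of additive Gaussian read noise.
#' @param decay_region `NULL`, or a list with `region_diam_um`,
#'   `core_diam_um`, `fraction` and optional `center_px`.
#' @return object of class `tg_fish_spec`.
#' @export
fish_image_spec <- function(field_um = 204.8, um_per_px = 0.2,
                            n_slices = 4L, z_step_um = 0.55,
                            bands = dentate_bands(), base_level = 10,
                            uniform_level = 20, uniform_density = 0,
                            punct_amp = 120, punct_amp_cv = 0.2,
                            psf_sigma_um = 0.25, psf_sigma_z_um = 0.6,
                            shot_noise = TRUE, read_noise_sd = 2,
                            decay_region = NULL) {
  npx <- round(field_um / um_per_px)
  if (!is.null(bands)) {
    stopifnot(all(c("name", "width_um", "density_per_um2", "level") %in% names(bands)))
    if (sum(bands$width_um) > field_um + 1e-9)
      stop("bands exceed the field")
  }
  if (!is.null(decay_region)) {
    stopifnot(all(c("region_diam_um", "core_diam_um", "fraction") %in%
                    names(decay_region)))
    if (decay_region$fraction <= 0 || decay_region$fraction > 1)
      stop("remaining fraction must be in (0, 1]")
    if (decay_region$core_diam_um >= decay_region$region_diam_um)
      stop("excluded core must be smaller than the region")
  }
  structure(list(field_um = field_um, um_per_px = um_per_px, npx = npx,
                 n_slices = as.integer(n_slices), z_step_um = z_step_um,
                 bands = bands, base_level = base_level,
                 uniform_level = uniform_level, uniform_density = uniform_density,
                 punct_amp = punct_amp, punct_amp_cv = punct_amp_cv,
                 psf_sigma_um = psf_sigma_um, psf_sigma_z_um = psf_sigma_z_um,
                 shot_noise = shot_noise, read_noise_sd = read_noise_sd,
                 decay_region = decay_region),
            class = "tg_fish_spec")
}

#' Default dentate-gyrus laminar band geometry
#'
#' Band widths, puncta surface densities and background levels for the 63x
#' puncta-counting field: granule cell layer (GCL) plus inner, middle and
#' outer molecular layers (IML/MML/OML), laid left to right along x.
#'
#' @return data.frame with columns `name`, `width_um`, `density_per_um2`,
#'   `level`.
#' @export
dentate_bands <- function() {
  data.frame(
    name = c("GCL", "IML", "MML", "OML"),
    width_um = c(60, 40, 60, 44.8),
    density_per_um2 = c(0.005, 0.02, 0.03, 0.015),
    level = c(30, 15, 15, 15),
    stringsAsFactors = FALSE)
}

#' Act-D decay-region imaging specification
#'
#' A 20x-style uniform field with a circular region of transcriptional
#' blockade (diameter within the reported 300-500 um) around the pipette
#' site, a 150-um damaged core excluded from measurement, and signal inside
#' the region scaled to the fraction remaining after `time_min` minutes of
#' block at half-life `t_half`. The transgenic 60-min default gives
#' `f = 2^(-60 / 144.57) = 0.75`.
#'
#' @param time_min minutes of transcriptional block.
#' @param t_half mRNA half-life in minutes (default: the transgenic in-vivo
#'   value implied by 75 percent remaining at 60 min).
#' @param fraction override the remaining fraction directly.
#' @param region_diam_um,core_diam_um blockade-region geometry.
#' @param ... passed to [fish_image_spec()].
#' @return object of class `tg_fish_spec`.
#' @export
fish_actd_spec <- function(time_min = 60, t_half = HALF_LIFE_TG_INVIVO,
                           fraction = NULL,
                           region_diam_um = 400, core_diam_um = 150, ...) {
  f <- if (is.null(fraction)) fraction_remaining(time_min, t_half) else fraction
  fish_image_spec(field_um = 819.2, um_per_px = 0.8,
                  n_slices = 1L,  # single wide-field 20x image
                  bands = NULL, uniform_level = 100, uniform_density = 0,
                  base_level = 0,
                  decay_region = list(region_diam_um = region_diam_um,
                                      core_diam_um = core_diam_um,
                                      fraction = f),
                  ...)
}
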