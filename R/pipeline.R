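#' Run the end-to-end locus-discovery pipeline
#'
#' Simulates the study design and recovers the integration call: reference
#' building, transgenic haplotype assembly, 150-bp paired-end read
#' simulation at the scenario coverage, adapter/quality trimming with pair
#' filtering, mapping, integration calling, and copy-number estimation by
#' read depth and by a simulated qPCR plate. All stage seeds are fanned out
#' deterministically from `seed`.
#'
#' @param scenario an [integration_scenario()]; the default encodes the
#'   characterized locus (homozygous, 15 copies, 13.5x coverage via
#'   `params`).
#' @param params a [read_sim_params()]; `coverage` is interpreted as
#'   haploid-reference-equivalent depth (the diploid haplotype pool is
#'   sequenced at `coverage / 2` per haplotype).
#' @param qpcr a [qpcr_plate_spec()]; its `copies` field is synchronized to
#'   the scenario.
#' @param filter a [pair_filter_params()].
#' @param config caller configuration, see [call_integration()].
#' @param seed top-level integer seed.
#' @return object of class `tg_report_bundle`: integration `call`,
#'   `copy_depth`, `copy_qpcr`, read-count `counts`, and `provenance`
#'   (seed, configuration hash, package version).
#' @export
run_locus_pipeline <- function(scenario = integration_scenario(),
                               params = read_sim_params(),
                               qpcr = qpcr_plate_spec(),
                               filter = pair_filter_params(),
                               config = list(), seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  qpcr$copies <- scenario$copies

  refs <- build_reference_set(scenario, seed = seeds[1])
  allele <- build_transgenic_allele(refs)
  p2 <- params
  p2$coverage <- params$coverage / 2  # diploid pool -> reference depth
  reads <- simulate_read_pairs(allele, p2, seed = seeds[2])
  prepped <- prep_pairs(reads, filter)
  index <- build_index(refs)
  aln <- map_read_pairs(index, prepped$read1, prepped$read2, params)
  call <- call_integration(aln, refs, config)

  zyg <- if (identical(call$status, "call")) {
    if (call$zygosity == "homozygous") "homozygous" else "hemizygous"
  } else "wt"
  cn_depth <- depth_copy_number(aln, refs, zygosity = zyg)
  plate <- simulate_qpcr_plate(qpcr, seed = seeds[3])
  cn_qpcr <- qpcr_copy_number(plate, efficiency = qpcr$efficiency,
                              genotype = if (zyg == "wt") NULL else zyg)

  cfg_hash <- config_hash(list(scenario = unclass(scenario),
                               params = unclass(params),
                               qpcr = unclass(qpcr)[names(qpcr) != "panel"],
                               filter = unclass(filter), config = config))
  structure(list(
    call = call, copy_depth = cn_depth, copy_qpcr = cn_qpcr,
    counts = cbind(prepped$stats,
                   n_aligned = sum(aln$mapped),
                   n_informative = length(unique(
                     extract_informative_pairs(aln, refs)$qname))),
    scenario = scenario,
    provenance = list(seed = seed, stage_seeds = seeds,
                      config_hash = cfg_hash,
                      package_version = as.character(
                        utils::packageVersion("tgsite")))),
    class = "tg_report_bundle")
}

# md5 of a canonical deparse of the configuration
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' @export
print.tg_report_bundle <- function(x, ...) {
  cat("Locus-discovery report (seed ", x$provenance$seed, ")\n", sep = "")
  print(x$call)
  print(x$copy_depth)
  print(x$copy_qpcr)
  cat(sprintf("  pairs: %d simulated, %d kept after trimming/filtering\n",
              x$counts$input, x$counts$kept))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `integration_call.tsv`, `copy_number.tsv`, `bundle.json` and
#' `run.log` (seed and configuration echo) under `dir`. Re-running the same
#' bundle reproduces the files byte for byte.
#'
#' @param bundle a `tg_report_bundle`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_reports <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- bundle$call
  call_df <- if (identical(cl$status, "call")) {
    data.frame(status = "call", chrom = cl$chrom, left_bp = cl$left_bp,
               right_bp = cl$right_bp, deletion_length = cl$deletion_length,
               h_left = cl$h_left, h_right = cl$h_right,
               orientation = cl$orientation,
               support_left = cl$support["left"],
               support_right = cl$support["right"],
               zygosity = cl$zygosity, low_confidence = cl$low_confidence,
               n_secondary_sites = nrow(cl$secondary_sites))
  } else {
    data.frame(status = "no_call", chrom = NA, left_bp = NA, right_bp = NA,
               deletion_length = NA, h_left = NA, h_right = NA,
               orientation = NA, support_left = NA, support_right = NA,
               zygosity = NA, low_confidence = NA, n_secondary_sites = NA)
  }
  f1 <- file.path(dir, "integration_call.tsv")
  write.table(call_df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  cn <- rbind(
    data.frame(method = "depth", total = bundle$copy_depth$total,
               per_locus = bundle$copy_depth$per_locus,
               per_locus_int = bundle$copy_depth$per_locus_int),
    data.frame(method = "qpcr", total = bundle$copy_qpcr$total,
               per_locus = bundle$copy_qpcr$per_locus,
               per_locus_int = bundle$copy_qpcr$per_locus_int))
  f2 <- file.path(dir, "copy_number.tsv")
  write.table(cn, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir, "bundle.json")
  jsonlite::write_json(list(call = call_df, copy_number = cn,
                            counts = bundle$counts,
                            provenance = bundle$provenance),
                       f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  f4 <- file.path(dir, "run.log")
  writeLines(c(sprintf("seed: %d", bundle$provenance$seed),
               sprintf("config_hash: %s", bundle$provenance$config_hash),
               sprintf("package_version: %s",
                       bundle$provenance$package_version)), f4)
  invisible(c(f1, f2, f3, f4))
}
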