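# End-to-end pipeline: read inputs, annotate variants against predicted
# sites, prioritize by expression, and write reports plus a reproducible
# run manifest.

#' Validate a pipeline configuration
#'
#' Checks the structure before any computation: required input paths, the
#' variant dialect, numeric parameters. Raises a
#' `polymirts_config_error` on any violation.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Fields: `inputs$utr`, `inputs$mirnas`, `inputs$variants` (paths),
#'   optional `inputs$expression`, optional `inputs$variant_dialect`
#'   (`"tsv"`/`"vcf_lite"`), optional `params` (`cutoff`, `flank`,
#'   `noncanonical`, `emit_6mer`, `min_supplementary`), `out_dir`.
#' @return The normalized config list, invisibly.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config),
            class = "polymirts_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("Config must be a list or a YAML file path.",
          class = "polymirts_config_error")
  }
  defaults <- list(params = list(cutoff = 45L, flank = 0L, noncanonical = TRUE,
                                 emit_6mer = TRUE, min_supplementary = 0L))
  config$params <- modifyList(defaults$params, config$params %||% list())
  for (f in c("utr", "mirnas", "variants")) {
    p <- config$inputs[[f]]
    if (is.null(p) || !is.character(p)) {
      abort(sprintf("Config is missing required input path 'inputs$%s'.", f),
            class = "polymirts_config_error")
    }
    if (!file.exists(p)) {
      abort(sprintf("Input file for '%s' does not exist: %s", f, p),
            class = "polymirts_config_error")
    }
  }
  config$inputs$variant_dialect <- config$inputs$variant_dialect %||% "tsv"
  if (!config$inputs$variant_dialect %in% c("tsv", "vcf_lite")) {
    abort("inputs$variant_dialect must be 'tsv' or 'vcf_lite'.",
          class = "polymirts_config_error")
  }
  if (is.null(config$out_dir)) {
    abort("Config is missing 'out_dir'.", class = "polymirts_config_error")
  }
  pr <- config$params
  if (pr$cutoff < 0 || pr$flank < 0 || pr$min_supplementary < 0) {
    abort("cutoff, flank and min_supplementary must be >= 0.",
          class = "polymirts_config_error")
  }
  invisible(config)
}

#' Run the annotate-prioritize pipeline
#'
#' Reads the configured inputs, annotates every variant against predicted
#' miRNA target sites, writes the record table (TSV + JSON), builds the
#' expression-prioritized candidate report, and writes a run manifest
#' (package version, config hash, input file digests, seed, timestamp).
#' Outputs are deterministic given fixed inputs.
#'
#' @inheritParams validate_config
#' @param seed Optional integer recorded in the manifest (the annotation
#'   stage itself is deterministic).
#' @return A list with `records`, `report`, `paths` (output files) and
#'   `manifest`, invisibly.
#' @export
run_pipeline <- function(config, seed = NULL) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  utrs <- read_rna_fasta(config$inputs$utr)
  mirnas <- read_mirna_fasta(config$inputs$mirnas)
  polys <- read_variant_table(config$inputs$variants,
                              dialect = config$inputs$variant_dialect)
  expression <- if (!is.null(config$inputs$expression)) {
    read_expression_table(config$inputs$expression)
  }
  cfg <- scan_config(noncanonical = config$params$noncanonical,
                     emit_6mer = config$params$emit_6mer,
                     min_supplementary = config$params$min_supplementary)
  records <- annotate_polymirts(utrs, polys, mirnas, expression,
                                config = cfg, flank = config$params$flank)
  report <- build_candidate_report(records, cutoff = config$params$cutoff)

  paths <- list(
    records_tsv = file.path(config$out_dir, "records.tsv"),
    records_json = file.path(config$out_dir, "records.json"),
    candidates_json = file.path(config$out_dir, "candidates.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_report(records, paths$records_tsv, "tsv")
  write_report(records, paths$records_json, "json")
  jsonlite::write_json(
    list(cutoff = report$cutoff,
         n_input_mirnas = report$n_input_mirnas,
         n_candidate_mirnas = report$n_candidate_mirnas,
         candidates = report$candidates,
         by_snp = report$by_snp),
    paths$candidates_json, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  inputs <- unlist(config$inputs[c("utr", "mirnas", "variants", "expression")])
  manifest <- list(
    tool = "polymirts",
    version = as.character(packageVersion("polymirts")),
    config_hash = rlang::hash(config[c("inputs", "params")]),
    input_digests = as.list(setNames(unname(tools::md5sum(unname(inputs))),
                                     names(inputs))),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(records = records, report = report, paths = paths,
                 manifest = manifest))
}
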