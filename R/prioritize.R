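# Candidate narrowing: from all annotated (variant, miRNA) records down to
# the miRNAs actually expressed in the tissue of interest, using a raw-read
# cutoff from small-RNA profiling.

#' Count distinct predicted miRNAs in a record table
#'
#' @param records Record tibble with a `mirna_name` column.
#' @return Integer: the number of distinct miRNA names (set semantics).
#' @export
count_distinct_mirnas <- function(records) {
  dplyr::n_distinct(records$mirna_name)
}

#' Filter records to expressed miRNAs
#'
#' Keeps records whose `raw_reads` is greater than or equal to `cutoff`
#' (inclusive: a record sitting exactly on the cutoff survives), in stable
#' input order. The operation is monotone in the cutoff and idempotent.
#'
#' @param records Record tibble with a `raw_reads` column.
#' @param cutoff Non-negative raw-read threshold. The default of 45 reads
#'   is the human cerebral neocortex expression cutoff used to narrow the
#'   candidate list.
#' @return The retained records.
#' @export
filter_expressed <- function(records, cutoff = 45L) {
  cutoff <- as.numeric(cutoff)
  if (is.na(cutoff) || cutoff < 0) {
    abort("cutoff must be >= 0.", class = "polymirts_contract_error")
  }
  dplyr::filter(records, .data$raw_reads >= cutoff)
}

#' Build a candidate-prioritization report
#'
#' Composes the expression filter with per-SNP grouping: the full input
#' records, the expressed subset, the distinct candidate miRNAs with their
#' SNPs, and summary counts.
#'
#' @inheritParams filter_expressed
#' @return A list of class `polymirts_report` with elements `records`,
#'   `expressed`, `candidates` (tibble: `mirna_name`, `raw_reads`,
#'   `n_snps`, `snp_ids`), `by_snp` (tibble: `snp_id`, `position`,
#'   `polymorphism`, `n_mirnas`, `n_expressed`), `cutoff`,
#'   `n_input_mirnas`, `n_candidate_mirnas`.
#' @export
build_candidate_report <- function(records, cutoff = 45L) {
  expressed <- filter_expressed(records, cutoff)
  candidates <- if (nrow(expressed) == 0L) {
    tibble(mirna_name = character(), raw_reads = integer(),
           n_snps = integer(), snp_ids = character())
  } else dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(expressed, .data$mirna_name),
      raw_reads = max(.data$raw_reads),
      n_snps = dplyr::n_distinct(.data$snp_id),
      snp_ids = paste(sort(unique(.data$snp_id)), collapse = ","),
      .groups = "drop"
    ),
    dplyr::desc(.data$raw_reads), .data$mirna_name
  )
  by_snp <- dplyr::summarise(
    dplyr::group_by(records, .data$snp_id, .data$position, .data$polymorphism),
    n_mirnas = dplyr::n_distinct(.data$mirna_name),
    n_expressed = dplyr::n_distinct(.data$mirna_name[.data$raw_reads >= cutoff]),
    .groups = "drop"
  )
  structure(
    list(records = records, expressed = expressed, candidates = candidates,
         by_snp = dplyr::arrange(by_snp, .data$position), cutoff = cutoff,
         n_input_mirnas = count_distinct_mirnas(records),
         n_candidate_mirnas = count_distinct_mirnas(expressed)),
    class = "polymirts_report"
  )
}

#' @export
print.polymirts_report <- function(x, ...) {
  cat(sprintf("polymiRTS candidate report (raw-read cutoff >= %s)\n", x$cutoff))
  cat(sprintf("  %d records, %d distinct miRNAs in input\n",
              nrow(x$records), x$n_input_mirnas))
  cat(sprintf("  %d candidate miRNAs expressed at or above the cutoff:\n",
              x$n_candidate_mirnas))
  if (nrow(x$candidates) > 0L) {
    print(x$candidates, n = Inf)
  }
  invisible(x)
}
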