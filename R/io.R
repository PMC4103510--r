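# Readers and writers for every external file the pipeline touches.
# All user-facing coordinates are 1-based inclusive; sequences are
# normalized to RNA (T -> U) on read.

#' Read a nucleotide FASTA file into a tibble
#'
#' Sequences are uppercased, T is mapped to U, multi-line records are
#' concatenated, and file order is preserved. Ambiguity codes (including N)
#' are rejected: the scanner requires fully determined sequences.
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet).
#' @return A tibble with columns `name`, `seq` (RNA alphabet) and `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">u1", "ggct", "acct"), fa)
#' read_rna_fasta(fa)
read_rna_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "polymirts_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("Cannot parse FASTA file %s: %s", path, conditionMessage(e)),
            class = "polymirts_format_error")
    }
  )
  if (length(set) == 0L) {
    abort(sprintf("FASTA file %s contains no records.", path),
          class = "polymirts_format_error")
  }
  nm <- stringr::str_trim(names(set))
  if (any(nm == "")) {
    abort("FASTA records must have non-empty headers.",
          class = "polymirts_format_error")
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    bad <- nm[nchar(seqs) == 0L][1]
    abort(sprintf("FASTA record '%s' has an empty sequence.", bad),
          class = "polymirts_format_error")
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_rna(seqs[i], what = sprintf("record '%s'", nm[i]))
  }, character(1))
  tibble(name = nm, seq = unname(seqs), length = nchar(seqs))
}

#' Read mature miRNA sequences from FASTA
#'
#' Like [read_rna_fasta()] but additionally validates that every miRNA is
#' at least 8 nt long (so that the seed, positions 2-8, exists) and adds a
#' `seed` column with those residues.
#'
#' @inheritParams read_rna_fasta
#' @return A tibble with columns `name`, `seq`, `length`, `seed`.
#' @export
read_mirna_fasta <- function(path) {
  out <- read_rna_fasta(path)
  short <- out$length < 8L
  if (any(short)) {
    abort(sprintf("miRNA '%s' is shorter than 8 nt; the seed (positions 2-8) must exist.",
                  out$name[short][1]),
          class = "polymirts_format_error")
  }
  dplyr::mutate(out, seed = substr(.data$seq, 2L, 8L))
}

#' Build a tibble of 3'UTR polymorphisms
#'
#' Normalizes raw variant fields to the internal representation: `ref`
#' carries the affected reference bases (empty for a pure insertion), `alt`
#' the replacement (empty for a pure deletion), `position` the 1-based
#' first affected base, and the affected interval is
#' `[position, position + nchar(ref) - 1]`.
#'
#' @param snp_id Variant identifiers.
#' @param position 1-based position of the first affected base in the UTR.
#' @param ref,alt Reference / alternate alleles (RNA or DNA letters; no
#'   anchor bases). Use `""` for the empty allele.
#' @param utr_name Optional UTR name the variant lies on.
#' @return A tibble with columns `snp_id`, `utr_name`, `position`, `end`,
#'   `ref`, `alt`, `kind`, `label` (a printed form such as `C/U` or `delCA`).
#' @export
#' @examples
#' polymorphism_table("rs141849450", 515, "CA", "")
polymorphism_table <- function(snp_id, position, ref, alt, utr_name = NA_character_) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) {
    abort("Variant positions must be integers >= 1.",
          class = "polymirts_coordinate_error")
  }
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  ref[is.na(ref) | ref %in% c("-", ".")] <- ""
  alt[is.na(alt) | alt %in% c("-", ".")] <- ""
  ref <- ifelse(ref == "", "", normalize_rna(ref, "ref allele"))
  alt <- ifelse(alt == "", "", normalize_rna(alt, "alt allele"))
  kind <- dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(alt) == 0L & nchar(ref) >= 1L ~ "deletion",
    nchar(ref) == 0L & nchar(alt) >= 1L ~ "insertion",
    TRUE ~ "complex"
  )
  if (any(kind == "complex")) {
    abort("Unsupported allele combination (use SNV, pure deletion or pure insertion).",
          class = "polymirts_format_error")
  }
  if (any(kind == "SNV" & ref == alt)) {
    abort("SNV ref and alt alleles must differ.", class = "polymirts_format_error")
  }
  tibble(
    snp_id = as.character(snp_id),
    utr_name = utr_name,
    position = position,
    end = position + pmax(nchar(ref) - 1L, 0L),
    ref = ref,
    alt = alt,
    kind = kind,
    label = dplyr::case_when(
      kind == "SNV" ~ paste0(ref, "/", alt),
      kind == "deletion" ~ paste0("del", ref),
      kind == "insertion" ~ paste0("ins", alt)
    )
  )
}

#' Read a polymorphism table (TSV or minimal VCF)
#'
#' Two dialects are supported. `tsv` expects header columns `snp_id`,
#' `position`, `ref`, `alt` (and optionally `utr_name`), with alleles given
#' without anchor bases (a pure deletion has an empty `alt`). `vcf_lite` is
#' a minimal VCF: `CHROM` holds the UTR name, `POS` is 1-based, and indels
#' follow the usual anchor-base convention; the anchor base is stripped and
#' the position advanced so both dialects yield identical variants.
#'
#' @param path Path to the variant file.
#' @param dialect `"tsv"` or `"vcf_lite"`.
#' @return A tibble as returned by [polymorphism_table()].
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Variant file not found: %s", path), class = "polymirts_io_error")
  }
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    need <- c("snp_id", "position", "ref", "alt")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L) {
      abort(sprintf("Variant TSV is missing columns: %s", paste(missing, collapse = ", ")),
            class = "polymirts_format_error")
    }
    utr <- if ("utr_name" %in% names(df)) df$utr_name else NA_character_
    pos <- suppressWarnings(as.integer(df$position))
    if (any(is.na(pos))) {
      abort("Variant TSV positions must be integers.", class = "polymirts_coordinate_error")
    }
    return(polymorphism_table(df$snp_id, pos, df$ref, df$alt, utr_name = utr))
  }
  # vcf_lite: parse with vcfR, then strip anchor bases for indels.
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("Cannot parse VCF %s: %s", path, conditionMessage(e)),
                              class = "polymirts_format_error")
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    abort(sprintf("VCF %s contains no variant rows.", path),
          class = "polymirts_format_error")
  }
  pos <- as.integer(fix$POS)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  if (any(grepl(",", alt, fixed = TRUE))) {
    abort("Multi-allelic VCF records are not supported; split them first.",
          class = "polymirts_format_error")
  }
  # Strip the shared anchor base of indel records (REF and ALT both start
  # with it by convention); SNVs pass through unchanged.
  is_indel <- nchar(ref) != nchar(alt)
  anchored <- is_indel & substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &
    nchar(ref) >= 1L & nchar(alt) >= 1L
  ref[anchored] <- substr(ref[anchored], 2L, nchar(ref[anchored]))
  alt[anchored] <- substr(alt[anchored], 2L, nchar(alt[anchored]))
  pos[anchored] <- pos[anchored] + 1L
  polymorphism_table(fix$ID, pos, ref, alt, utr_name = fix$CHROM)
}

#' Read a miRNA expression table
#'
#' Expects header columns `name` and `count` (small-RNA sequencing raw
#' reads). Duplicate miRNA names are an error because downstream joins
#' would be ambiguous.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `mirna_name`, `raw_reads`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Expression file not found: %s", path), class = "polymirts_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(c("name", "count"), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Expression table is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "polymirts_format_error")
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    abort("Expression counts must be non-negative integers.",
          class = "polymirts_format_error")
  }
  if (anyDuplicated(df$name)) {
    abort(sprintf("Duplicate miRNA name in expression table: %s",
                  df$name[duplicated(df$name)][1]),
          class = "polymirts_format_error")
  }
  tibble(mirna_name = df$name, raw_reads = as.integer(cnt))
}

REPORT_COLUMNS <- c("snp_id", "utr_name", "position", "end", "polymorphism",
                    "mirna_name", "seed_region", "raw_reads")

#' Write an annotated polymiRTS report
#'
#' Rows are emitted in a deterministic order (variant position ascending,
#' then miRNA name, then SNP id) so repeated writes are byte-identical,
#' and the file round-trips losslessly through [read_report()].
#'
#' @param records Record tibble as produced by [annotate_polymirts()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  missing <- setdiff(REPORT_COLUMNS, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Report records are missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "polymirts_format_error")
  }
  records <- dplyr::arrange(records[, REPORT_COLUMNS],
                            .data$position, .data$mirna_name, .data$snp_id)
  ok <- tryCatch({
    if (format == "tsv") {
      readr::write_tsv(records, path, progress = FALSE)
    } else {
      jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = FALSE,
                           digits = NA, pretty = TRUE, na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("Cannot write report to %s: %s", path, conditionMessage(ok)),
          class = "polymirts_io_error")
  }
  invisible(path)
}

#' Read back a polymiRTS report written by [write_report()]
#'
#' @param path Report path.
#' @param format `"tsv"` or `"json"`.
#' @return A record tibble with the standard report columns.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Report file not found: %s", path), class = "polymirts_io_error")
  }
  df <- if (format == "tsv") {
    readr::read_tsv(path, col_types = readr::cols(
      snp_id = readr::col_character(), utr_name = readr::col_character(),
      position = readr::col_integer(), end = readr::col_integer(),
      polymorphism = readr::col_character(), mirna_name = readr::col_character(),
      seed_region = readr::col_character(), raw_reads = readr::col_integer()
    ), progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  df <- as_tibble(df)
  df$position <- as.integer(df$position)
  df$end <- as.integer(df$end)
  df$raw_reads <- as.integer(df$raw_reads)
  df$utr_name <- as.character(df$utr_name)
  df[, REPORT_COLUMNS]
}
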