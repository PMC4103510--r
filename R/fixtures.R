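# Packaged reference data: the published table of Nicastrin 3'UTR
# polymorphisms located in or near predicted miRNA target sites.

#' Nicastrin 3'UTR polymiRTS reference table
#'
#' The published screen of known SNPs in the human Nicastrin (NCSTN)
#' 3'UTR against predicted miRNA binding sites (canonical and
#' non-canonical): one row per (polymorphism, predicted miRNA) pair with
#' the printed seed-region flag and the miRNA's raw small-RNA read count
#' in human cerebral neocortex. 22 distinct miRNAs across 9 polymorphic
#' loci; 6 miRNAs survive the 45-raw-read expression cutoff.
#'
#' Positions are stored exactly as printed (1-based in the 3'UTR). Whether
#' they count from the first base after the stop codon or from the start
#' of the cloned ~700-bp fragment is not documented in the source and is
#' left unresolved here. The seed-region flag is likewise the printed
#' value: for some rows it may encode a non-seed footprint overlap, for
#' others a non-canonical seed -- the scanner's own classification of a
#' given sequence is reported separately, never forced to match.
#'
#' @return A tibble with columns `snp_id`, `utr_name`, `position`, `end`,
#'   `polymorphism`, `mirna_name`, `seed_region` (`"Y"`/`"N"`),
#'   `raw_reads`.
#' @export
#' @examples
#' tbl <- ncstn_polymirts()
#' count_distinct_mirnas(tbl)
#' count_distinct_mirnas(filter_expressed(tbl, 45))
ncstn_polymirts <- function() {
  path <- system.file("extdata", "ncstn_table1.tsv", package = "polymirts",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), utr_name = readr::col_character(),
    position = readr::col_integer(), end = readr::col_integer(),
    polymorphism = readr::col_character(), mirna_name = readr::col_character(),
    seed_region = readr::col_character(), raw_reads = readr::col_integer()
  ), progress = FALSE)
}
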