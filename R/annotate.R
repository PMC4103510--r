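# Intersection of 3'UTR polymorphisms with predicted miRNA target sites:
# seed vs compensatory classification, allele application with coordinate
# remapping, windowed rescan of the alternate allele, and per-(variant,
# miRNA) effect calls.

#' Classify where a variant falls relative to one target site
#'
#' Interval-intersection semantics on 1-based inclusive intervals
#' (any-overlap rule, so deletions spanning a boundary count): `"Y"` if the
#' variant's affected interval intersects the site's seed interval, `"N"`
#' if it intersects the footprint extended by `flank` but not the seed,
#' `"none"` otherwise.
#'
#' @param poly One-row polymorphism tibble (see [polymorphism_table()]).
#' @param site One-row site tibble from [scan_sites()].
#' @param flank Non-negative flank (nt) added to the footprint when testing
#'   "near"-site overlap. Default 0: footprint only.
#' @return `"Y"`, `"N"` or `"none"`.
#' @export
classify_overlap <- function(poly, site, flank = 0L) {
  if (nrow(poly) != 1L || nrow(site) != 1L) {
    abort("classify_overlap() expects one variant and one site.",
          class = "polymirts_contract_error")
  }
  if (!is.na(poly$utr_name) && !identical(poly$utr_name, site$utr_name)) {
    abort(sprintf("Variant is on '%s' but site is on '%s'.",
                  poly$utr_name, site$utr_name),
          class = "polymirts_contract_error")
  }
  flank <- as.integer(flank)
  if (flank < 0L) abort("flank must be >= 0.", class = "polymirts_contract_error")
  a <- poly$position; b <- poly$end
  if (intervals_overlap(a, b, site$seed_start, site$seed_end)) return("Y")
  if (intervals_overlap(a, b, site$footprint_start - flank,
                        site$footprint_end + flank)) return("N")
  "none"
}

#' Apply a variant allele to a UTR sequence
#'
#' The reference allele is checked against the sequence at the stated
#' position (a mismatch raises a reference-disagreement error naming the
#' position, the expected and the found bases -- this guards against
#' fixture or coordinate drift). Returns the alternate sequence together
#' with a coordinate map from reference to alternate positions.
#'
#' @param utr A single UTR sequence (string, named vector, 1-row tibble).
#' @param poly One-row polymorphism tibble.
#' @return A list with elements `seq` (alternate UTR string), `name`,
#'   `map` (integer vector, length `nchar(ref utr)`: `map[i]` is the
#'   alternate-coordinate of reference position i, `NA` for deleted bases)
#'   and `inverse` (the polymorphism that undoes this allele).
#' @export
apply_allele <- function(utr, poly) {
  utr <- as_seq_tbl(utr, "utr")
  if (nrow(utr) != 1L || nrow(poly) != 1L) {
    abort("apply_allele() expects one UTR and one variant.",
          class = "polymirts_contract_error")
  }
  seq <- utr$seq
  L <- nchar(seq)
  a <- poly$position
  ref <- poly$ref; alt <- poly$alt
  nref <- nchar(ref); nalt <- nchar(alt)
  if (a > L + (nref == 0L)) {
    abort(sprintf("Variant position %d lies beyond the %d-nt UTR.", a, L),
          class = "polymirts_coordinate_error")
  }
  if (nref > 0L) {
    found <- substr(seq, a, a + nref - 1L)
    if (!identical(found, ref)) {
      abort(sprintf(
        "Reference disagreement at position %d of '%s': expected '%s', found '%s'.",
        a, utr$name, ref, found
      ), class = "polymirts_reference_error")
    }
  }
  left <- substr(seq, 1L, a - 1L)
  right <- if (a + nref <= L) substr(seq, a + nref, L) else ""
  new_seq <- paste0(left, alt, right)
  map <- integer(L)
  if (a > 1L) map[1:(a - 1L)] <- 1:(a - 1L)
  if (nref > 0L) {
    # bases inside the affected interval: SNV maps onto itself, deleted
    # (or replaced-away) bases map to nothing
    affected <- a:(a + nref - 1L)
    map[affected] <- if (nalt == nref) affected else NA_integer_
  }
  shift <- nalt - nref
  if (a + nref <= L) map[(a + nref):L] <- ((a + nref):L) + shift
  inverse <- polymorphism_table(poly$snp_id, a, ref = alt, alt = ref,
                                utr_name = poly$utr_name)
  list(seq = new_seq, name = utr$name, map = map, inverse = inverse)
}

# Affected interval of a variant on the alternate sequence: the image of
# the edit. For an SNV the substituted base; for a deletion the junction
# (flanking alternate positions); for an insertion the inserted bases.
alt_affected_interval <- function(poly, map, alt_len) {
  a <- poly$position
  switch(poly$kind,
    SNV = c(a, a),
    deletion = c(max(1L, a - 1L), min(alt_len, a)),
    insertion = c(a, a + nchar(poly$alt) - 1L)
  )
}

#' Call the per-allele consequence of a variant for one miRNA
#'
#' Scans the neighborhood of the variant on both alleles (a windowed rescan
#' provably identical to a full rescan restricted to that neighborhood) and
#' compares the sites whose footprint intersects the affected interval:
#' `site_loss` if reference sites disappear on the alternate allele,
#' `site_gain` for the reverse, `type_change` if sites persist with a
#' different class or seed pairing, `unchanged` otherwise.
#'
#' @inheritParams apply_allele
#' @param mirna A single mature miRNA sequence.
#' @param config A [scan_config()].
#' @param flank Flank (nt) added to the affected interval when selecting
#'   overlapping sites.
#' @return A one-row tibble: `snp_id`, `mirna_name`, `call`, `n_ref_sites`,
#'   `n_alt_sites`, plus list-columns `ref_sites` and `alt_sites` holding
#'   the overlapping site tibbles.
#' @export
allele_effect <- function(utr, poly, mirna, config = scan_config(), flank = 0L) {
  utr <- as_seq_tbl(utr, "utr"); mirna <- as_seq_tbl(mirna, "mirna")
  if (nrow(mirna) != 1L) {
    abort("allele_effect() expects a single miRNA.", class = "polymirts_contract_error")
  }
  flank <- as.integer(flank)
  a <- poly$position; b <- poly$end
  ref_region <- c(a - flank, b + flank)
  ref_sites <- scan_sites(utr, mirna, config, region = ref_region)

  applied <- apply_allele(utr, poly)
  alt_utr <- tibble(name = applied$name, seq = applied$seq)
  alt_iv <- alt_affected_interval(poly, applied$map, nchar(applied$seq))
  alt_sites <- scan_sites(alt_utr, mirna, config,
                          region = c(alt_iv[1] - flank, alt_iv[2] + flank))

  call <- if (nrow(ref_sites) > 0L && nrow(alt_sites) == 0L) {
    "site_loss"
  } else if (nrow(ref_sites) == 0L && nrow(alt_sites) > 0L) {
    "site_gain"
  } else if (nrow(ref_sites) == 0L && nrow(alt_sites) == 0L) {
    "unchanged"
  } else {
    sig <- function(x) {
      s <- dplyr::arrange(
        x[, c("site_type", "wobble_count", "mismatch_count")],
        .data$site_type, .data$wobble_count, .data$mismatch_count
      )
      paste(s$site_type, s$wobble_count, s$mismatch_count, collapse = ";")
    }
    if (identical(sig(ref_sites), sig(alt_sites))) "unchanged" else "type_change"
  }
  tibble(
    snp_id = poly$snp_id, mirna_name = mirna$name, call = call,
    n_ref_sites = nrow(ref_sites), n_alt_sites = nrow(alt_sites),
    ref_sites = list(ref_sites), alt_sites = list(alt_sites)
  )
}

#' Annotate polymorphisms with overlapping miRNA target sites
#'
#' For every (variant, miRNA) pair whose predicted sites lie in or near the
#' variant, emits one report record in the style of a polymiRTS table: the
#' variant, the miRNA, a seed-region flag (`"Y"` when the variant interval
#' intersects a site's seed interval, `"N"` when it only touches the
#' footprint or configured flank) and the miRNA's raw-read count (0 when
#' the miRNA is absent from the expression table). Classification is
#' per-pair: a variant hitting the seed of one miRNA's site and merely the
#' footprint of another's yields two records with different flags.
#'
#' @param utrs UTR sequences (tibble/named vector/string).
#' @param polys Polymorphism tibble (see [polymorphism_table()]).
#' @param mirnas miRNA sequences (tibble/named vector).
#' @param expression Optional expression tibble with `mirna_name`,
#'   `raw_reads` (see [read_expression_table()]).
#' @param config A [scan_config()].
#' @param flank Footprint flank (nt) defining "near".
#' @return A record tibble sorted by UTR position then miRNA name, with
#'   columns `snp_id`, `utr_name`, `position`, `end`, `polymorphism`,
#'   `mirna_name`, `seed_region`, `raw_reads`.
#' @export
annotate_polymirts <- function(utrs, polys, mirnas, expression = NULL,
                               config = scan_config(), flank = 0L) {
  utrs <- as_seq_tbl(utrs, "utr"); mirnas <- as_seq_tbl(mirnas, "mirna")
  empty <- tibble(
    snp_id = character(), utr_name = character(), position = integer(),
    end = integer(), polymorphism = character(), mirna_name = character(),
    seed_region = character(), raw_reads = integer()
  )
  if (nrow(polys) == 0L) return(empty)
  recs <- purrr::map_dfr(seq_len(nrow(polys)), function(pi) {
    poly <- polys[pi, ]
    utr_nm <- if (!is.na(poly$utr_name)) poly$utr_name else utrs$name[1]
    utr <- utrs[utrs$name == utr_nm, ]
    if (nrow(utr) != 1L) {
      abort(sprintf("Variant %s names UTR '%s' which is not among the inputs.",
                    poly$snp_id, utr_nm),
            class = "polymirts_contract_error")
    }
    sites <- scan_sites(utr, mirnas, config,
                        region = c(poly$position - flank, poly$end + flank))
    if (nrow(sites) == 0L) return(NULL)
    sites$flag <- vapply(seq_len(nrow(sites)), function(i) {
      classify_overlap(poly, sites[i, ], flank = flank)
    }, character(1))
    flags <- dplyr::summarise(
      dplyr::group_by(sites, .data$mirna_name),
      seed_region = if (any(.data$flag == "Y")) "Y"
                    else if (any(.data$flag == "N")) "N" else "none",
      .groups = "drop"
    )
    flags <- dplyr::filter(flags, .data$seed_region != "none")
    if (nrow(flags) == 0L) return(NULL)
    tibble(
      snp_id = poly$snp_id, utr_name = utr_nm, position = poly$position,
      end = poly$end, polymorphism = poly$label,
      mirna_name = flags$mirna_name, seed_region = flags$seed_region
    )
  })
  if (is.null(recs) || nrow(recs) == 0L) return(empty)
  if (is.null(expression)) {
    recs$raw_reads <- 0L
  } else {
    recs <- dplyr::left_join(recs, expression[, c("mirna_name", "raw_reads")],
                             by = "mirna_name")
    recs$raw_reads[is.na(recs$raw_reads)] <- 0L
  }
  dplyr::arrange(recs, .data$utr_name, .data$position, .data$mirna_name)
}
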