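# miRNA target-site scanner.
#
# Geometry: gapless antiparallel alignment. If the UTR base at position s
# pairs miRNA position 7, then miRNA position i faces UTR position
# s + (7 - i): the seed core (miRNA 2-7) occupies UTR s..s+5, miRNA
# position 8 faces s-1, and position 1 faces s+6. Site classes follow the
# canonical seed-match taxonomy (8mer > 7mer-m8 > 7mer-A1 > 6mer), with
# non-canonical 7-windows allowing exactly one G:U wobble or one mismatch
# across miRNA positions 2-8 and Watson-Crick pairs elsewhere.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer",
                "noncanonical-wobble", "noncanonical-mismatch")

#' Scanner configuration
#'
#' @param noncanonical Emit non-canonical sites (one G:U wobble or one
#'   mismatch in the miRNA 2-8 window)? Canonical sites are always emitted.
#' @param emit_6mer Emit 6mer sites? They are reported with
#'   `low_confidence = TRUE` since a 6-nt match alone is weak evidence.
#' @param min_supplementary Minimum number of Watson-Crick pairs between
#'   miRNA positions 13-16 and the facing UTR bases required to report a
#'   *non-canonical* site (canonical sites are never filtered on this).
#' @param max_deviations Maximum seed deviations in a non-canonical site;
#'   fixed at 1.
#' @return A list of class `polymirts_scan_config`.
#' @export
scan_config <- function(noncanonical = TRUE, emit_6mer = TRUE,
                        min_supplementary = 0L, max_deviations = 1L) {
  if (!identical(as.integer(max_deviations), 1L)) {
    abort("Only max_deviations = 1 is supported.", class = "polymirts_config_error")
  }
  structure(
    list(noncanonical = isTRUE(noncanonical),
         emit_6mer = isTRUE(emit_6mer),
         min_supplementary = as.integer(min_supplementary),
         max_deviations = 1L),
    class = "polymirts_scan_config"
  )
}

# Coerce sequence input (tibble with name/seq, named character vector, or
# a single string) to a two-column tibble.
as_seq_tbl <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    if (!all(c("name", "seq") %in% names(x))) {
      abort(sprintf("%s table must have columns 'name' and 'seq'.", what),
            class = "polymirts_format_error")
    }
    return(tibble(name = as.character(x$name), seq = as.character(x$seq)))
  }
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      if (length(x) != 1L) {
        abort(sprintf("Unnamed %s vectors must have length 1.", what),
              class = "polymirts_format_error")
      }
      nm <- what
    }
    return(tibble(name = nm, seq = unname(x)))
  }
  abort(sprintf("Cannot interpret %s input.", what), class = "polymirts_format_error")
}

empty_sites <- function() {
  tibble(
    utr_name = character(), mirna_name = character(),
    seed_start = integer(), seed_end = integer(),
    site_type = character(), wobble_count = integer(), mismatch_count = integer(),
    supplementary_score = integer(),
    footprint_start = integer(), footprint_end = integer(),
    low_confidence = logical()
  )
}

# Scan one (UTR, miRNA) pair. `s_range` restricts the core anchor positions
# evaluated; footprints are always computed against the full UTR.
scan_pair <- function(utr_seq, utr_name, mirna_seq, mirna_name, config,
                      s_range = NULL) {
  L <- nchar(utr_seq)
  M <- nchar(mirna_seq)
  if (M < 8L) {
    abort(sprintf("miRNA '%s' is shorter than 8 nt.", mirna_name),
          class = "polymirts_format_error")
  }
  if (L < 6L) return(empty_sites())
  u <- chars(utr_seq)
  m <- chars(mirna_seq)
  s_lo <- 1L; s_hi <- L - 5L
  if (!is.null(s_range)) {
    s_lo <- max(s_lo, s_range[1]); s_hi <- min(s_hi, s_range[2])
  }
  if (s_lo > s_hi) return(empty_sites())
  s <- s_lo:s_hi
  # pair classes for miRNA positions 2..8 at every anchor
  cls <- matrix(NA_integer_, nrow = 7L, ncol = length(s))
  for (i in 2:8) {
    idx <- s + (7L - i)
    ok <- idx >= 1L & idx <= L
    row <- rep(NA_integer_, length(s))
    row[ok] <- PAIR_CLASS[m[i], u[idx[ok]]]
    cls[i - 1L, ] <- row
  }
  wc27 <- colSums(cls[1:6, , drop = FALSE] == 2L) == 6L
  p8 <- cls[7L, ]
  t1_idx <- s + 6L
  t1A <- t1_idx <= L & u[pmin(t1_idx, L)] == "A"
  wc28 <- wc27 & !is.na(p8) & p8 == 2L
  n_wob <- colSums(cls == 1L, na.rm = TRUE)
  n_mis <- colSums(cls == 0L, na.rm = TRUE)
  n_wc <- colSums(cls == 2L, na.rm = TRUE)
  full_window <- !is.na(p8)

  type <- rep(NA_character_, length(s))
  type[wc28 & t1A] <- "8mer"
  type[wc28 & !t1A] <- "7mer-m8"
  type[wc27 & !wc28 & t1A] <- "7mer-A1"
  type[wc27 & !wc28 & !t1A] <- "6mer"
  nc_w <- is.na(type) & full_window & n_wob == 1L & n_mis == 0L & n_wc == 6L
  nc_m <- is.na(type) & full_window & n_mis == 1L & n_wob == 0L & n_wc == 6L
  type[nc_w] <- "noncanonical-wobble"
  type[nc_m] <- "noncanonical-mismatch"

  keep <- !is.na(type)
  if (!config$emit_6mer) keep <- keep & type != "6mer"
  if (!config$noncanonical) keep <- keep & !startsWith(type, "noncanonical")
  if (!any(keep)) return(empty_sites())

  s <- s[keep]; type <- type[keep]
  n_wob <- n_wob[keep]; n_mis <- n_mis[keep]
  six_based <- type %in% c("7mer-A1", "6mer")
  seed_start <- ifelse(six_based, s, s - 1L)
  seed_end <- s + 5L
  fp_start <- pmax(1L, s + 7L - M)
  fp_end <- pmin(L, s + 6L)

  supp <- vapply(s, function(si) supplementary_count(u, m, si), integer(1))

  out <- tibble(
    utr_name = utr_name, mirna_name = mirna_name,
    seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
    site_type = type,
    wobble_count = as.integer(n_wob), mismatch_count = as.integer(n_mis),
    supplementary_score = supp,
    footprint_start = as.integer(fp_start), footprint_end = as.integer(fp_end),
    low_confidence = type == "6mer"
  )
  if (config$noncanonical && config$min_supplementary > 0L) {
    out <- dplyr::filter(out, !startsWith(.data$site_type, "noncanonical") |
                           .data$supplementary_score >= config$min_supplementary)
  }
  out
}

# Watson-Crick pair count between miRNA positions 13-16 and the facing UTR
# bases; positions off either molecule contribute 0.
supplementary_count <- function(u, m, s) {
  L <- length(u); M <- length(m)
  total <- 0L
  for (i in 13:16) {
    if (i > M) next
    idx <- s + (7L - i)
    if (idx < 1L || idx > L) next
    if (PAIR_CLASS[m[i], u[idx]] == 2L) total <- total + 1L
  }
  total
}

#' Predict miRNA target sites on 3'UTR sequences
#'
#' Every UTR window is evaluated against miRNA positions 2-8 under gapless
#' antiparallel alignment. Canonical classes are assigned by precedence
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer, so each window carries exactly one (the
#' strongest) label; the A1 condition is an adenosine in the UTR facing
#' miRNA position 1 regardless of pairing. Non-canonical sites are
#' 7-windows (miRNA 2-8) with exactly one G:U wobble or exactly one
#' mismatch and Watson-Crick pairs elsewhere. Overlapping sites are all
#' reported, for the same and for different miRNAs.
#'
#' @param utrs UTR sequences: a tibble with columns `name`, `seq`, a named
#'   character vector, or a single string (RNA alphabet; use
#'   [read_rna_fasta()] for files).
#' @param mirnas Mature miRNA sequences, same accepted forms.
#' @param config A [scan_config()].
#' @param region Optional 1-based inclusive interval `c(start, end)`;
#'   only sites whose footprint overlaps it are returned. The result is
#'   identical to a full scan filtered to that neighborhood.
#' @return A tibble of class `polymirts_sites` with one row per site:
#'   `utr_name`, `mirna_name`, `seed_start`/`seed_end` (1-based inclusive
#'   UTR interval pairing miRNA 2-8, or 2-7 for 7mer-A1/6mer), `site_type`,
#'   `wobble_count`, `mismatch_count`, `supplementary_score` (Watson-Crick
#'   pairs at miRNA 13-16), `footprint_start`/`footprint_end` (UTR bases
#'   facing the whole miRNA, truncated at UTR ends), `low_confidence`.
#'   Sorted by UTR name, seed start, miRNA name, site type.
#' @export
#' @examples
#' scan_sites(c(utr = "GGGGGCUACCUCAGGGGG"),
#'            c(`let-7a` = "UGAGGUAGUAGGUUGUAUAGUU"))
scan_sites <- function(utrs, mirnas, config = scan_config(), region = NULL) {
  utrs <- as_seq_tbl(utrs, "utr")
  mirnas <- as_seq_tbl(mirnas, "mirna")
  s_range <- NULL
  if (!is.null(region)) {
    region <- as.integer(region)
    # widest miRNA bounds the reach of a footprint past its core anchor
    max_m <- if (nrow(mirnas) > 0L) max(nchar(mirnas$seq)) else 8L
    s_range <- c(region[1] - 8L, region[2] + max_m)
  }
  out <- purrr::pmap_dfr(utrs, function(name, seq, ...) {
    utr_nm <- name; utr_seq <- seq
    purrr::pmap_dfr(mirnas, function(name, seq, ...) {
      scan_pair(utr_seq, utr_nm, seq, name, config, s_range = s_range)
    })
  })
  if (nrow(out) == 0L) out <- empty_sites()
  if (!is.null(region)) {
    out <- dplyr::filter(out, intervals_overlap(.data$footprint_start,
                                                .data$footprint_end,
                                                region[1], region[2]))
  }
  out <- dplyr::arrange(out, .data$utr_name, .data$seed_start,
                        .data$mirna_name, .data$site_type)
  class(out) <- c("polymirts_sites", class(tibble()))
  out
}

#' Count compensatory (3' supplementary) pairing for a predicted site
#'
#' Returns the number of Watson-Crick pairs between miRNA positions 13-16
#' and the facing UTR bases under the gapless antiparallel alignment
#' anchored at the site's seed; positions falling off the UTR (or a miRNA
#' shorter than 13 nt) contribute 0. This is the pairing of the mRNA
#' region 5' of the seed match -- the "compensatory" region where e.g. a
#' variant can sit without touching the seed.
#'
#' @param utr A single UTR sequence (string, named vector, or 1-row tibble).
#' @param site One row of a [scan_sites()] result for this UTR/miRNA pair.
#' @param mirna The matching miRNA sequence.
#' @return Integer in `[0, 4]`.
#' @export
supplementary_pairing <- function(utr, site, mirna) {
  utr <- as_seq_tbl(utr, "utr"); mirna <- as_seq_tbl(mirna, "mirna")
  if (nrow(utr) != 1L || nrow(mirna) != 1L || nrow(site) != 1L) {
    abort("supplementary_pairing() expects a single UTR, site and miRNA.",
          class = "polymirts_contract_error")
  }
  if (!identical(site$utr_name, utr$name) || !identical(site$mirna_name, mirna$name)) {
    abort("Site does not belong to the given UTR/miRNA pair.",
          class = "polymirts_contract_error")
  }
  s <- if (site$site_type %in% c("7mer-A1", "6mer")) site$seed_start else site$seed_start + 1L
  supplementary_count(chars(utr$seq), chars(mirna$seq), s)
}
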