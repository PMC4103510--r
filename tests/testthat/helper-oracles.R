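# Independent oracles used to cross-check the package implementation.
# Deliberately written with a different structure (per-base loops, explicit
# branch logic) than the vectorized production code.

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_rc <- function(x) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  b <- strsplit(x, "")[[1]]
  out <- character(length(b))
  for (i in seq_along(b)) out[i] <- comp[[b[length(b) - i + 1L]]]
  paste(out, collapse = "")
}

oracle_wc <- function(m, u) {
  (m == "A" && u == "U") || (m == "U" && u == "A") ||
    (m == "G" && u == "C") || (m == "C" && u == "G")
}
oracle_wobble <- function(m, u) {
  (m == "G" && u == "U") || (m == "U" && u == "G")
}

# Exhaustive per-offset site enumeration following the class definitions
# directly. Returns a data frame with the same columns as scan_sites().
oracle_scan <- function(utr_seq, utr_name, mirna_seq, mirna_name,
                        noncanonical = TRUE, emit_6mer = TRUE,
                        min_supplementary = 0L) {
  u <- strsplit(utr_seq, "")[[1]]
  m <- strsplit(mirna_seq, "")[[1]]
  L <- length(u); M <- length(m)
  empty <- data.frame(utr_name = character(), mirna_name = character(),
                      seed_start = integer(), seed_end = integer(),
                      site_type = character(), wobble_count = integer(),
                      mismatch_count = integer(), supplementary_score = integer(),
                      footprint_start = integer(), footprint_end = integer(),
                      low_confidence = logical(), stringsAsFactors = FALSE)
  rows <- list()
  if (L < 6L) return(empty)
  for (s in 1:(L - 5L)) {
    face <- function(i) {
      idx <- s + 7L - i
      if (idx >= 1L && idx <= L) u[idx] else NA_character_
    }
    cls <- character(7)
    for (i in 2:8) {
      ub <- face(i)
      cls[i - 1L] <- if (is.na(ub)) "absent"
        else if (oracle_wc(m[i], ub)) "W"
        else if (oracle_wobble(m[i], ub)) "O" else "M"
    }
    wc27 <- all(cls[1:6] == "W")
    wc28 <- wc27 && cls[7] == "W"
    t1 <- face(1L)
    t1A <- !is.na(t1) && t1 == "A"
    n_o <- sum(cls == "O"); n_m <- sum(cls == "M"); n_w <- sum(cls == "W")
    label <- NA_character_
    if (wc28) {
      label <- if (t1A) "8mer" else "7mer-m8"
    } else if (wc27) {
      label <- if (t1A) "7mer-A1" else "6mer"
    } else if (all(cls != "absent")) {
      if (n_o == 1L && n_m == 0L && n_w == 6L) label <- "noncanonical-wobble"
      if (n_m == 1L && n_o == 0L && n_w == 6L) label <- "noncanonical-mismatch"
    }
    if (is.na(label)) next
    if (!emit_6mer && label == "6mer") next
    if (!noncanonical && (label == "noncanonical-wobble" ||
                          label == "noncanonical-mismatch")) next
    supp <- 0L
    for (i in 13:16) {
      if (i > M) next
      ub <- face(i)
      if (!is.na(ub) && oracle_wc(m[i], ub)) supp <- supp + 1L
    }
    if (min_supplementary > 0L &&
        (label == "noncanonical-wobble" || label == "noncanonical-mismatch") &&
        supp < min_supplementary) next
    facing <- integer(0)
    for (i in 1:M) {
      idx <- s + 7L - i
      if (idx >= 1L && idx <= L) facing <- c(facing, idx)
    }
    seed_start <- if (label %in% c("7mer-A1", "6mer")) s else s - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      utr_name = utr_name, mirna_name = mirna_name,
      seed_start = as.integer(seed_start), seed_end = as.integer(s + 5L),
      site_type = label, wobble_count = as.integer(n_o),
      mismatch_count = as.integer(n_m), supplementary_score = supp,
      footprint_start = min(facing), footprint_end = max(facing),
      low_confidence = label == "6mer",
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0L) empty else do.call(rbind, rows)
  out[order(out$utr_name, out$seed_start, out$mirna_name, out$site_type), ,
      drop = FALSE]
}

# normalize a site table for comparison
site_df <- function(x) {
  x <- as.data.frame(x)[, c("utr_name", "mirna_name", "seed_start", "seed_end",
                            "site_type", "wobble_count", "mismatch_count",
                            "supplementary_score", "footprint_start",
                            "footprint_end", "low_confidence")]
  x <- x[order(x$utr_name, x$seed_start, x$mirna_name, x$site_type), ,
         drop = FALSE]
  rownames(x) <- NULL
  x
}

expect_same_sites <- function(got, want) {
  testthat::expect_equal(site_df(got), site_df(want))
}

# allele-effect oracle: full rescan of both alleles with the oracle scanner
oracle_allele_call <- function(utr_seq, utr_name, poly, mirna_seq, mirna_name) {
  ref_sites <- oracle_scan(utr_seq, utr_name, mirna_seq, mirna_name)
  ov <- ref_sites$footprint_start <= poly$end & poly$position <= ref_sites$footprint_end
  ref_sites <- ref_sites[ov, , drop = FALSE]
  a <- poly$position
  left <- substr(utr_seq, 1, a - 1)
  right <- substr(utr_seq, a + nchar(poly$ref), nchar(utr_seq))
  alt_seq <- paste0(left, poly$alt, right)
  if (poly$kind == "SNV") {
    lo <- a; hi <- a
  } else if (poly$kind == "deletion") {
    lo <- max(1, a - 1); hi <- min(nchar(alt_seq), a)
  } else {
    lo <- a; hi <- a + nchar(poly$alt) - 1
  }
  alt_sites <- oracle_scan(alt_seq, utr_name, mirna_seq, mirna_name)
  ov <- alt_sites$footprint_start <= hi & lo <= alt_sites$footprint_end
  alt_sites <- alt_sites[ov, , drop = FALSE]
  sig <- function(x) {
    o <- order(x$site_type, x$wobble_count, x$mismatch_count)
    paste(x$site_type[o], x$wobble_count[o], x$mismatch_count[o], collapse = ";")
  }
  if (nrow(ref_sites) > 0 && nrow(alt_sites) == 0) return("site_loss")
  if (nrow(ref_sites) == 0 && nrow(alt_sites) > 0) return("site_gain")
  if (nrow(ref_sites) == 0 && nrow(alt_sites) == 0) return("unchanged")
  if (identical(sig(ref_sites), sig(alt_sites))) "unchanged" else "type_change"
}
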