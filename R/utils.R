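# RNA alphabet helpers shared across the scanner and the generators.
# The package works internally on RNA (A/C/G/U); DNA input is mapped on read.

RNA_BASES <- c("A", "C", "G", "U")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# pair_class codes: 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch.
PAIR_CLASS <- local({
  m <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- 2L
  m["G", "U"] <- m["U", "G"] <- 1L
  m
})

check_rna <- function(x, what = "sequence") {
  bad <- stringr::str_locate(x, "[^ACGU]")[, "start"]
  if (!is.na(bad)) {
    abort(
      sprintf(
        "Invalid character '%s' at position %d of %s (RNA alphabet A/C/G/U expected).",
        substr(x, bad, bad), bad, what
      ),
      class = "polymirts_alphabet_error"
    )
  }
  invisible(x)
}

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and maps T to U. Any character outside A/C/G/U after
#' normalization raises an alphabet error naming the offending position.
#'
#' @param x Character vector of nucleotide strings (DNA or RNA).
#' @param what Label used in error messages.
#' @return Character vector over the A/C/G/U alphabet.
#' @export
#' @examples
#' normalize_rna("ggctACCT")
normalize_rna <- function(x, what = "sequence") {
  out <- chartr("Tt", "Uu", toupper(x))
  out <- toupper(out)
  for (i in seq_along(out)) {
    lab <- if (length(out) > 1L) sprintf("%s [%d]", what, i) else what
    check_rna(out[i], lab)
  }
  out
}

#' Reverse complement of an RNA string
#'
#' Antiparallel Watson-Crick complement; an involution
#' (`reverse_complement(reverse_complement(x)) == x`).
#'
#' @param x Character vector of RNA strings (A/C/G/U).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("GAGGUAG")
reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    check_rna(s)
    stringr::str_c(rev(RNA_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify the pairing of one miRNA base against one UTR base
#'
#' Watson-Crick pairs are A:U, U:A, G:C, C:G; G:U and U:G are wobble
#' pairs; everything else is a mismatch.
#'
#' @param b_mirna,b_utr Single RNA bases.
#' @return One of `"watson_crick"`, `"wobble"`, `"mismatch"`.
#' @export
#' @examples
#' pair_type("G", "U")
pair_type <- function(b_mirna, b_utr) {
  check_rna(b_mirna, "miRNA base")
  check_rna(b_utr, "UTR base")
  c("mismatch", "wobble", "watson_crick")[PAIR_CLASS[b_mirna, b_utr] + 1L]
}

# 1-based inclusive interval overlap (any-overlap rule).
intervals_overlap <- function(a1, a2, b1, b2) {
  a1 <= b2 & b1 <= a2
}

# strsplit to a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
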