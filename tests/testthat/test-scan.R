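LET7 <- c(`let-7a` = "UGAGGUAGUAGGUUGUAUAGUU")

test_that("reverse_complement is the Watson-Crick involution", {
  expect_equal(reverse_complement("GAGGUAG"), "CUACCUC")
  expect_equal(reverse_complement(""), "")
  expect_error(reverse_complement("ACGT"), class = "polymirts_alphabet_error")
  set.seed(11)
  for (i in 1:25) {
    x <- random_rna(sample(1:60, 1))
    expect_equal(reverse_complement(reverse_complement(x)), x)
    expect_equal(reverse_complement(x), oracle_rc(x))
  }
})

test_that("pair_type follows the Watson-Crick / wobble / mismatch table", {
  expect_equal(pair_type("G", "C"), "watson_crick")
  expect_equal(pair_type("G", "U"), "wobble")
  expect_equal(pair_type("U", "G"), "wobble")
  expect_equal(pair_type("A", "G"), "mismatch")
  for (m in c("A", "C", "G", "U")) for (u in c("A", "C", "G", "U")) {
    expect_equal(pair_type(m, u) == "watson_crick",
                 oracle_wc(m, u))
    expect_equal(pair_type(m, u) == "wobble", oracle_wobble(m, u))
  }
})

test_that("an implanted perfect seed match is called as an 8mer", {
  out <- scan_sites(c(utr = "GGGGGCUACCUCAGGGGG"), LET7)
  expect_equal(nrow(out), 1L)
  expect_equal(out$site_type, "8mer")
  expect_equal(c(out$seed_start, out$seed_end), c(6L, 12L))
  expect_equal(out$footprint_end, 13L)  # the A1 adenosine at position 13
  expect_equal(out$wobble_count + out$mismatch_count, 0L)
})

test_that("a single seed edit produces the expected non-canonical site", {
  out <- scan_sites(c(utr = "GGGGGCUACUUCAGGGGG"), LET7)
  expect_equal(nrow(out), 1L)
  expect_equal(out$site_type, "noncanonical-wobble")
  expect_equal(out$wobble_count, 1L)  # G:U at miRNA position 4
  expect_equal(c(out$seed_start, out$seed_end), c(6L, 12L))
})

test_that("scanner output equals exhaustive brute-force enumeration", {
  set.seed(42)
  mirnas <- tibble::tibble(
    name = sprintf("mir%02d", 1:5),
    seq = vapply(1:5, function(i) random_rna(22), character(1))
  )
  for (rep in 1:12) {
    utr <- random_rna(sample(80:160, 1), gc = sample(c(0.35, 0.5, 0.65), 1))
    got <- scan_sites(c(u = utr), mirnas)
    want <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i) {
      oracle_scan(utr, "u", mirnas$seq[i], mirnas$name[i])
    }))
    expect_same_sites(got, want)
  }
})

test_that("scanner config filters match the oracle's filters", {
  set.seed(43)
  utr <- random_rna(300)
  mir <- random_rna(22)
  for (nc in c(TRUE, FALSE)) for (e6 in c(TRUE, FALSE)) for (ms in c(0L, 2L)) {
    got <- scan_sites(c(u = utr), c(m1 = mir),
                      scan_config(noncanonical = nc, emit_6mer = e6,
                                  min_supplementary = ms))
    want <- oracle_scan(utr, "u", mir, "m1", noncanonical = nc,
                        emit_6mer = e6, min_supplementary = ms)
    expect_same_sites(got, want)
  }
})

test_that("canonical precedence: weakening an 8mer's A1 base yields a 7mer-m8", {
  utr <- "GGGGGCUACCUCAGGGGG"
  out8 <- scan_sites(c(u = utr), LET7)
  substr(utr, 13, 13) <- "G"
  out7 <- scan_sites(c(u = utr), LET7)
  expect_equal(out8$site_type, "8mer")
  expect_equal(out7$site_type, "7mer-m8")
  expect_equal(out7$seed_start, out8$seed_start)
  expect_equal(out7$seed_end, out8$seed_end)
  # no window ever receives two labels
  set.seed(44)
  for (i in 1:10) {
    sites <- scan_sites(c(u = random_rna(250)), LET7)
    expect_false(any(duplicated(sites[, c("mirna_name", "seed_end")])))
  }
})

test_that("disabling non-canonical sites yields a subset of the enabled run", {
  set.seed(45)
  for (i in 1:10) {
    utr <- c(u = random_rna(200))
    all_sites <- scan_sites(utr, LET7, scan_config(noncanonical = TRUE))
    canon <- scan_sites(utr, LET7, scan_config(noncanonical = FALSE))
    key <- function(x) paste(x$seed_start, x$seed_end, x$site_type)
    expect_true(all(key(canon) %in% key(all_sites)))
  }
})

test_that("prepending bases shifts interior site intervals by exactly k", {
  set.seed(46)
  for (i in 1:8) {
    utr <- random_rna(200)
    k <- sample(3:40, 1)
    before <- scan_sites(c(u = utr), LET7)
    # interior sites: footprint and compensatory region fully on the UTR
    before <- dplyr::filter(before, footprint_start > 1, seed_start > 12)
    after <- scan_sites(c(u = paste0(strrep("G", k), utr)), LET7)
    for (j in seq_len(nrow(before))) {
      hit <- dplyr::filter(after,
                           seed_start == before$seed_start[j] + k,
                           seed_end == before$seed_end[j] + k,
                           site_type == before$site_type[j])
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$supplementary_score, before$supplementary_score[j])
      expect_equal(hit$footprint_start, before$footprint_start[j] + k)
    }
  }
})

test_that("supplementary pairing counts Watson-Crick pairs at miRNA 13-16", {
  # implant a perfect seed match preceded by the exact complement of 13-16
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  mb <- strsplit(m, "")[[1]]
  comp1316 <- reverse_complement(paste(mb[13:16], collapse = ""))
  utr <- paste0("GGGG", "CC", comp1316, "CCCC", "CUACCUC", "A", "GGGG")
  sites <- scan_sites(c(u = utr), c(m1 = m))
  site <- dplyr::filter(sites, site_type == "8mer")
  expect_equal(site$supplementary_score, 4L)
  expect_equal(supplementary_pairing(c(u = utr), site, c(m1 = m)), 4L)

  # a site flush against the UTR start has no upstream bases to pair
  utr2 <- paste0("CUACCUC", "A", "GGGGGG")
  s2 <- scan_sites(c(u = utr2), c(m1 = m))
  s2 <- dplyr::filter(s2, seed_start == 1L)
  expect_equal(s2$supplementary_score, 0L)

  expect_error(supplementary_pairing(c(u = utr), site, c(other = m)),
               class = "polymirts_contract_error")
})

test_that("UTRs shorter than the seed core return an empty result", {
  expect_equal(nrow(scan_sites(c(u = "ACGUA"), LET7)), 0L)
})

test_that("site plots and autoplot build without error", {
  sites <- scan_sites(c(u = "GGGGGCUACCUCAGGGGG"), LET7)
  p <- plot_sites(sites, utr_length = 18)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(sites), "ggplot")
})
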