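LET7 <- c(`let-7a` = "UGAGGUAGUAGGUUGUAUAGUU")

# one implanted 8mer for let-7a with a fully paired compensatory region
make_utr <- function() {
  comp1316 <- reverse_complement(substr(unname(LET7), 13, 16))
  paste0(strrep("G", 20), "CC", comp1316, "CCCC", "CUACCUC", "A", strrep("G", 20))
}

test_that("classify_overlap distinguishes seed, compensatory and distant hits", {
  utr <- c(u = make_utr())
  site <- dplyr::filter(scan_sites(utr, LET7), site_type == "8mer")
  seed_del <- polymorphism_table("del1", site$seed_start + 1L, "UA", "",
                                 utr_name = "u")
  expect_equal(classify_overlap(seed_del, site), "Y")

  comp_snv <- polymorphism_table("snv1", site$seed_start - 7L, "C", "A",
                                 utr_name = "u")
  expect_equal(classify_overlap(comp_snv, site), "N")

  far_snv <- polymorphism_table("snv2", 2L, "G", "A", utr_name = "u")
  expect_equal(classify_overlap(far_snv, site, flank = 0L), "none")
  # with a large flank the distant variant becomes "near"
  expect_equal(classify_overlap(far_snv, site, flank = 50L), "N")

  other <- polymorphism_table("snv3", 5L, "G", "A", utr_name = "other_utr")
  expect_error(classify_overlap(other, site), class = "polymirts_contract_error")
})

test_that("classify_overlap is invariant under a coordinate shift of the system", {
  utr <- make_utr()
  site <- dplyr::filter(scan_sites(c(u = utr), LET7), site_type == "8mer")
  k <- 17L
  shifted_site <- dplyr::filter(scan_sites(c(u = paste0(strrep("A", k), utr)), LET7),
                                site_type == "8mer")
  for (pos in c(site$seed_start, site$seed_start - 7L, 3L)) {
    p <- polymorphism_table("v", pos, substr(utr, pos, pos),
                            setdiff(c("A", "C", "G", "U"), substr(utr, pos, pos))[1],
                            utr_name = "u")
    ps <- polymorphism_table("v", pos + k, p$ref, p$alt, utr_name = "u")
    expect_equal(classify_overlap(p, site), classify_overlap(ps, shifted_site))
  }
})

test_that("apply_allele substitutes, deletes and verifies the reference", {
  utr <- c(u = strrep("ACGU", 150))  # 600 nt
  snv <- polymorphism_table("s", 10L, substr(utr[[1]], 10, 10), "A",
                            utr_name = "u")
  out <- apply_allele(utr, snv)
  expect_equal(nchar(out$seq), 600L)
  expect_equal(substr(out$seq, 10, 10), "A")
  expect_equal(out$map, 1:600)  # identity map for an SNV

  del <- polymorphism_table("rs_del", 515L, "CA", "", utr_name = "u")
  utr2 <- c(u = paste0(substr(utr[[1]], 1, 514), "CA", substr(utr[[1]], 517, 600)))
  out2 <- apply_allele(utr2, del)
  expect_equal(nchar(out2$seq), 598L)      # two bases removed
  expect_equal(out2$map[[517]], 515L)      # downstream bases shift left by 2
  expect_true(all(is.na(out2$map[515:516])))

  bad <- polymorphism_table("b", 515L, "GG", "", utr_name = "u")
  err <- expect_error(apply_allele(utr2, bad), class = "polymirts_reference_error")
  expect_match(conditionMessage(err), "515")
  expect_match(conditionMessage(err), "GG")
})

test_that("applying an allele and its inverse restores sequence and sites", {
  utr <- c(u = make_utr())
  ref25 <- substr(utr[[1]], 25, 25)
  polys <- dplyr::bind_rows(
    polymorphism_table("snv", 25L, ref25,
                       setdiff(c("A", "C", "G", "U"), ref25)[1], utr_name = "u"),
    polymorphism_table("del", 30L, substr(utr[[1]], 30, 31), "", utr_name = "u")
  )
  for (i in seq_len(nrow(polys))) {
    fwd <- apply_allele(utr, polys[i, ])
    back <- apply_allele(c(u = fwd$seq), fwd$inverse)
    expect_equal(back$seq, utr[[1]])
    expect_same_sites(scan_sites(c(u = back$seq), LET7), scan_sites(utr, LET7))
  }
})

test_that("a deletion inside a perfect seed match is called site_loss", {
  utr <- c(u = make_utr())
  site <- dplyr::filter(scan_sites(utr, LET7), site_type == "8mer")
  del <- polymorphism_table(
    "del", site$seed_start + 2L,
    substr(utr[[1]], site$seed_start + 2L, site$seed_start + 3L), "",
    utr_name = "u")
  eff <- allele_effect(utr, del, LET7)
  expect_equal(eff$call, "site_loss")
  expect_gt(eff$n_ref_sites, 0L)
  expect_equal(eff$n_alt_sites, 0L)
})

test_that("an SNV turning a seed G:C pair into G:U is a type change", {
  utr <- c(u = "GGGGGCUACCUCAGGGGG")
  snv <- polymorphism_table("s", 10L, "C", "U", utr_name = "u")
  eff <- allele_effect(utr, snv, LET7)
  expect_equal(eff$call, "type_change")
  expect_equal(eff$ref_sites[[1]]$site_type, "8mer")
  expect_equal(eff$alt_sites[[1]]$site_type, "noncanonical-wobble")
})

test_that("allele_effect agrees with a brute-force full rescan of both alleles", {
  set.seed(77)
  n_checked <- 0L
  for (i in 1:40) {
    utr_seq <- random_rna(150)
    mir <- random_rna(22)
    pos <- sample(5:140, 1)
    if (sample(c(TRUE, FALSE), 1)) {
      ref <- substr(utr_seq, pos, pos)
      poly <- polymorphism_table("v", pos, ref,
                                 sample(setdiff(c("A", "C", "G", "U"), ref), 1),
                                 utr_name = "u")
    } else {
      poly <- polymorphism_table("v", pos, substr(utr_seq, pos, pos + 1), "",
                                 utr_name = "u")
    }
    eff <- allele_effect(c(u = utr_seq), poly, c(m1 = mir))
    expect_equal(eff$call,
                 oracle_allele_call(utr_seq, "u", poly, mir, "m1"))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 40L)
})

test_that("the windowed rescan equals the full rescan on the neighborhood", {
  set.seed(78)
  for (i in 1:10) {
    utr_seq <- random_rna(400)
    mir <- random_rna(22)
    pos <- sample(30:370, 1)
    poly <- polymorphism_table("v", pos, substr(utr_seq, pos, pos + 1), "",
                               utr_name = "u")
    eff <- allele_effect(c(u = utr_seq), poly, c(m1 = mir))
    full_ref <- scan_sites(c(u = utr_seq), c(m1 = mir))
    full_ref <- dplyr::filter(full_ref, footprint_start <= poly$end,
                              footprint_end >= poly$position)
    expect_same_sites(eff$ref_sites[[1]], full_ref)

    alt <- apply_allele(c(u = utr_seq), poly)
    full_alt <- scan_sites(c(u = alt$seq), c(m1 = mir))
    lo <- max(1L, pos - 1L); hi <- min(nchar(alt$seq), pos)
    full_alt <- dplyr::filter(full_alt, footprint_start <= hi,
                              footprint_end >= lo)
    expect_same_sites(eff$alt_sites[[1]], full_alt)
  }
})

test_that("annotate produces one flagged record per (variant, miRNA) pair", {
  utr <- c(u = make_utr())
  site <- dplyr::filter(scan_sites(utr, LET7), site_type == "8mer")
  polys <- dplyr::bind_rows(
    polymorphism_table("seed_snv", site$seed_start + 1L,
                       substr(utr[[1]], site$seed_start + 1L, site$seed_start + 1L),
                       "G", utr_name = "u"),
    polymorphism_table("far_snv", 2L, "G", "A", utr_name = "u")
  )
  expr <- tibble::tibble(mirna_name = "let-7a", raw_reads = 99L)
  recs <- annotate_polymirts(utr, polys, LET7, expr)
  expect_equal(nrow(recs), 1L)  # the distant variant is dropped
  expect_equal(recs$seed_region, "Y")
  expect_equal(recs$raw_reads, 99L)
  # absent miRNA in the expression table joins as 0 reads
  recs0 <- annotate_polymirts(utr, polys, LET7,
                              tibble::tibble(mirna_name = "other", raw_reads = 5L))
  expect_equal(recs0$raw_reads, 0L)
  # empty variant list gives an empty record table
  expect_equal(nrow(annotate_polymirts(utr, polys[0, ], LET7, expr)), 0L)
})

test_that("flag Y records always intersect a seed interval (re-checked)", {
  spec <- simulation_spec(seed = 5)
  sim <- simulate_utr(spec)
  polys <- simulate_variants(sim, spec)
  mirnas <- tibble::tibble(name = names(spec$mirnas), seq = unname(spec$mirnas))
  recs <- annotate_polymirts(sim$utr[, c("name", "seq")], polys, mirnas)
  sites <- scan_sites(sim$utr[, c("name", "seq")], mirnas)
  for (i in seq_len(nrow(recs))) {
    if (recs$seed_region[i] != "Y") next
    hits <- dplyr::filter(sites, mirna_name == recs$mirna_name[i],
                          seed_start <= recs$end[i], seed_end >= recs$position[i])
    expect_gt(nrow(hits), 0L)
  }
})
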