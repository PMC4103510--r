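test_that("generators are fully deterministic under spec + seed", {
  spec <- simulation_spec(seed = 12)
  a <- simulate_utr(spec); b <- simulate_utr(spec)
  expect_identical(a$utr$seq, b$utr$seq)
  expect_identical(as.data.frame(a$sites), as.data.frame(b$sites))
  expect_identical(simulate_variants(a, spec), simulate_variants(b, spec))
  expect_identical(simulate_expression(spec), simulate_expression(spec))
  expect_identical(simulate_reporter(spec), simulate_reporter(spec))
  expect_identical(simulate_genotypes(spec), simulate_genotypes(spec))
  # a different seed changes the background
  expect_false(identical(simulate_utr(simulation_spec(seed = 13))$utr$seq,
                         a$utr$seq))
})

test_that("implanted sites are recovered exactly, with no accidental canonical sites", {
  for (seed in 1:10) {
    spec <- simulation_spec(seed = seed)
    sim <- simulate_utr(spec)
    mirnas <- tibble::tibble(name = names(spec$mirnas), seq = unname(spec$mirnas))
    found <- scan_sites(sim$utr[, c("name", "seq")], mirnas,
                        scan_config(noncanonical = FALSE))
    expect_equal(nrow(found), nrow(spec$implants))
    key <- paste(found$mirna_name, found$seed_start, found$site_type)
    want <- paste(spec$implants$mirna_name, spec$implants$position,
                  spec$implants$site_type)
    expect_setequal(key, want)
  }
})

test_that("all six implantable site classes scan back as constructed", {
  types <- c("8mer", "7mer-m8", "7mer-A1", "6mer",
             "noncanonical-wobble", "noncanonical-mismatch")
  for (ty in types) {
    spec <- simulation_spec(
      seed = 8, utr_length = 200,
      mirnas = c(m1 = "UGAGGUAGUAGGUUGUAUAGUU"),
      implants = tibble::tibble(mirna_name = "m1", site_type = ty,
                                position = 90L),
      variants = tibble::tibble(snp_id = character(), placement = character(),
                                kind = character(), target = character(),
                                del_length = integer())
    )
    sim <- simulate_utr(spec)
    hit <- dplyr::filter(sim$sites, implant == 1L)
    expect_equal(hit$site_type, ty)
    expect_equal(hit$seed_start, 90L)
  }
})

test_that("infeasible implant layouts raise spec errors", {
  expect_error(
    simulate_utr(simulation_spec(
      seed = 1, utr_length = 50,
      implants = tibble::tibble(mirna_name = "syn-miR-1", site_type = "8mer",
                                position = 48L))),
    class = "polymirts_spec_error")
  expect_error(
    simulate_utr(simulation_spec(
      seed = 1,
      implants = tibble::tibble(mirna_name = c("syn-miR-1", "syn-miR-2"),
                                site_type = c("8mer", "8mer"),
                                position = c(100L, 103L)))),
    class = "polymirts_spec_error")
})

test_that("variant placements verify against the annotator", {
  for (seed in 1:5) {
    spec <- simulation_spec(seed = seed)
    sim <- simulate_utr(spec)
    vars <- simulate_variants(sim, spec)
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      if (v$placement == "outside") next
      site <- sim$sites[sim$sites$mirna_name == v$target, ]
      expect_equal(classify_overlap(v, site[, !names(site) %in% "implant"]),
                   if (v$placement == "seed") "Y" else "N")
      if (v$placement == "seed" && v$kind == "deletion") {
        eff <- allele_effect(sim$utr[, c("name", "seq")], v,
                             stats::setNames(spec$mirnas[v$target], v$target))
        expect_equal(eff$call, "site_loss")
      }
    }
  }
})

test_that("simulate_study redraws layouts until every truth label verifies", {
  # seed 175 draws a background whose in-seed deletion junction recreates a
  # weak site for every placement; the joint generator must still succeed
  spec <- simulation_spec(seed = 175)
  expect_error(simulate_variants(simulate_utr(spec), spec),
               class = "polymirts_spec_error")
  study <- simulate_study(spec)
  del <- study$variants[study$variants$kind == "deletion", ]
  eff <- allele_effect(study$sim$utr[, c("name", "seq")], del,
                       stats::setNames(study$spec$mirnas[del$target], del$target))
  expect_equal(eff$call, "site_loss")
  expect_identical(simulate_study(spec)$sim$utr$seq, study$sim$utr$seq)
})

test_that("expression draws follow the negative-binomial spec", {
  zero <- simulation_spec(seed = 2, expression = tibble::tibble(
    mirna_name = "m", mean = 0, dispersion = 0.3))
  expect_equal(simulate_expression(zero, n = 50)$raw_reads, rep(0L, 50))

  spec <- simulation_spec(seed = 2, expression = tibble::tibble(
    mirna_name = c("hi", "lo"), mean = c(500, 40), dispersion = c(0.2, 0.2)))
  draws <- simulate_expression(spec, n = 10000)
  for (nm in c("hi", "lo")) {
    x <- draws$raw_reads[draws$mirna_name == nm]
    mu <- spec$expression$mean[spec$expression$mirna_name == nm]
    disp <- 0.2
    se <- sqrt((mu + disp * mu^2) / length(x))
    expect_lt(abs(mean(x) - mu), 3 * se)
  }
  # dispersion -> 0 concentrates at the mean (Poisson limit)
  tight <- simulation_spec(seed = 2, expression = tibble::tibble(
    mirna_name = "m", mean = 400, dispersion = 0))
  x <- simulate_expression(tight, n = 5000)$raw_reads
  expect_lt(stats::var(x) / mean(x), 1.1)  # index of dispersion near 1
})

test_that("reporter truth behaves as specified at the noise extremes", {
  spec0 <- simulation_spec(seed = 4, sigma = 0)
  rel <- relative_luciferase(simulate_reporter(spec0))
  for (m in names(spec0$repression)) {
    expect_equal(unique(round(rel$relative[rel$mirna == m], 12)),
                 unname(spec0$repression[m]))
  }
  # r = 1 is indistinguishable from the control in expectation
  spec1 <- simulation_spec(seed = 4, sigma = 0,
                           repression = c(`syn-miR-1` = 1, `syn-miR-2` = 1,
                                          `syn-miR-3` = 1))
  rel1 <- relative_luciferase(simulate_reporter(spec1))
  expect_equal(rel1$relative, rep(1, nrow(rel1)))
  # attenuation moves the expectation back toward 1
  spec2 <- simulation_spec(
    seed = 4, sigma = 0,
    constructs = tibble::tibble(construct = c("WT", "MUT"),
                                mirna = "syn-miR-1",
                                attenuation = c(0, 0.6)))
  rel2 <- relative_luciferase(simulate_reporter(spec2))
  m1 <- rel2[rel2$mirna == "syn-miR-1", ]
  expect_equal(unique(round(m1$relative[m1$construct == "WT"], 12)), 0.5)
  expect_equal(unique(round(m1$relative[m1$construct == "MUT"], 12)),
               0.5 + 0.6 * 0.5)
})

test_that("genotype simulation is exact-count and errors on empty cohorts", {
  spec <- simulation_spec(seed = 6, cohort = list(
    ad_total = 20L, ad_carriers = 3L, control_total = 10L, control_carriers = 1L))
  geno <- simulate_genotypes(spec)
  counts <- carrier_counts(geno)
  expect_equal(counts$carriers, c(3L, 1L))
  expect_equal(counts$total, c(20L, 10L))
  expect_error(simulate_genotypes(simulation_spec(cohort = list(
    ad_total = 0L, ad_carriers = 0L, control_total = 0L, control_carriers = 0L))),
    class = "polymirts_spec_error")
  expect_error(simulate_genotypes(simulation_spec(cohort = list(
    ad_total = 5L, ad_carriers = 6L, control_total = 5L, control_carriers = 0L))),
    class = "polymirts_spec_error")
})

test_that("simulate_inputs writes files the readers round-trip", {
  spec <- simulation_spec(seed = 10)
  td <- withr::local_tempdir()
  paths <- simulate_inputs(spec, td)
  objs <- attr(paths, "objects")

  utr <- read_rna_fasta(paths$utr)
  expect_equal(utr$seq, objs$sim$utr$seq)
  mir <- read_mirna_fasta(paths$mirnas)
  expect_equal(stats::setNames(mir$seq, mir$name), spec$mirnas)

  vt <- read_variant_table(paths$variants, "tsv")
  vv <- read_variant_table(paths$variants_vcf, "vcf_lite")
  cols <- c("snp_id", "position", "end", "ref", "alt", "kind")
  expect_equal(as.data.frame(vt[, cols]), as.data.frame(vv[, cols]))
  expect_equal(as.data.frame(vt[, cols]),
               as.data.frame(objs$variants[, cols]))

  expr <- read_expression_table(paths$expression)
  expect_equal(expr$raw_reads, objs$expression$raw_reads)
})
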