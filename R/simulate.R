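# Seeded generators for every input the pipeline consumes, with exact
# ground-truth labels. Sites are implanted (written into the sequence) and
# the background is rejection-resampled until no accidental canonical site
# exists for any listed miRNA outside the implants, so truth is exact by
# construction rather than inferred post hoc.

# run expr under a temporary RNG state (restores the caller's stream)
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fixed synthetic mature miRNAs (22 nt); names mark them as synthetic
SYNTH_MIRNAS <- c(
  "syn-miR-1" = "UGAGGUAGUAGGUUGUAUAGUU",
  "syn-miR-2" = "UAGCACCAUUUGAAAUCGGUUA",
  "syn-miR-3" = "ACUGCAUCAGGAACUGAUUGGA"
)

#' Build a simulation specification
#'
#' Bundles every knob of the synthetic-data generators, with defaults
#' emulating the study conditions: a ~700-nt 3'UTR carrying implanted
#' target sites for three miRNAs, the three validated variant archetypes
#' (a seed deletion, a seed SNV and a compensatory-region SNV),
#' negative-binomial expression counts, a dual-luciferase experiment of 3
#' independent experiments in triplicate (n = 9 wells per condition) with
#' multiplicative lognormal noise, and a case/control cohort with fixed
#' carrier counts (1/511 cases, 0/631 controls).
#'
#' @param seed Integer RNG seed; identical spec + seed give byte-identical
#'   outputs.
#' @param utr_name,utr_length,gc_content Background sequence model
#'   (i.i.d. bases at the stated GC content).
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param implants Tibble `mirna_name`, `site_type`, `position`
#'   (1-based seed start of the implanted site). Implants must not overlap.
#' @param variants Tibble `snp_id`, `placement`
#'   (`"seed"`/`"compensatory"`/`"outside"`), `kind` (`"SNV"`/`"deletion"`),
#'   `target` (implant miRNA the placement refers to; ignored for
#'   `"outside"`), `del_length` (deletion length, default 2).
#' @param expression Tibble `mirna_name`, `mean`, `dispersion`
#'   (negative-binomial; variance `mean + dispersion * mean^2`).
#' @param repression Named vector of true repression factors r (expected
#'   relative activity of a targeting miRNA on the wild-type construct).
#' @param constructs Tibble `construct`, `mirna`, `attenuation`: the
#'   fraction by which the variant allele moves the expectation from r
#'   back toward 1 (0 = unaffected, 1 = repression fully abolished).
#' @param sigma Lognormal noise SD on the firefly/renilla ratio.
#' @param n_experiments,replicates Experiments and wells per condition per
#'   experiment.
#' @param cohort List with `ad_total`, `ad_carriers`, `control_total`,
#'   `control_carriers`.
#' @param scan_config Scanner configuration used for closed-loop
#'   verification of the generated truth labels.
#' @return A list of class `polymirts_sim_spec`.
#' @export
simulation_spec <- function(
    seed = 1L,
    utr_name = "synthetic_utr",
    utr_length = 700L,
    gc_content = 0.5,
    mirnas = SYNTH_MIRNAS,
    implants = tibble(
      mirna_name = names(SYNTH_MIRNAS),
      site_type = c("8mer", "7mer-m8", "8mer"),
      position = c(120L, 350L, 560L)
    ),
    variants = tibble(
      snp_id = c("sim_del_seed", "sim_snv_seed", "sim_snv_comp"),
      placement = c("seed", "seed", "compensatory"),
      kind = c("deletion", "SNV", "SNV"),
      target = names(SYNTH_MIRNAS),
      del_length = c(2L, NA, NA)
    ),
    expression = tibble(
      mirna_name = names(SYNTH_MIRNAS),
      mean = c(1200, 100, 45),
      dispersion = c(0.2, 0.2, 0.2)
    ),
    repression = setNames(rep(0.5, length(SYNTH_MIRNAS)), names(SYNTH_MIRNAS)),
    constructs = tibble(construct = "WT",
                        mirna = names(SYNTH_MIRNAS),
                        attenuation = 0),
    sigma = 0.1,
    n_experiments = 3L,
    replicates = 3L,
    cohort = list(ad_total = 511L, ad_carriers = 1L,
                  control_total = 631L, control_carriers = 0L),
    scan_config = polymirts::scan_config()) {
  force(scan_config)
  spec <- list(
    seed = as.integer(seed), utr_name = utr_name,
    utr_length = as.integer(utr_length), gc_content = gc_content,
    mirnas = vapply(mirnas, normalize_rna, character(1)),
    implants = implants, variants = variants, expression = expression,
    repression = repression, constructs = constructs, sigma = sigma,
    n_experiments = as.integer(n_experiments),
    replicates = as.integer(replicates),
    cohort = cohort, scan_config = scan_config
  )
  if (spec$replicates < 2L || spec$n_experiments < 1L) {
    abort("Need at least 2 replicates and 1 experiment.",
          class = "polymirts_spec_error")
  }
  if (nrow(implants) > 0L) {
    bad <- setdiff(implants$mirna_name, names(spec$mirnas))
    if (length(bad) > 0L) {
      abort(sprintf("Implants name unknown miRNAs: %s", paste(bad, collapse = ", ")),
            class = "polymirts_spec_error")
    }
  }
  structure(spec, class = "polymirts_sim_spec")
}

# the written segment for one implant; returns list(start, bases)
implant_segment <- function(mirna_seq, site_type, position) {
  m <- chars(mirna_seq)
  rc28 <- reverse_complement(paste(m[2:8], collapse = ""))   # pairs miRNA 8..2
  rc27 <- reverse_complement(paste(m[2:7], collapse = ""))
  non_a <- "C"
  # a base that neither Watson-Crick- nor wobble-pairs m[8]
  mism8 <- setdiff(RNA_BASES, names(which(PAIR_CLASS[m[8], ] > 0L)))[1]
  switch(site_type,
    "8mer" = list(start = position, bases = chars(paste0(rc28, "A"))),
    "7mer-m8" = list(start = position, bases = chars(paste0(rc28, non_a))),
    "7mer-A1" = list(start = position - 1L,
                     bases = chars(paste0(mism8, rc27, "A"))),
    "6mer" = list(start = position - 1L,
                  bases = chars(paste0(mism8, rc27, non_a))),
    "noncanonical-wobble" = {
      # introduce one G:U wobble at a miRNA position in 2..7 (position 8
      # would be re-labelled canonical by precedence)
      cand <- which(m[2:7] %in% c("G", "U")) + 1L
      if (length(cand) == 0L) {
        abort("miRNA seed has no wobble-capable base at positions 2-7.",
              class = "polymirts_spec_error")
      }
      i <- cand[1]
      seg <- chars(rc28)
      idx <- 9L - i  # utr offset within rc28 (1-based) facing miRNA position i
      seg[idx] <- if (m[i] == "G") "U" else "G"
      list(start = position, bases = c(seg, non_a))
    },
    "noncanonical-mismatch" = {
      i <- 3L  # any seed position in 2..7 works
      seg <- chars(rc28)
      idx <- 9L - i
      seg[idx] <- setdiff(RNA_BASES, names(which(PAIR_CLASS[m[i], ] > 0L)))[1]
      list(start = position, bases = c(seg, non_a))
    },
    abort(sprintf("Unknown site type '%s'.", site_type),
          class = "polymirts_spec_error")
  )
}

#' Simulate a 3'UTR with implanted miRNA target sites
#'
#' Background bases are i.i.d. at the spec's GC content; implanted windows
#' are exact type-conforming matches. The background is resampled until
#' the scanner finds no canonical site (of any class) for a listed miRNA
#' outside the implants, so the returned truth is exact.
#'
#' @param spec A [simulation_spec()].
#' @param max_tries Resampling attempts before giving up.
#' @return A list with `utr` (tibble `name`, `seq`, `length`) and `sites`
#'   (the implanted sites as found by [scan_sites()], plus an `implant`
#'   index column).
#' @export
simulate_utr <- function(spec, max_tries = 200L) {
  L <- spec$utr_length
  implants <- spec$implants
  segs <- NULL
  if (nrow(implants) > 0L) {
    segs <- purrr::pmap(implants, function(mirna_name, site_type, position, ...) {
      seg <- implant_segment(spec$mirnas[[mirna_name]], site_type, position)
      if (seg$start < 1L || seg$start + length(seg$bases) - 1L > L) {
        abort(sprintf("Implant for %s at position %d does not fit in a %d-nt UTR.",
                      mirna_name, position, L),
              class = "polymirts_spec_error")
      }
      seg
    })
    iv <- purrr::map_dfr(segs, ~ tibble(start = .x$start,
                                        end = .x$start + length(.x$bases) - 1L))
    iv <- dplyr::arrange(iv, .data$start)
    if (nrow(iv) > 1L && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      abort("Implants overlap; adjust their positions.",
            class = "polymirts_spec_error")
    }
  }
  p <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
         G = spec$gc_content / 2, U = (1 - spec$gc_content) / 2)
  canon_cfg <- scan_config(noncanonical = FALSE, emit_6mer = TRUE)
  mirna_tbl <- tibble(name = names(spec$mirnas), seq = unname(spec$mirnas))

  with_seed(spec$seed, {
    for (try in seq_len(max_tries)) {
      bases <- sample(RNA_BASES, L, replace = TRUE, prob = p)
      for (seg in segs %||% list()) {
        bases[seg$start:(seg$start + length(seg$bases) - 1L)] <- seg$bases
      }
      utr <- tibble(name = spec$utr_name,
                    seq = paste(bases, collapse = ""), length = L)
      if (nrow(implants) == 0L || length(spec$mirnas) == 0L) {
        return(list(utr = utr, sites = empty_sites()))
      }
      found <- scan_sites(utr[, c("name", "seq")], mirna_tbl, canon_cfg)
      found$implant <- NA_integer_
      ok <- TRUE
      nc <- startsWith(implants$site_type, "noncanonical")
      for (k in which(!nc)) {
        hit <- which(found$mirna_name == implants$mirna_name[k] &
                       found$seed_start == implants$position[k] &
                       found$site_type == implants$site_type[k])
        if (length(hit) != 1L) { ok <- FALSE; break }
        found$implant[hit] <- k
      }
      # non-canonical implants are invisible to the canonical-only scan
      if (ok && any(nc)) {
        nc_found <- scan_sites(utr[, c("name", "seq")], mirna_tbl, spec$scan_config)
        for (k in which(nc)) {
          hit <- which(nc_found$mirna_name == implants$mirna_name[k] &
                         nc_found$seed_start == implants$position[k] &
                         nc_found$site_type == implants$site_type[k])
          if (length(hit) != 1L) { ok <- FALSE; break }
          nc_row <- nc_found[hit, ]
          nc_row$implant <- k
          found <- dplyr::bind_rows(found, nc_row)
        }
      }
      if (ok && any(is.na(found$implant))) ok <- FALSE  # accidental canonical site
      if (ok) {
        return(list(utr = utr,
                    sites = dplyr::arrange(found, .data$seed_start)))
      }
    }
    abort(sprintf("Could not realize the implant layout in %d attempts.", max_tries),
          class = "polymirts_spec_error")
  })
}

#' Simulate labelled 3'UTR variants relative to implanted sites
#'
#' Places each requested variant inside the seed interval, inside the
#' compensatory region (the UTR bases facing miRNA positions 13-16), or
#' away from every footprint, according to its `placement` label, and
#' verifies the label closed-loop: seed variants intersect the implant's
#' seed interval; seed deletions are additionally verified (and locally
#' re-placed if needed) to yield an `allele_effect()` call of `site_loss`.
#'
#' @param sim Result of [simulate_utr()].
#' @param spec The same [simulation_spec()].
#' @return A polymorphism tibble (see [polymorphism_table()]) with
#'   `placement` and `target` columns added.
#' @export
simulate_variants <- function(sim, spec) {
  utr <- sim$utr; truth <- sim$sites
  u <- chars(utr$seq)
  vs <- spec$variants
  if (!"del_length" %in% names(vs)) vs$del_length <- NA_integer_
  if (nrow(vs) == 0L) {
    return(dplyr::mutate(polymorphism_table(character(), integer(),
                                            character(), character()),
                         placement = character(), target = character()))
  }
  with_seed(spec$seed + 1L, {
    one_variant <- function(i) {
      v <- vs[i, ]
      if (v$placement %in% c("seed", "compensatory")) {
        site <- truth[truth$mirna_name == v$target, ][1, ]
        if (is.na(site$mirna_name)) {
          abort(sprintf("No implanted site for target miRNA '%s'.", v$target),
                class = "polymirts_spec_error")
        }
      }
      if (v$placement == "seed" && v$kind == "deletion") {
        dl <- if (is.na(v$del_length)) 2L else as.integer(v$del_length)
        starts <- site$seed_start:(site$seed_end - dl + 1L)
        starts <- sample(starts)  # random order, then verify closed-loop
        for (st in starts) {
          ref <- substr(utr$seq, st, st + dl - 1L)
          poly <- polymorphism_table(v$snp_id, st, ref, "", utr_name = utr$name)
          eff <- allele_effect(utr[, c("name", "seq")], poly,
                               setNames(spec$mirnas[v$target], v$target),
                               config = spec$scan_config)
          if (eff$call == "site_loss") {
            return(dplyr::mutate(poly, placement = v$placement, target = v$target))
          }
        }
        abort("Could not place a seed deletion yielding site_loss.",
              class = "polymirts_spec_error")
      }
      if (v$placement == "seed" && v$kind == "SNV") {
        pos <- sample(site$seed_start:site$seed_end, 1L)
        ref <- u[pos]
        # break the Watson-Crick pair: any different base changes the class
        alt <- sample(setdiff(RNA_BASES, ref), 1L)
        poly <- polymorphism_table(v$snp_id, pos, ref, alt, utr_name = utr$name)
        return(dplyr::mutate(poly, placement = v$placement, target = v$target))
      }
      if (v$placement == "compensatory") {
        # UTR bases facing miRNA 13-16: seed-anchored, 5' of the seed match
        s <- if (site$site_type %in% c("7mer-A1", "6mer")) site$seed_start
             else site$seed_start + 1L
        lo <- max(site$footprint_start, s - 9L)
        hi <- min(s - 6L, site$seed_start - 1L)
        if (lo > hi) {
          abort("Compensatory region truncated away; move the implant.",
                class = "polymirts_spec_error")
        }
        pos <- sample(lo:hi, 1L)
        ref <- u[pos]
        alt <- sample(setdiff(RNA_BASES, ref), 1L)
        poly <- polymorphism_table(v$snp_id, pos, ref, alt, utr_name = utr$name)
        return(dplyr::mutate(poly, placement = v$placement, target = v$target))
      }
      # outside: any position not overlapping a footprint
      margin <- 1L
      blocked <- rep(FALSE, utr$length)
      for (k in seq_len(nrow(truth))) {
        blocked[max(1L, truth$footprint_start[k] - margin):
                  min(utr$length, truth$footprint_end[k] + margin)] <- TRUE
      }
      pos <- sample(which(!blocked), 1L)
      ref <- u[pos]
      if (v$kind == "deletion") {
        dl <- if (is.na(v$del_length)) 2L else as.integer(v$del_length)
        ref <- substr(utr$seq, pos, pos + dl - 1L)
        poly <- polymorphism_table(v$snp_id, pos, ref, "", utr_name = utr$name)
      } else {
        alt <- sample(setdiff(RNA_BASES, ref), 1L)
        poly <- polymorphism_table(v$snp_id, pos, ref, alt, utr_name = utr$name)
      }
      dplyr::mutate(poly, placement = v$placement, target = NA_character_)
    }
    dplyr::bind_rows(lapply(seq_len(nrow(vs)), one_variant))
  })
}

#' Simulate a UTR and its labelled variants jointly
#'
#' Draws the implanted UTR and the labelled variant set as one unit,
#' extending the implant-and-reject scheme across stages: if a background
#' admits no variant placement satisfying its truth label (e.g. no in-seed
#' deletion yields a clean site loss because the deletion junction happens
#' to recreate a weak site), the whole layout is redrawn under a derived
#' attempt seed. Deterministic given the spec.
#'
#' @param spec A [simulation_spec()].
#' @param max_layouts Layout redraws before giving up.
#' @return A list with `sim` (see [simulate_utr()]), `variants` (see
#'   [simulate_variants()]) and `spec` (the spec actually realized, whose
#'   seed reflects the accepted attempt).
#' @export
simulate_study <- function(spec, max_layouts = 50L) {
  for (k in seq_len(max_layouts) - 1L) {
    spec_k <- spec
    spec_k$seed <- as.integer((spec$seed + k * 100003) %% .Machine$integer.max)
    res <- tryCatch({
      sim <- simulate_utr(spec_k)
      list(sim = sim, variants = simulate_variants(sim, spec_k), spec = spec_k)
    }, polymirts_spec_error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  abort(sprintf("No feasible (UTR, variant) layout in %d attempts.", max_layouts),
        class = "polymirts_spec_error")
}

#' Simulate miRNA expression counts
#'
#' Negative-binomial raw-read counts per miRNA (variance
#' `mean + dispersion * mean^2`); a dispersion of 0 uses the Poisson
#' limit, and a mean of 0 yields all zeros.
#'
#' @param spec A [simulation_spec()].
#' @param n Draws per miRNA (default 1, one observed count each).
#' @return A tibble `mirna_name`, `raw_reads` (and `draw` when `n > 1`).
#' @export
simulate_expression <- function(spec, n = 1L) {
  ex <- spec$expression
  with_seed(spec$seed + 2L, {
    out <- purrr::map_dfr(seq_len(nrow(ex)), function(i) {
      mu <- ex$mean[i]; disp <- ex$dispersion[i]
      draws <- if (mu == 0) {
        rep(0L, n)
      } else if (disp <= 0) {
        rpois(n, mu)
      } else {
        rnbinom(n, mu = mu, size = 1 / disp)
      }
      tibble(mirna_name = ex$mirna_name[i], draw = seq_len(n),
             raw_reads = as.integer(draws))
    })
    if (n == 1L) out$draw <- NULL
    out
  })
}

#' Simulate dual-luciferase measurements with known truth
#'
#' Scrambled-control wells have expected relative activity exactly 1;
#' wells of a targeting miRNA have expectation equal to its repression
#' factor r, moved toward 1 on variant constructs by the construct's
#' attenuation fraction: `r + attenuation * (1 - r)`. Noise is
#' multiplicative lognormal on the firefly/renilla ratio (intensities are
#' positive ratios), so `sigma = 0` reproduces the expectations exactly.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with columns `experiment`, `construct`, `mirna`,
#'   `firefly`, `renilla` and the ground-truth `true_relative`.
#' @export
simulate_reporter <- function(spec) {
  grid <- tidyr::expand_grid(
    experiment = paste0("exp", seq_len(spec$n_experiments)),
    construct = unique(spec$constructs$construct),
    mirna = c("SCR", names(spec$repression)),
    well = seq_len(spec$replicates)
  )
  att <- spec$constructs
  grid <- dplyr::left_join(grid, att, by = c("construct", "mirna"))
  grid$attenuation[is.na(grid$attenuation)] <- 0
  r <- spec$repression
  grid$true_relative <- ifelse(
    grid$mirna == "SCR", 1,
    r[grid$mirna] + grid$attenuation * (1 - r[grid$mirna])
  )
  base_ratio <- 2
  with_seed(spec$seed + 3L, {
    n <- nrow(grid)
    renilla <- rlnorm(n, meanlog = log(1000), sdlog = 0.2)
    noise <- if (spec$sigma > 0) rlnorm(n, 0, spec$sigma) else rep(1, n)
    grid$renilla <- renilla
    grid$firefly <- renilla * base_ratio * grid$true_relative * noise
    grid$well <- NULL
    grid
  })
}

#' Simulate a case/control genotype table with fixed carrier counts
#'
#' Carrier counts are exact (not sampled); only the sample order is
#' shuffled under the seed, so [carrier_counts()] reproduces the spec's
#' counts identically.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble `sample_id`, `group`, `carrier`.
#' @export
simulate_genotypes <- function(spec) {
  ch <- spec$cohort
  if (ch$ad_total + ch$control_total <= 0L) {
    abort("Cohort sizes are zero; nothing to simulate.",
          class = "polymirts_spec_error")
  }
  if (ch$ad_carriers > ch$ad_total || ch$control_carriers > ch$control_total) {
    abort("Carrier counts exceed group sizes.", class = "polymirts_spec_error")
  }
  tbl <- dplyr::bind_rows(
    tibble(sample_id = sprintf("AD_%04d", seq_len(ch$ad_total)),
           group = "AD",
           carrier = seq_len(ch$ad_total) <= ch$ad_carriers),
    tibble(sample_id = sprintf("CT_%04d", seq_len(ch$control_total)),
           group = "control",
           carrier = seq_len(ch$control_total) <= ch$control_carriers)
  )
  with_seed(spec$seed + 4L, tbl[sample(nrow(tbl)), ])
}

#' Write a full set of synthetic pipeline inputs to disk
#'
#' Materializes one simulated study as the plain-text files the readers
#' consume: UTR and miRNA FASTA, variant TSV and minimal VCF, expression
#' TSV, reporter TSV and genotype TSV.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly; the generated objects as
#'   attribute `"objects"`.
#' @export
simulate_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(spec)
  sim <- study$sim
  polys <- study$variants
  expr <- simulate_expression(spec)
  rep_tbl <- simulate_reporter(spec)
  geno <- simulate_genotypes(spec)

  paths <- list(
    utr = file.path(dir, "utr.fa"), mirnas = file.path(dir, "mirnas.fa"),
    variants = file.path(dir, "variants.tsv"),
    variants_vcf = file.path(dir, "variants.vcf"),
    expression = file.path(dir, "expression.tsv"),
    reporter = file.path(dir, "reporter.tsv"),
    genotypes = file.path(dir, "genotypes.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(setNames(sim$utr$seq, sim$utr$name)), paths$utr)
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(spec$mirnas), paths$mirnas)
  readr::write_tsv(
    tibble(snp_id = polys$snp_id, position = polys$position,
           ref = polys$ref, alt = polys$alt, utr_name = polys$utr_name),
    paths$variants, progress = FALSE)
  write_vcf_lite(polys, sim$utr, paths$variants_vcf)
  readr::write_tsv(tibble(name = expr$mirna_name, count = expr$raw_reads),
                   paths$expression, progress = FALSE)
  readr::write_tsv(rep_tbl, paths$reporter, progress = FALSE)
  readr::write_tsv(geno, paths$genotypes, progress = FALSE)
  out <- structure(paths,
                   objects = list(sim = sim, variants = polys, expression = expr,
                                  reporter = rep_tbl, genotypes = geno))
  invisible(out)
}

# minimal VCF writer (anchor-base convention for indels)
write_vcf_lite <- function(polys, utr, path) {
  u <- chars(utr$seq)
  rows <- purrr::map_chr(seq_len(nrow(polys)), function(i) {
    p <- polys[i, ]
    if (p$kind == "SNV") {
      sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", utr$name, p$position, p$snp_id,
              chartr("U", "T", p$ref), chartr("U", "T", p$alt))
    } else if (p$kind == "deletion") {
      anchor <- u[p$position - 1L]
      sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", utr$name, p$position - 1L, p$snp_id,
              chartr("U", "T", paste0(anchor, p$ref)), chartr("U", "T", anchor))
    } else {
      anchor <- u[p$position - 1L]
      sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", utr$name, p$position - 1L, p$snp_id,
              chartr("U", "T", anchor), chartr("U", "T", paste0(anchor, p$alt)))
    }
  })
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", utr$name, utr$length),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
}
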