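let7 <- "UGAGGUAGUAGGUUGUAUAGUU"   # seed 2-8 = GAGGUAG

test_that("representative UTR is the longest, ties by transcript id", {
  utrs <- data.frame(gene = c("G1", "G1", "G2", "G2", "G3"),
                     transcript = c("t2", "t1", "t9", "t1", "t1"),
                     sequence = c(strrep("A", 500), strrep("A", 1200),
                                  strrep("C", 100), strrep("G", 100),
                                  "ACGU"))
  rep1 <- longest_utr(utrs)
  expect_equal(nchar(rep1$sequence[rep1$gene == "G1"]), 1200L)
  expect_equal(rep1$transcript[rep1$gene == "G2"], "t1")
  expect_equal(rep1$sequence[rep1$gene == "G3"], "ACGU")
  expect_message(longest_utr(rbind(utrs, data.frame(
    gene = "G4", transcript = "t1", sequence = ""))), "empty")
})

test_that("seed sites are found and typed 6mer/7mer-A1/7mer-m8/8mer", {
  ## 8mer: complement of positions 8..2 followed by an A
  s <- find_seed_sites(let7, "NNNCUACCUCANNN")
  expect_equal(nrow(s), 1L)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$site_start, 4L)

  ## 6mer only: 5' flank is U (not C), 3' flank is G (not A)
  s2 <- find_seed_sites(let7, "NNNUACCUCGNNN")
  expect_equal(s2$site_type, "6mer")
  expect_equal(s2$site_start, 4L)

  ## 7mer-A1 and 7mer-m8 variants
  expect_equal(find_seed_sites(let7, "NNNUACCUCANNN")$site_type, "7mer-A1")
  expect_equal(find_seed_sites(let7, "NNNCUACCUCGNNN")$site_type, "7mer-m8")

  ## no complementary hexamer
  expect_equal(nrow(find_seed_sites(let7, strrep("A", 50))), 0L)
  expect_error(find_seed_sites("UGAG", "ACGU"), ">= 8 nt")
  expect_error(find_seed_sites(let7, "ACGT"), "non-RNA")
})

test_that("every emitted site reverse-complements back to the seed", {
  set.seed(17)
  for (rep in 1:200) {
    mirna <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                   collapse = "")
    utr <- paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE),
                 collapse = "")
    sites <- find_seed_sites(mirna, utr)
    if (nrow(sites) == 0) next
    seed <- strsplit(substr(mirna, 1, 8), "")[[1]]
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    for (i in seq_len(nrow(sites))) {
      o <- sites$core_start[i]
      core <- substr(utr, o, o + 5)
      ## core bases complement miRNA positions 7..2 in 5'->3' order
      expect_equal(strsplit(core, "")[[1]],
                   unname(comp[seed[7:2]]))
      if (sites$site_type[i] %in% c("7mer-m8", "8mer")) {
        expect_equal(substr(utr, o - 1, o - 1), unname(comp[seed[8]]))
      }
      if (sites$site_type[i] %in% c("7mer-A1", "8mer")) {
        expect_equal(substr(utr, o + 6, o + 6), "A")
      }
      ## alignment map inverts to the site span
      aln <- site_alignment(sites[i, ])
      expect_equal(unname(aln[as.character(7:2)]), o:(o + 5))
    }
  }
})

test_that("aligned variant duos classify by Watson-Crick alt pairing", {
  site <- data.frame(gene = "G1", site_start = 9L, core_start = 10L,
                     site_type = "7mer-m8")
  ## miRNA position 4 aligns to UTR position 10 + (7-4) = 13
  mk_mv <- function(ref, alt) data.frame(
    chrom = "chr1", pos = 555L, mature_pos = 4L, mature_last = 4L,
    ref_rna = ref, alt_rna = alt, af_joint = 0.001)
  mk_uv <- function(ref, alt, af = 0.001) data.frame(
    gene = "G1", utr_pos = 13L, ref = ref, alt = alt, af_joint = af)

  p1 <- pair_variants(site, mk_mv("G", "A"), mk_uv("C", "U"))
  expect_equal(p1$classification, "compensatory")
  expect_equal(p1$duplex_pos, 4L)
  p2 <- pair_variants(site, mk_mv("G", "A"), mk_uv("C", "G"))
  expect_equal(p2$classification, "disruptive")
  ## G:U wobble after substitution is disruptive unless relaxed
  p3 <- pair_variants(site, mk_mv("C", "G"), mk_uv("G", "U"))
  expect_equal(p3$classification, "disruptive")
  p3b <- pair_variants(site, mk_mv("C", "G"), mk_uv("G", "U"),
                       allow_wobble = TRUE)
  expect_equal(p3b$classification, "compensatory")

  ## no UTR variant at the aligned position -> no pair
  expect_equal(nrow(pair_variants(site, mk_mv("G", "A"),
                                  within(mk_uv("C", "U"),
                                         utr_pos <- 12L))), 0L)
  ## InDels at aligned positions are excluded
  expect_message(
    expect_equal(nrow(pair_variants(site, mk_mv("G", "AG"),
                                    mk_uv("C", "U"))), 0L),
    "InDel")
  ## AF-class summary from both members
  expect_equal(p1$af_class_summary, "both_rare")
  p4 <- pair_variants(site, mk_mv("G", "A"), mk_uv("C", "U", af = 0.03))
  expect_equal(p4$af_class_summary, "one_snp")

  ## classification symmetry: swapping member order preserves the label
  expect_equal(p1$classification,
               pair_variants(site, mk_uv_as_mv <- mk_mv("C", "U"),
                             data.frame(gene = "G1", utr_pos = 13L,
                                        ref = "G", alt = "A",
                                        af_joint = 0.001))$classification)
})

test_that("population specificity requires a shared unique argmax", {
  af1 <- c(afr = 0.05, nfe = 0.01, eas = 0.02)
  af2 <- c(afr = 0.03, nfe = 0.02, eas = 0.01)
  expect_equal(population_specificity(af1, af2),
               list(specific = TRUE, population = "afr"))
  af3 <- c(afr = 0.01, nfe = 0.05, eas = 0.02)
  expect_false(population_specificity(af1, af3)$specific)
  ## a two-way tie breaks specificity
  af4 <- c(afr = 0.05, nfe = 0.05, eas = 0.01)
  expect_false(population_specificity(af4, af2)$specific)
  ## all-zero AFs are never specific
  expect_false(population_specificity(c(afr = 0, nfe = 0), af2)$specific)
})

test_that("compensatory ratio test matches the exact oracle", {
  mk <- function(n_comp, n_disr, type = "6mer") data.frame(
    classification = rep(c("compensatory", "disruptive"),
                         c(n_comp, n_disr)),
    site_type = type)
  r <- compensatory_ratio_test(mk(10, 10), mk(10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  r2 <- compensatory_ratio_test(mk(40, 10), mk(10, 40))
  expect_equal(r2$p_value, fisher_oracle_p(40, 10, 10, 40),
               tolerance = 1e-9)

  ## site-type restriction drops 6mer pairs before testing
  a <- rbind(mk(5, 5, "6mer"), mk(20, 2, "8mer"))
  b <- rbind(mk(5, 5, "6mer"), mk(2, 20, "7mer-m8"))
  r3 <- compensatory_ratio_test(a, b, min_site = "7mer-A1")
  expect_equal(unname(r3$table["a", ]), c(20, 2))
  expect_equal(unname(r3$table["b", ]), c(2, 20))
  expect_error(compensatory_ratio_test(mk(1, 1)[0, ], mk(1, 1)),
               "nonempty")
})

test_that("ClinVar annotation joins both pair members exactly", {
  pairs <- data.frame(
    mirna = "m1", gene = "G1", site_type = "6mer", site_start = 5L,
    duplex_pos = 3L, utr_pos = 9L, mirna_ref = "G", mirna_alt = "A",
    utr_ref = "C", utr_alt = "U", mirna_chrom = "chr1",
    mirna_gpos = 1234L, mirna_af = 0.001, utr_af = 0.001,
    classification = "compensatory", af_class_summary = "both_rare")
  clin <- data.frame(chrom = c("G1", "chr1"), pos = c(9L, 1234L),
                     ref = c("C", "G"), alt = c("T", "A"),
                     classification = c("Pathogenic", "Benign"),
                     phenotypes = c("ph1", "ph2"))
  ann <- annotate_clinvar(pairs, clin)
  expect_equal(ann$utr_clinvar, "Pathogenic")   # T/U normalized
  expect_equal(ann$mirna_clinvar, "Benign")
  ## no matches -> empty annotations
  ann2 <- annotate_clinvar(pairs, clin[0, ])
  expect_equal(ann2$utr_clinvar, "")
  expect_equal(ann2$mirna_clinvar, "")
})

test_that("end-to-end detection recovers exactly the planted pairs", {
  fx <- make_fixture(fixture_spec(seed = 7))
  out <- run_scoring(fx)
  seqs <- with(out$groups, setNames(sequence[!duplicated(group)],
                                    group[!duplicated(group)]))
  pairs <- suppressMessages(detect_compensatory_pairs(
    fx$tables$interactions, seqs, longest_utr(fx$tables$utrs),
    out$mapped, fx$tables$utr_variants, groups = out$groups))
  truth <- fx$manifest$pairs
  key <- function(d) paste(d$mirna, d$gene, d$duplex_pos)
  ## sensitivity and specificity both 1
  expect_setequal(key(pairs), key(truth))
  m <- merge(pairs, truth, by = c("mirna", "gene", "duplex_pos"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$classification.x, m$classification.y)
  expect_equal(m$site_type.x, m$site_type.y)
  expect_equal(m$population_specific.x, m$population_specific.y)
  expect_equal(m$population.x, m$population.y)
  expect_equal(m$af_class_summary.x, m$af_class_summary.y)

  ## a compensatory alt duplex is always Watson-Crick
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  is_wc <- unname(comp[pairs$mirna_alt] == pairs$utr_alt)
  expect_equal(pairs$classification == "compensatory", is_wc)

  ## min_site filter removes weaker site classes
  strong <- suppressMessages(detect_compensatory_pairs(
    fx$tables$interactions, seqs, longest_utr(fx$tables$utrs),
    out$mapped, fx$tables$utr_variants, groups = out$groups,
    min_site = "7mer-m8"))
  expect_true(all(strong$site_type %in% c("7mer-m8", "8mer")))

  ## empty interaction list -> empty result
  empty <- suppressMessages(detect_compensatory_pairs(
    fx$tables$interactions[0, ], seqs, longest_utr(fx$tables$utrs),
    out$mapped, fx$tables$utr_variants, groups = out$groups))
  expect_equal(nrow(empty), 0L)
})
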