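## Seeded synthetic-input generator with planted ground truth. Emulates
## the shapes of the real inputs (miRBase-style GFF3, gnomAD-style
## per-population AFs, tissue expression tables, UTR FASTA, target
## interactions, APA sites, ClinVar-style annotations) so that every
## analysis module is testable without downloads.

#' Specification for a synthetic fixture
#'
#' Collects all generator parameters with the defaults used throughout
#' the package's tests. Allele frequencies are drawn from class-conditional
#' scaled Beta distributions truncated to the class interval (rare
#' `(0, 0.01]`, SNP `(0.01, 0.05]`, common `(0.05, 1]`), so planted AF
#' classes respect the classification boundaries by construction. Mature
#' lengths are drawn from 20-24 nt to exercise coverage-fraction logic.
#'
#' @param seed Master seed; every output stream derives its own seed from
#'   it, so the same spec yields byte-identical files.
#' @param n_precursors Number of precursor hairpins.
#' @param frac_two_arm Fraction of precursors with both arms annotated.
#' @param frac_minus Fraction of minus-strand precursors.
#' @param populations Population codes for per-population AF columns.
#' @param n_hc,n_lc Sizes of the planted highly/least conserved groups
#'   (HC miRNAs carry exactly one rare non-seed variant; LC miRNAs carry
#'   `lc_variant_range` variants including `lc_seed_snps` seed SNPs).
#' @param lc_variant_range,lc_seed_snps,mid_variant_range Variant-burden
#'   parameters per group.
#' @param n_zero_variant Number of planted zero-variant miRNAs.
#' @param expression_link Component score driving expression (`"PCS"`,
#'   `"SCS"`, `"NSCS"`, `"TVS"`).
#' @param expression_noise_sd Noise SD of the expression link, on the
#'   scale of the (0-100) expression values.
#' @param n_genes,utr_len_range Target-gene count and UTR length range.
#' @param n_comp_pairs,n_disr_pairs Planted compensatory/disruptive
#'   variant-pair counts.
#' @param frac_pop_specific Fraction of planted pairs whose two variants
#'   share their maximum-AF population.
#' @param apa_sites_range Range of APA sites per gene.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         n_precursors = 10L,
                         frac_two_arm = 0.6,
                         frac_minus = 0.3,
                         populations = GNOMAD_POPULATIONS,
                         n_hc = 4L, n_lc = 4L,
                         lc_variant_range = c(6L, 10L),
                         lc_seed_snps = 2L,
                         mid_variant_range = c(3L, 5L),
                         n_zero_variant = 1L,
                         expression_link = "PCS",
                         expression_noise_sd = 0.5,
                         n_genes = 12L,
                         utr_len_range = c(150L, 300L),
                         n_comp_pairs = 20L,
                         n_disr_pairs = 20L,
                         frac_pop_specific = 0.5,
                         apa_sites_range = c(0L, 3L)) {
  spec <- as.list(environment())
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(frac_two_arm >= 0, frac_two_arm <= 1,
            frac_minus >= 0, frac_minus <= 1,
            frac_pop_specific >= 0, frac_pop_specific <= 1)
  class(spec) <- "fixture_spec"
  spec
}

rand_af <- function(n, class) {
  switch(class,
         rare = 0.01 * stats::rbeta(n, 1, 5),
         snp = 0.01 + 0.04 * stats::rbeta(n, 2, 2),
         common = 0.05 + 0.55 * stats::rbeta(n, 1, 2),
         stop_valid("unknown AF class '%s'", class))
}

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

## miRNA-sense RNA base at mature position -> genomic DNA allele
sense_base_to_genomic <- function(base, strand) {
  dna <- chartr("U", "T", base)
  if (strand == "-") revcomp_dna(dna) else dna
}

mature_pos_to_genomic <- function(locus, p) {
  if (locus$strand == "-") locus$end - p + 1L else locus$start + p - 1L
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes (or returns in memory) a miRBase-style GFF3, a mature-sequence
#' FASTA, a variant TSV with joint and per-population AFs, two expression
#' TSVs whose mean expression is a monotone function of a chosen component
#' score, a UTR FASTA with planted seed-match sites, a UTR-variant TSV,
#' an interaction TSV, an APA TSV and a ClinVar-style TSV, together with
#' a manifest of every planted truth.
#'
#' HC miRNAs receive exactly one rare non-seed variant; LC miRNAs receive
#' dense variants including seed SNPs, so every HC OCS exceeds every LC
#' OCS by construction. Compensatory/disruptive pairs are planted by
#' mutating aligned seed/UTR positions (complementary alternate alleles
#' for compensatory pairs), with both variants' maximum per-population AF
#' in one chosen population for the population-specific fraction.
#' Background UTR sequence is scrubbed of accidental seed-core matches of
#' the interacting miRNAs so planted pairs are recovered exactly.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with `tables` (all generated data frames),
#'   `manifest` (planted truths) and `files` (paths written, if any).
#' @export
make_fixture <- function(spec, outdir = NULL) {
  build_fixture(spec, outdir, null_structure = FALSE)
}

#' Generate a null fixture without planted structure
#'
#' Same outputs as [make_fixture()], but variant burden is homogeneous
#' across miRNAs (no HC/LC separation), expression is independent of the
#' scores, and planted pair classifications and population assignments
#' are random coin flips independent of any grouping. Used for
#' calibration tests (permutation and Fisher p-values should be
#' approximately uniform).
#'
#' @inheritParams make_fixture
#' @return As [make_fixture()].
#' @export
null_fixture <- function(spec, outdir = NULL) {
  build_fixture(spec, outdir, null_structure = TRUE)
}

build_fixture <- function(spec, outdir, null_structure) {
  stopifnot(inherits(spec, "fixture_spec"))
  pops <- spec$populations

  ## ---- loci ----------------------------------------------------------
  loci <- with_seed(derive_seed(spec$seed, "loci"), {
    rows <- list()
    n2 <- round(spec$frac_two_arm * spec$n_precursors)
    for (i in seq_len(spec$n_precursors)) {
      strand <- if (stats::runif(1) < spec$frac_minus) "-" else "+"
      chrom <- sample(c("chr1", "chr2"), 1L)
      d5 <- sample(2:5, 1L)
      la5 <- sample(20:24, 1L)
      loopl <- sample(12:20, 1L)
      la3 <- sample(20:24, 1L)
      d3 <- sample(0:3, 1L)
      Lp <- d5 + la5 + loopl + la3 + d3
      pstart <- 100000L * i + sample(0:500, 1L)
      pend <- pstart + Lp - 1L
      pid <- sprintf("SYNMI%04d", i)
      pname <- sprintf("syn-mir-%d", i)
      rows[[length(rows) + 1L]] <- data.frame(
        id = pid, name = pname, chrom = chrom, start = pstart, end = pend,
        strand = strand, feature_kind = "precursor", derives_from = "",
        arm = "unknown", stringsAsFactors = FALSE)
      mk_arm <- function(arm, ls, le) {
        g1 <- mature_pos_to_genomic(
          data.frame(strand = strand, start = pstart, end = pend), ls)
        g2 <- mature_pos_to_genomic(
          data.frame(strand = strand, start = pstart, end = pend), le)
        data.frame(
          id = sprintf("SYNMIMAT%04d%s", i, arm),
          name = sprintf("syn-miR-%d-%s", i, arm),
          chrom = chrom, start = min(g1, g2), end = max(g1, g2),
          strand = strand, feature_kind = "mature", derives_from = pid,
          arm = arm, stringsAsFactors = FALSE)
      }
      s5 <- d5 + 1L; e5 <- s5 + la5 - 1L
      s3 <- e5 + loopl + 1L; e3 <- s3 + la3 - 1L
      if (i <= n2) {
        rows[[length(rows) + 1L]] <- mk_arm("5p", s5, e5)
        rows[[length(rows) + 1L]] <- mk_arm("3p", s3, e3)
      } else if (i %% 2L == 0L) {
        rows[[length(rows) + 1L]] <- mk_arm("5p", s5, e5)
      } else {
        rows[[length(rows) + 1L]] <- mk_arm("3p", s3, e3)
      }
    }
    do.call(rbind, rows)
  })
  mat <- loci[loci$feature_kind == "mature", , drop = FALSE]

  ## ---- mature sequences (with one multi-copy pair when possible) -----
  sequences <- with_seed(derive_seed(spec$seed, "sequences"), {
    lens <- mat$end - mat$start + 1L
    seqs <- vapply(lens, rand_rna, character(1))
    names(seqs) <- mat$id
    dup <- which(duplicated(lens) | duplicated(lens, fromLast = TRUE))
    pre_of <- mat$derives_from
    pair <- NULL
    for (a in dup) for (b in dup) {
      if (a < b && lens[a] == lens[b] && pre_of[a] != pre_of[b]) {
        pair <- c(a, b); break
      }
    }
    if (!is.null(pair)) seqs[pair[2L]] <- seqs[pair[1L]]
    seqs
  })
  groups <- collapse_identical_matures(loci, sequences)
  gnames <- unique(groups$group)
  multi <- unique(groups$group[groups$n_copies > 1L])

  ## ---- group roles ---------------------------------------------------
  roles <- with_seed(derive_seed(spec$seed, "misc"), {
    eligible <- setdiff(gnames, multi)
    eligible <- sample(eligible)
    r <- stats::setNames(rep("mid", length(gnames)), gnames)
    nz <- min(spec$n_zero_variant, length(eligible))
    if (nz > 0) {
      r[eligible[seq_len(nz)]] <- "zero"
      eligible <- eligible[-seq_len(nz)]
    }
    if (!null_structure) {
      nh <- min(spec$n_hc, length(eligible))
      r[eligible[seq_len(nh)]] <- "HC"
      eligible <- eligible[-seq_len(nh)]
      nl <- min(spec$n_lc, length(eligible))
      r[eligible[seq_len(nl)]] <- "LC"
    } else {
      ## labels without structure, for calibration tests
      nh <- min(spec$n_hc, length(eligible))
      r[eligible[seq_len(nh)]] <- "HC"
      eligible <- eligible[-seq_len(nh)]
      nl <- min(spec$n_lc, length(eligible))
      r[eligible[seq_len(nl)]] <- "LC"
    }
    r
  })

  ## representative locus per group (variants are planted there; extra
  ## copies of multi-copy groups stay variant-free)
  rep_locus <- vapply(gnames, function(g) {
    groups$id[groups$group == g][1L]
  }, character(1))
  glen <- vapply(gnames, function(g)
    nchar(groups$sequence[groups$group == g][1L]), integer(1))

  ## ---- mature variants per group -------------------------------------
  vstate <- with_seed(derive_seed(spec$seed, "variants"), {
    mature_vars <- list()   # per group: data.frame(p, p_last, ref, alt, class)
    add_var <- function(g, p, p_last, alt = NULL, class = "rare") {
      seq_g <- groups$sequence[groups$group == g][1L]
      refb <- substr(seq_g, p, p_last)
      if (is.null(alt)) {
        alt <- sample(setdiff(c("A", "C", "G", "U"),
                              substr(refb, 1L, 1L)), 1L)
      }
      mature_vars[[g]] <<- rbind(
        mature_vars[[g]],
        data.frame(p = p, p_last = p_last, ref = refb, alt = alt,
                   class = class, stringsAsFactors = FALSE))
    }
    used_pos <- function(g) {
      if (is.null(mature_vars[[g]])) integer(0) else
        unlist(lapply(seq_len(nrow(mature_vars[[g]])), function(i)
          seq(mature_vars[[g]]$p[i], mature_vars[[g]]$p_last[i])))
    }
    for (g in gnames) {
      role <- roles[[g]]
      L <- glen[[g]]
      if (role == "zero") next
      if (null_structure) {
        nv <- sample(0:max(spec$mid_variant_range), 1L)
        if (nv > 0) {
          ps <- sample(seq_len(L), nv)
          for (p in ps) add_var(g, p, p,
                                class = sample(c("rare", "rare", "snp"), 1L))
        }
      } else if (role == "HC") {
        p <- sample(8:L, 1L)
        add_var(g, p, p, class = "rare")
      } else if (role == "LC") {
        sp <- sample(2:7, spec$lc_seed_snps)
        for (p in sp) add_var(g, p, p, class = "snp")
        nrest <- sample(spec$lc_variant_range[1L]:spec$lc_variant_range[2L],
                        1L) - spec$lc_seed_snps
        free <- setdiff(seq_len(L), used_pos(g))
        ps <- sample(free, min(nrest, length(free)))
        for (p in ps) add_var(g, p, p, class = "rare")
        ## one non-seed deletion spanning two positions, if room
        free <- setdiff(8:(L - 1L), c(used_pos(g), used_pos(g) - 1L))
        if (length(free)) {
          p <- if (length(free) == 1L) free else sample(free, 1L)
          seq_g <- groups$sequence[groups$group == g][1L]
          mature_vars[[g]] <- rbind(
            mature_vars[[g]],
            data.frame(p = p, p_last = p + 1L,
                       ref = substr(seq_g, p, p + 1L),
                       alt = substr(seq_g, p, p),
                       class = "rare", stringsAsFactors = FALSE))
        }
      } else {
        ## mid-burden miRNAs carry the component-decoupling structure:
        ## AF classes are mixed (wide SCS/NSCS spread), one seed variant
        ## (SCS varies independently of position burden), and a
        ## multiallelic site of variable depth (v_t decoupled from p_v,
        ## so PCS and TVS rank miRNAs differently)
        ## Mid-burden miRNAs decouple the score components: positional
        ## burden (p_v, driving PCS) is drawn independently of a latent
        ## allele-frequency burden b that jointly drives SCS, NSCS and
        ## the multiallelic depth behind TVS. PCS thus carries positional
        ## information that the AF-driven components do not share.
        b <- stats::runif(1)
        bclass <- if (b < 1 / 3) "rare" else if (b < 2 / 3) "snp" else
          "common"
        nv <- sample(spec$mid_variant_range[1L]:spec$mid_variant_range[2L],
                     1L)
        ps <- sample(8:L, min(nv, L - 7L))
        add_var(g, ps[1L], ps[1L], class = bclass)
        for (p in ps[-1L]) add_var(g, p, p, class = "rare")
        sp <- sample(2:7, 1L)
        add_var(g, sp, sp, class = bclass)
        ## extra alternate alleles stacked on existing positions
        seq_g <- groups$sequence[groups$group == g][1L]
        extras <- min(round(b * 10), 2L * (length(ps) + 1L))
        slots <- rep(c(ps, sp), each = 2L)
        for (p in slots[seq_len(extras)]) {
          mv <- mature_vars[[g]]
          used <- mv$alt[mv$p == p]
          avail <- setdiff(c("A", "C", "G", "U"),
                           c(substr(seq_g, p, p), used))
          if (length(avail)) {
            add_var(g, p, p, alt = avail[1L], class = "rare")
          }
        }
      }
    }
    list(mature_vars = mature_vars)
  })
  mature_vars <- vstate$mature_vars

  ## ---- planted pairs (add seed variants + UTR plan) -------------------
  genes <- sprintf("SYNG%03d", seq_len(spec$n_genes))
  pair_plan <- with_seed(derive_seed(spec$seed, "targets"), {
    n_pairs <- spec$n_comp_pairs + spec$n_disr_pairs
    cand <- gnames[roles %in% c("LC", "mid")]
    combos <- expand.grid(g = cand, p = 2:8, stringsAsFactors = FALSE)
    ## avoid positions already carrying a variant in that group
    keep <- vapply(seq_len(nrow(combos)), function(i) {
      mv <- mature_vars[[combos$g[i]]]
      is.null(mv) || !any(mv$p <= combos$p[i] & mv$p_last >= combos$p[i])
    }, logical(1))
    combos <- combos[keep, , drop = FALSE]
    if (nrow(combos) < n_pairs) {
      stop_valid("fixture spec cannot host %d pairs (only %d free seed slots)",
                 n_pairs, nrow(combos))
    }
    combos <- combos[sample(nrow(combos), n_pairs), , drop = FALSE]
    cls <- sample(rep(c("compensatory", "disruptive"),
                      c(spec$n_comp_pairs, spec$n_disr_pairs)))
    if (null_structure) cls <- sample(c("compensatory", "disruptive"),
                                      n_pairs, replace = TRUE)
    site_types <- vapply(combos$p, function(p) {
      if (p == 8L) sample(c("7mer-m8", "8mer"), 1L) else
        sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"), 1L)
    }, character(1))
    specific <- stats::runif(n_pairs) < spec$frac_pop_specific
    mirna_pop <- sample(pops, n_pairs, replace = TRUE)
    utr_pop <- vapply(seq_len(n_pairs), function(i) {
      if (specific[i]) mirna_pop[i] else
        sample(setdiff(pops, mirna_pop[i]), 1L)
    }, character(1))
    snp_member <- sample(c(0L, 1L, 2L), n_pairs, replace = TRUE,
                         prob = c(0.7, 0.2, 0.1))  # 0 none, 1 mirna, 2 utr
    data.frame(mirna = combos$g, gene = genes[(seq_len(n_pairs) - 1L) %%
                                                spec$n_genes + 1L],
               duplex_pos = combos$p, site_type = site_types,
               classification = cls, population_specific = specific,
               population = ifelse(specific, mirna_pop, NA_character_),
               mirna_pop = mirna_pop, utr_pop = utr_pop,
               snp_member = snp_member, stringsAsFactors = FALSE)
  })

  ## add the pairs' miRNA seed variants
  pair_state <- with_seed(derive_seed(spec$seed, "utrs"), {
    mirna_alts <- character(nrow(pair_plan))
    for (i in seq_len(nrow(pair_plan))) {
      g <- pair_plan$mirna[i]; p <- pair_plan$duplex_pos[i]
      seq_g <- groups$sequence[groups$group == g][1L]
      refb <- substr(seq_g, p, p)
      altb <- sample(setdiff(c("A", "C", "G", "U"), refb), 1L)
      cl <- if (pair_plan$snp_member[i] == 1L) "snp" else "rare"
      mature_vars[[g]] <- rbind(
        mature_vars[[g]],
        data.frame(p = p, p_last = p, ref = refb, alt = altb, class = cl,
                   stringsAsFactors = FALSE))
      mirna_alts[i] <- altb
    }

    ## build UTRs with planted sites (kept as character vectors while
    ## planting; joined to strings afterwards)
    utr_len <- sample(spec$utr_len_range[1L]:spec$utr_len_range[2L],
                      spec$n_genes, replace = TRUE)
    utr <- lapply(utr_len, function(l)
      sample(c("A", "C", "G", "U"), l, replace = TRUE))
    names(utr) <- genes
    site_offsets <- integer(nrow(pair_plan))
    next_off <- stats::setNames(rep(10L, spec$n_genes), genes)
    utr_rows <- list()
    for (i in seq_len(nrow(pair_plan))) {
      g <- pair_plan$mirna[i]; gene <- pair_plan$gene[i]
      p <- pair_plan$duplex_pos[i]; type <- pair_plan$site_type[i]
      seed8 <- strsplit(substr(groups$sequence[groups$group == g][1L],
                               1L, 8L), "")[[1L]]
      o <- next_off[[gene]]
      next_off[[gene]] <- o + 20L
      if (o + 6L > length(utr[[gene]])) {
        utr[[gene]] <- c(utr[[gene]],
                         sample(c("A", "C", "G", "U"), o + 30L,
                                replace = TRUE))
      }
      s <- utr[[gene]]
      s[o:(o + 5L)] <- rna_complement(seed8[7:2])
      m8c <- rna_complement(seed8[8L])
      s[o - 1L] <- if (type %in% c("7mer-m8", "8mer")) m8c else
        setdiff(c("A", "C", "G", "U"), m8c)[1L]
      s[o + 6L] <- if (type %in% c("7mer-A1", "8mer")) "A" else "C"
      utr[[gene]] <- s
      site_offsets[i] <- o
      ## aligned UTR variant
      upos <- if (p == 8L) o - 1L else o + (7L - p)
      uref <- s[upos]
      alt_m <- mirna_alts[i]
      if (pair_plan$classification[i] == "compensatory") {
        ualt <- rna_complement(alt_m)
      } else {
        excl <- c(uref, rna_complement(alt_m),
                  if (alt_m == "G") "U" else if (alt_m == "U") "G")
        ualt <- setdiff(c("A", "C", "G", "U"), excl)[1L]
      }
      if (ualt == uref) ualt <- setdiff(c("A", "C", "G", "U"),
                                        c(uref, rna_complement(alt_m)))[1L]
      cl <- if (pair_plan$snp_member[i] == 2L) "snp" else "rare"
      utr_rows[[i]] <- data.frame(gene = gene, utr_pos = upos, ref = uref,
                                  alt = ualt, class = cl,
                                  stringsAsFactors = FALSE)
    }
    utr <- vapply(utr, function(v) paste(v, collapse = ""), character(1))
    ## scrub accidental core matches outside planted sites
    protected <- split(lapply(seq_len(nrow(pair_plan)), function(i)
      c(site_offsets[i] - 1L, site_offsets[i] + 6L)), pair_plan$gene)
    cores_by_gene <- split(vapply(seq_len(nrow(pair_plan)), function(i) {
      seed8 <- strsplit(substr(groups$sequence[groups$group ==
                                                 pair_plan$mirna[i]][1L],
                               1L, 8L), "")[[1L]]
      paste(rna_complement(seed8[7:2]), collapse = "")
    }, character(1)), pair_plan$gene)
    for (gene in names(cores_by_gene)) {
      prot <- protected[[gene]]
      for (iter in 1:10) {
        s <- strsplit(utr[[gene]], "")[[1L]]
        changed <- FALSE
        for (core in unique(cores_by_gene[[gene]])) {
          hits <- gregexpr(core, utr[[gene]], fixed = TRUE)[[1L]]
          if (hits[1L] == -1L) next
          for (o in as.integer(hits)) {
            inprot <- any(vapply(prot, function(pr)
              o >= pr[1L] - 5L && o <= pr[2L], logical(1)))
            if (!inprot) {
              s[o + 2L] <- setdiff(c("A", "C", "G", "U"), s[o + 2L])[1L]
              changed <- TRUE
            }
          }
        }
        utr[[gene]] <- paste(s, collapse = "")
        if (!changed) break
      }
    }
    list(utr = utr, utr_rows = utr_rows, mature_vars = mature_vars,
         mirna_alts = mirna_alts, site_offsets = site_offsets)
  })
  mature_vars <- pair_state$mature_vars
  utr_seqs <- pair_state$utr

  ## ---- assemble variant table (mature + hairpin/flank + QC rejects) --
  variants <- with_seed(derive_seed(spec$seed, "misc") + 1L, {
    rows <- list()
    pop_afs <- function(af_joint, maxpop) {
      af <- stats::setNames(af_joint * stats::runif(length(pops), 0.1, 0.9),
                            pops)
      af[maxpop] <- min(1, af_joint * stats::runif(1, 1.05, 1.5))
      af
    }
    pair_of <- function(g, p) {
      hit <- which(pair_plan$mirna == g & pair_plan$duplex_pos == p)
      if (length(hit) == 1L) hit else NA_integer_
    }
    for (g in gnames) {
      mv <- mature_vars[[g]]
      if (is.null(mv)) next
      locus <- mat[mat$id == rep_locus[[g]], , drop = FALSE]
      for (i in seq_len(nrow(mv))) {
        af <- rand_af(1L, mv$class[i])
        pi <- pair_of(g, mv$p[i])
        maxpop <- if (!is.na(pi)) pair_plan$mirna_pop[pi] else
          sample(pops, 1L)
        af_pop <- pop_afs(af, maxpop)
        gref <- sense_base_to_genomic(mv$ref[i], locus$strand)
        galt <- sense_base_to_genomic(mv$alt[i], locus$strand)
        g1 <- mature_pos_to_genomic(locus, mv$p[i])
        g2 <- mature_pos_to_genomic(locus, mv$p_last[i])
        rows[[length(rows) + 1L]] <- c(
          list(chrom = locus$chrom, pos = min(g1, g2), ref = gref,
               alt = galt, af_joint = af),
          as.list(stats::setNames(af_pop, paste0("af_", pops))),
          list(in_wgs = TRUE, in_wes = stats::runif(1) < 0.5,
               af_discrepant = FALSE, pass_qc = TRUE))
      }
    }
    ## hairpin (loop/stem) and flank variants per precursor
    pre <- loci[loci$feature_kind == "precursor", , drop = FALSE]
    for (k in seq_len(nrow(pre))) {
      p <- pre[k, , drop = FALSE]
      kids <- mat[mat$derives_from == p$id, , drop = FALSE]
      part <- infer_hairpin_regions(p, kids)
      hp <- part[part$region %in% c("terminal_loop", "lower_stem_5p",
                                    "lower_stem_3p"), , drop = FALSE]
      cand <- unlist(lapply(seq_len(nrow(hp)), function(j)
        seq(hp$start[j], hp$end[j])))
      fl <- flank_regions(NULL, p)
      fcand <- unlist(lapply(seq_len(nrow(fl)), function(j)
        seq(fl$start[j], fl$end[j])))
      for (gp in c(sample(cand, min(3L, length(cand))),
                   sample(fcand, min(2L, length(fcand))))) {
        ref <- sample(c("A", "C", "G", "T"), 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        af <- rand_af(1L, "rare")
        rows[[length(rows) + 1L]] <- c(
          list(chrom = p$chrom, pos = gp, ref = ref, alt = alt,
               af_joint = af),
          as.list(stats::setNames(pop_afs(af, sample(pops, 1L)),
                                  paste0("af_", pops))),
          list(in_wgs = TRUE, in_wes = stats::runif(1) < 0.5,
               af_discrepant = FALSE, pass_qc = TRUE))
      }
    }
    ## QC-reject records (exercise the read filters)
    p1 <- pre[1L, ]
    rej <- list(
      list(pass_qc = FALSE, in_wgs = TRUE, af_discrepant = FALSE),
      list(pass_qc = TRUE, in_wgs = FALSE, af_discrepant = FALSE),
      list(pass_qc = TRUE, in_wgs = TRUE, af_discrepant = TRUE))
    for (j in seq_along(rej)) {
      af <- rand_af(1L, "rare")
      rows[[length(rows) + 1L]] <- c(
        list(chrom = p1$chrom, pos = p1$start - 30L - j, ref = "A",
             alt = "G", af_joint = af),
        as.list(stats::setNames(pop_afs(af, sample(pops, 1L)),
                                paste0("af_", pops))),
        list(in_wgs = rej[[j]]$in_wgs, in_wes = TRUE,
             af_discrepant = rej[[j]]$af_discrepant,
             pass_qc = rej[[j]]$pass_qc))
    }
    cols <- names(rows[[1L]])
    v <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn)
      unlist(lapply(rows, `[[`, cn), use.names = FALSE)))
    v <- v[!duplicated(v[, c("chrom", "pos", "ref", "alt")]), , drop = FALSE]
    rownames(v) <- NULL
    attr(v, "populations") <- pops
    v
  })

  ## ---- true component values and expression ---------------------------
  true_tab <- do.call(rbind, lapply(gnames, function(g) {
    mv <- mature_vars[[g]]
    L <- glen[[g]]
    if (is.null(mv)) {
      return(data.frame(group = g, role = roles[[g]], L = L, v_t = 0L,
                        p_v = 0L, PCS = 1, TVS = 1, stringsAsFactors = FALSE))
    }
    pv <- length(unique(unlist(lapply(seq_len(nrow(mv)), function(i)
      seq(mv$p[i], mv$p_last[i])))))
    data.frame(group = g, role = roles[[g]], L = L, v_t = nrow(mv),
               p_v = pv, PCS = clamp01(1 - pv / L),
               TVS = clamp01(1 - nrow(mv) / L), stringsAsFactors = FALSE)
  }))

  make_expression <- function(stream) {
    with_seed(derive_seed(spec$seed, stream), {
      base_val <- if (null_structure) {
        stats::runif(length(gnames), 0, 100)
      } else {
        link <- true_tab[[spec$expression_link]] %||% true_tab$PCS
        100 * link + stats::rnorm(length(gnames), 0,
                                  spec$expression_noise_sd)
      }
      offs <- stats::runif(3L, -2, 2)
      df <- data.frame(mirna = true_tab$group)
      for (t in 1:3) df[[paste0("tissue", t)]] <- base_val + offs[t]
      df
    })
  }
  expr_a <- make_expression("expression_a")
  expr_b <- make_expression("expression_b")

  ## ---- UTR variants, interactions, APA, ClinVar ----------------------
  empty_utr_variants <- cbind(
    data.frame(gene = character(0), utr_pos = integer(0),
               ref = character(0), alt = character(0),
               af_joint = numeric(0)),
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(pops)),
                                  paste0("af_", pops))))
  utr_variants <- if (nrow(pair_plan) == 0L) empty_utr_variants else
    with_seed(derive_seed(spec$seed, "misc") + 2L, {
    rows <- lapply(seq_len(nrow(pair_plan)), function(i) {
      r <- pair_state$utr_rows[[i]]
      af <- rand_af(1L, r$class)
      maxpop <- pair_plan$utr_pop[i]
      af_pop <- stats::setNames(af * stats::runif(length(pops), 0.1, 0.9),
                                pops)
      af_pop[maxpop] <- min(1, af * stats::runif(1, 1.05, 1.5))
      cbind(r[, c("gene", "utr_pos", "ref", "alt")],
            data.frame(af_joint = af, stringsAsFactors = FALSE),
            as.data.frame(as.list(stats::setNames(af_pop,
                                                  paste0("af_", pops)))))
    })
    do.call(rbind, rows)
  })

  interactions <- unique(rbind(
    pair_plan[, c("mirna", "gene")],
    data.frame(mirna = gnames[1:2],
               gene = genes[c(spec$n_genes, spec$n_genes - 1L)],
               stringsAsFactors = FALSE)))
  rownames(interactions) <- NULL

  apa <- with_seed(derive_seed(spec$seed, "apa"), {
    rows <- list()
    for (g in genes) {
      n <- sample(spec$apa_sites_range[1L]:spec$apa_sites_range[2L], 1L)
      if (n == 0L) next
      posn <- sort(sample(seq_len(nchar(utr_seqs[[g]])), n))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, utr_pos = posn,
        read_support = sample(5:100, n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(0), utr_pos = integer(0),
                 read_support = integer(0))
  })

  clinvar <- with_seed(derive_seed(spec$seed, "clinvar"), {
    n_ann <- min(2L, nrow(utr_variants))
    idx <- seq_len(n_ann)
    if (n_ann == 0L) {
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 classification = character(0),
                 phenotypes = character(0))
    } else {
      data.frame(
        chrom = utr_variants$gene[idx],
        pos = utr_variants$utr_pos[idx],
        ref = utr_variants$ref[idx],
        alt = utr_variants$alt[idx],
        classification = c("Pathogenic", "Uncertain significance")[idx],
        phenotypes = paste0("synthetic phenotype ", idx),
        stringsAsFactors = FALSE)
    }
  })

  ## pair manifest with AF-class summary from the realized joint AFs
  manifest_pairs <- pair_plan[, c("mirna", "gene", "duplex_pos",
                                  "site_type", "classification",
                                  "population_specific", "population")]
  manifest_pairs$af_class_summary <- vapply(seq_len(nrow(pair_plan)),
                                            function(i) {
    cls <- sort(c(if (pair_plan$snp_member[i] == 1L) "snp" else "rare",
                  if (pair_plan$snp_member[i] == 2L) "snp" else "rare"))
    if (all(cls == "rare")) "both_rare" else
      if (all(cls == "snp")) "both_snp" else "one_snp"
  }, character(1))

  manifest <- list(
    seed = spec$seed,
    null_structure = null_structure,
    counts = list(n_precursors = sum(loci$feature_kind == "precursor"),
                  n_matures = sum(loci$feature_kind == "mature"),
                  n_loci = nrow(loci),
                  n_groups = length(gnames),
                  n_variants = nrow(variants),
                  n_pairs = nrow(manifest_pairs),
                  n_genes = spec$n_genes),
    populations = pops,
    groups = true_tab,
    pairs = manifest_pairs,
    representative_apa = representative_apa(apa)
  )

  utrs <- data.frame(gene = genes, transcript = paste0(genes, ".t1"),
                     sequence = unname(utr_seqs[genes]),
                     stringsAsFactors = FALSE)

  tables <- list(loci = loci, sequences = sequences, groups = groups,
                 variants = variants, expression_a = expr_a,
                 expression_b = expr_b, utrs = utrs,
                 utr_variants = utr_variants, interactions = interactions,
                 apa = apa, clinvar = clinvar)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- write_fixture_files(tables, manifest, outdir)
  }
  invisible(list(tables = tables, manifest = manifest, files = files))
}

write_fixture_files <- function(tables, manifest, outdir) {
  fp <- function(f) file.path(outdir, f)
  wt <- function(df, f) {
    utils::write.table(df, fp(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fp(f)
  }
  files <- c(
    gff = {
      write_mirna_gff(tables$loci, fp("mirna.gff3"))
      fp("mirna.gff3")
    },
    mature_fa = {
      writeLines(as.vector(rbind(paste0(">", names(tables$sequences)),
                                 unname(tables$sequences))),
                 fp("mature.fa"))
      fp("mature.fa")
    },
    variants = wt(tables$variants, "variants.tsv"),
    expression_a = wt(tables$expression_a, "expression_a.tsv"),
    expression_b = wt(tables$expression_b, "expression_b.tsv"),
    utrs = {
      writeLines(as.vector(rbind(
        paste0(">", tables$utrs$gene, "|", tables$utrs$transcript),
        tables$utrs$sequence)), fp("utrs.fa"))
      fp("utrs.fa")
    },
    utr_variants = wt(tables$utr_variants, "utr_variants.tsv"),
    interactions = wt(tables$interactions, "interactions.tsv"),
    apa = wt(tables$apa, "apa.tsv"),
    clinvar = wt(tables$clinvar, "clinvar.tsv"),
    manifest = {
      jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      fp("manifest.json")
    }
  )
  files
}
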