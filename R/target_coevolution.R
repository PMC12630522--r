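## Seed-site alignment in 3'UTRs and detection/classification of
## compensatory miRNA-target variant pairs.

#' Pick the representative (longest) 3'UTR per gene
#'
#' @param utrs `data.frame` with columns `gene`, `transcript`, `sequence`.
#'   Ties on length break by lowest transcript id; empty sequences are
#'   skipped with a message.
#' @return `data.frame` with one row per gene (`gene`, `transcript`,
#'   `sequence`).
#' @export
longest_utr <- function(utrs) {
  empty <- !nzchar(utrs$sequence)
  if (any(empty)) {
    message(sprintf("skipping %d empty UTR record(s)", sum(empty)))
    utrs <- utrs[!empty, , drop = FALSE]
  }
  utrs <- utrs[order(utrs$gene, -nchar(utrs$sequence), utrs$transcript), ,
               drop = FALSE]
  out <- utrs[!duplicated(utrs$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read 3'UTR sequences from FASTA
#'
#' Headers are expected as `gene|transcript` (or just `gene`); sequences
#' are converted to RNA (T -> U).
#'
#' @param path FASTA path.
#' @return `data.frame` with `gene`, `transcript`, `sequence` columns.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)   # accepts DNA or RNA alphabets
  hdr <- strsplit(names(ss), "|", fixed = TRUE)
  data.frame(
    gene = vapply(hdr, `[`, character(1), 1L),
    transcript = vapply(hdr, function(h)
      if (length(h) > 1L) h[2L] else h[1L], character(1)),
    sequence = dna_to_rna(as.character(ss)),
    stringsAsFactors = FALSE
  )
}

#' Find canonical seed-match sites of a miRNA in a 3'UTR
#'
#' Scans for every occurrence of the 6mer core (UTR bases complementary to
#' miRNA seed positions 7..2, read 5'-to-3') and types each occurrence as
#' `6mer`, `7mer-A1` (an A in the UTR opposite miRNA position 1, at the
#' site's 3' end), `7mer-m8` (a match to miRNA position 8 at the site's 5'
#' end) or `8mer` (both). Overlapping evidence at one core locus is
#' reported once at the strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#'
#' @param mirna_seq Mature miRNA sequence, RNA, 5'-to-3', length >= 8.
#' @param utr_seq Representative UTR sequence (RNA; `N`s allowed and never
#'   matched).
#' @param gene Optional gene label carried into the output.
#' @return `data.frame` with `gene`, `site_start` (1-based UTR offset of
#'   the full site), `core_start` (offset of the 6mer core), `site_type`.
#' @export
find_seed_sites <- function(mirna_seq, utr_seq, gene = NA_character_) {
  mirna_seq <- toupper(mirna_seq); utr_seq <- toupper(utr_seq)
  assert_rna(mirna_seq, "mirna_seq")
  if (grepl("[^ACGUN]", utr_seq)) stop_valid("utr_seq has non-RNA characters")
  if (nchar(mirna_seq) < 8L) stop_valid("miRNA sequence must be >= 8 nt")
  seed <- strsplit(substr(mirna_seq, 1L, 8L), "")[[1L]]
  core <- paste(rna_complement(seed[7:2]), collapse = "")
  m8 <- rna_complement(seed[8L])
  hits <- gregexpr(core, utr_seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    return(data.frame(gene = character(0), site_start = integer(0),
                      core_start = integer(0), site_type = character(0)))
  }
  ub <- strsplit(utr_seq, "")[[1L]]
  n <- nchar(utr_seq)
  out <- lapply(as.integer(hits), function(o) {
    has_m8 <- o > 1L && ub[o - 1L] == m8
    has_a1 <- (o + 6L) <= n && ub[o + 6L] == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    data.frame(gene = gene,
               site_start = if (has_m8) o - 1L else o,
               core_start = o, site_type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Duplex alignment map of a binding site
#'
#' Maps paired miRNA positions to UTR positions for one site: seed
#' positions 2..7 always, position 8 for `7mer-m8`/`8mer` sites. Position
#' 1 (the A1 adenosine is not base-paired) is never part of the map.
#'
#' @param site One row from [find_seed_sites()].
#' @return Named integer vector, names = miRNA positions.
#' @export
site_alignment <- function(site) {
  o <- site$core_start
  pos <- 2:7
  utr <- o + (7L - pos)
  if (site$site_type %in% c("7mer-m8", "8mer")) {
    pos <- c(pos, 8L)
    utr <- c(utr, o - 1L)
  }
  stats::setNames(as.integer(utr), pos)
}

#' Pair aligned miRNA-seed and UTR variants and classify them
#'
#' For each binding site, emits one pair per (miRNA seed variant, UTR
#' variant) duo occurring at aligned duplex positions (miRNA positions
#' 2..8; position 1 is never paired). Only SNV-SNV duos are classified;
#' aligned InDels are excluded with a message. A pair is `compensatory`
#' iff the two alternate alleles form a Watson-Crick pair (A:U or G:C);
#' G:U wobbles after substitution count as disruptive unless
#' `allow_wobble = TRUE`. The AF-class summary is `both_rare`, `one_snp`,
#' `both_snp` (or `other` when a common allele is involved), from the
#' joint AFs of both members.
#'
#' @param sites Site table from [find_seed_sites()] for one miRNA/gene.
#' @param mirna_variants Mature-level mapped variants of the miRNA
#'   (columns `mature_pos`, `mature_last`, `ref_rna`, `alt_rna`, AF
#'   columns).
#' @param utr_variants UTR variants in representative-UTR coordinates
#'   (columns `utr_pos`, `ref`, `alt` on the UTR sense -- RNA or DNA --
#'   plus AF columns).
#' @param mirna Optional miRNA name carried through.
#' @param allow_wobble Treat alt G:U as preserved pairing.
#' @return `data.frame` of pairs with site type, duplex position, both
#'   alleles, `classification` and `af_class_summary`.
#' @export
pair_variants <- function(sites, mirna_variants, utr_variants,
                          mirna = NA_character_, allow_wobble = FALSE) {
  out <- list()
  mv <- mirna_variants
  uv <- utr_variants
  if (is.null(mv$mature_last)) mv$mature_last <- mv$mature_pos
  if (is.null(mv$chrom)) mv$chrom <- NA_character_
  if (is.null(mv$pos)) mv$pos <- NA_integer_
  uv$ref <- dna_to_rna(uv$ref); uv$alt <- dna_to_rna(uv$alt)
  n_indel <- 0L
  for (si in seq_len(nrow(sites))) {
    site <- sites[si, , drop = FALSE]
    aln <- site_alignment(site)
    for (p in as.integer(names(aln))) {
      upos <- aln[[as.character(p)]]
      mhit <- which(mv$mature_pos <= p & mv$mature_last >= p)
      uhit <- which(uv$utr_pos == upos)
      for (i in mhit) for (j in uhit) {
        if (nchar(mv$ref_rna[i]) != 1L || nchar(mv$alt_rna[i]) != 1L ||
            nchar(uv$ref[j]) != 1L || nchar(uv$alt[j]) != 1L) {
          n_indel <- n_indel + 1L
          next
        }
        alt_m <- mv$alt_rna[i]; alt_u <- uv$alt[j]
        wc <- is_watson_crick(alt_m, alt_u)
        wob <- paste0(pmin(alt_m, alt_u), pmax(alt_m, alt_u)) == "GU"
        cls <- if (wc || (allow_wobble && wob)) "compensatory" else
          "disruptive"
        afc <- sort(classify_af(c(mv$af_joint[i], uv$af_joint[j])))
        summ <- if (all(afc == "rare")) "both_rare" else
          if (all(afc == "snp")) "both_snp" else
            if (setequal(afc, c("rare", "snp"))) "one_snp" else "other"
        out[[length(out) + 1L]] <- data.frame(
          mirna = mirna, gene = site$gene, site_type = site$site_type,
          site_start = site$site_start, duplex_pos = p, utr_pos = upos,
          mirna_ref = mv$ref_rna[i], mirna_alt = alt_m,
          utr_ref = uv$ref[j], utr_alt = alt_u,
          mirna_chrom = mv$chrom[i],
          mirna_gpos = mv$pos[i],
          mirna_af = mv$af_joint[i], utr_af = uv$af_joint[j],
          classification = cls, af_class_summary = summ,
          mirna_row = i, utr_row = j,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_indel > 0L) {
    message(sprintf("excluded %d aligned InDel duo(s) from pairing", n_indel))
  }
  if (!length(out)) return(empty_pairs())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_pairs <- function() {
  data.frame(mirna = character(0), gene = character(0),
             site_type = character(0), site_start = integer(0),
             duplex_pos = integer(0), utr_pos = integer(0),
             mirna_ref = character(0), mirna_alt = character(0),
             utr_ref = character(0), utr_alt = character(0),
             mirna_chrom = character(0), mirna_gpos = integer(0),
             mirna_af = numeric(0), utr_af = numeric(0),
             classification = character(0), af_class_summary = character(0),
             mirna_row = integer(0), utr_row = integer(0),
             stringsAsFactors = FALSE)
}

#' Population specificity of a variant pair
#'
#' A pair is population-specific iff each member's per-population AF
#' attains its maximum in a single (strictly unique) population and both
#' maxima coincide. Ties in a member's AFs, or all-zero AFs, yield
#' `FALSE`.
#'
#' @param af_a,af_b Named numeric vectors of per-population AFs for the
#'   two members.
#' @return List with `specific` (flag) and `population` (code or `NA`).
#' @export
population_specificity <- function(af_a, af_b) {
  top <- function(af) {
    if (all(af == 0)) return(NA_character_)
    mx <- max(af)
    hits <- names(af)[af == mx]
    if (length(hits) != 1L) NA_character_ else hits
  }
  pa <- top(af_a); pb <- top(af_b)
  if (!is.na(pa) && !is.na(pb) && pa == pb) {
    list(specific = TRUE, population = pa)
  } else {
    list(specific = FALSE, population = NA_character_)
  }
}

#' Compensatory/disruptive ratio test between two pair groups
#'
#' Two-sided Fisher exact test on
#' `[[comp_a, disr_a], [comp_b, disr_b]]`, optionally restricted to sites
#' stronger than a minimum type (ordering 6mer < 7mer-A1 < 7mer-m8 <
#' 8mer).
#'
#' @param pairs_a,pairs_b Pair tables (from [pair_variants()]) for the two
#'   groups.
#' @param min_site Minimum site type to keep, or `NULL` for all.
#' @return List with `table`, `odds_ratio`, `p_value`.
#' @export
compensatory_ratio_test <- function(pairs_a, pairs_b, min_site = NULL) {
  strength <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
  if (!is.null(min_site)) {
    lim <- strength[[min_site]]
    pairs_a <- pairs_a[strength[pairs_a$site_type] >= lim, , drop = FALSE]
    pairs_b <- pairs_b[strength[pairs_b$site_type] >= lim, , drop = FALSE]
  }
  if (nrow(pairs_a) == 0L || nrow(pairs_b) == 0L) {
    stop_valid("both pair groups must be nonempty (after site restriction)")
  }
  tab <- matrix(c(sum(pairs_a$classification == "compensatory"),
                  sum(pairs_a$classification == "disruptive"),
                  sum(pairs_b$classification == "compensatory"),
                  sum(pairs_b$classification == "disruptive")),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("a", "b"), c("comp", "disr")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = if (is.finite(or)) or else NA_real_,
       p_value = ft$p.value)
}

#' Annotate pairs with ClinVar-style records
#'
#' Left-joins both members of every pair against an annotation table on
#' exact (chrom, pos, ref, alt). The miRNA member joins on its genomic
#' coordinates; the UTR member joins on (gene, utr_pos) against tables
#' expressed in representative-UTR coordinates (chrom column holding the
#' gene). Unmatched members get empty annotations.
#'
#' @param pairs Pair table from [pair_variants()] (needs `mirna_chrom`,
#'   `mirna_gpos`, `gene`, `utr_pos`, allele columns).
#' @param clinvar `data.frame` with `chrom`, `pos`, `ref`, `alt`,
#'   `classification`, `phenotypes`.
#' @return `pairs` with added `mirna_clinvar`, `mirna_phenotypes`,
#'   `utr_clinvar`, `utr_phenotypes`.
#' @export
annotate_clinvar <- function(pairs, clinvar) {
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  ck <- key(clinvar$chrom, clinvar$pos,
            dna_to_rna(clinvar$ref), dna_to_rna(clinvar$alt))
  mi <- match(key(pairs$mirna_chrom, pairs$mirna_gpos,
                  dna_to_rna(pairs$mirna_ref), dna_to_rna(pairs$mirna_alt)),
              ck)
  ui <- match(key(pairs$gene, pairs$utr_pos,
                  pairs$utr_ref, pairs$utr_alt), ck)
  pairs$mirna_clinvar <- ifelse(is.na(mi), "", clinvar$classification[mi])
  pairs$mirna_phenotypes <- ifelse(is.na(mi), "", clinvar$phenotypes[mi])
  pairs$utr_clinvar <- ifelse(is.na(ui), "", clinvar$classification[ui])
  pairs$utr_phenotypes <- ifelse(is.na(ui), "", clinvar$phenotypes[ui])
  pairs
}

#' End-to-end compensatory-pair detection
#'
#' For each experimentally supported miRNA-gene interaction, finds seed
#' sites in the gene's representative UTR, pairs aligned seed/UTR
#' variants, classifies them, and calls population specificity from the
#' per-population AF columns shared by both variant tables.
#'
#' @param interactions `data.frame` with `mirna`, `gene` columns.
#' @param mirna_seqs Named character vector of mature sequences (RNA) by
#'   miRNA name.
#' @param utrs Representative UTRs from [longest_utr()].
#' @param mirna_variants Mature-level mapped variants (with `mirna_name`).
#' @param utr_variants UTR variant table with `gene`, `utr_pos`, `ref`,
#'   `alt` and AF columns.
#' @param populations Population codes; defaults to those found on
#'   `mirna_variants` or the gnomAD nine.
#' @param groups Optional collapsed-group table from
#'   [collapse_identical_matures()]; when given, a miRNA's variants are
#'   selected by locus membership in its group (so multi-locus miRNAs
#'   collapsed under one name keep their variants), otherwise by
#'   `mirna_name`.
#' @param min_site Optional minimum site type (see
#'   [compensatory_ratio_test()]).
#' @param allow_wobble Passed to [pair_variants()].
#' @return Pair table with population-specificity columns.
#' @export
detect_compensatory_pairs <- function(interactions, mirna_seqs, utrs,
                                      mirna_variants, utr_variants,
                                      populations = NULL,
                                      groups = NULL,
                                      min_site = NULL,
                                      allow_wobble = FALSE) {
  populations <- populations %||% attr(mirna_variants, "populations") %||%
    GNOMAD_POPULATIONS
  popcols <- paste0("af_", populations)
  popcols <- intersect(popcols,
                       intersect(names(mirna_variants), names(utr_variants)))
  out <- list()
  for (k in seq_len(nrow(interactions))) {
    m <- interactions$mirna[k]; g <- interactions$gene[k]
    if (!m %in% names(mirna_seqs)) next
    utr <- utrs[utrs$gene == g, , drop = FALSE]
    if (nrow(utr) == 0L) next
    mv <- if (!is.null(groups)) {
      ids <- groups$id[groups$group == m]
      mirna_variants[mirna_variants$mirna_id %in% ids &
                       mirna_variants$level == "mature", , drop = FALSE]
    } else {
      mirna_variants[mirna_variants$mirna_name == m &
                       mirna_variants$level == "mature", , drop = FALSE]
    }
    uv <- utr_variants[utr_variants$gene == g, , drop = FALSE]
    if (nrow(mv) == 0L || nrow(uv) == 0L) next
    if (any(uv$utr_pos > nchar(utr$sequence[1L]))) {
      stop_valid("UTR variant beyond UTR length for gene '%s'", g)
    }
    sites <- find_seed_sites(mirna_seqs[[m]], utr$sequence[1L], gene = g)
    if (nrow(sites) == 0L) next
    pp <- pair_variants(sites, mv, uv, mirna = m,
                        allow_wobble = allow_wobble)
    if (nrow(pp) == 0L) next
    spec <- lapply(seq_len(nrow(pp)), function(i) {
      af_m <- stats::setNames(as.numeric(mv[pp$mirna_row[i], popcols]),
                              sub("^af_", "", popcols))
      af_u <- stats::setNames(as.numeric(uv[pp$utr_row[i], popcols]),
                              sub("^af_", "", popcols))
      population_specificity(af_m, af_u)
    })
    pp$population_specific <- vapply(spec, `[[`, logical(1), "specific")
    pp$population <- vapply(spec, `[[`, character(1), "population")
    out[[length(out) + 1L]] <- pp
  }
  res <- if (length(out)) do.call(rbind, out) else {
    e <- empty_pairs()
    e$population_specific <- logical(0)
    e$population <- character(0)
    e
  }
  if (!is.null(min_site)) {
    strength <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
    res <- res[strength[res$site_type] >= strength[[min_site]], ,
               drop = FALSE]
  }
  res$mirna_row <- NULL; res$utr_row <- NULL
  rownames(res) <- NULL
  res
}
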