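## Variant classification (AF class, InDel, Ti/Tv, ref:alt RNA pair) and
## positional / regional statistics.

#' Classify an allele frequency into rare / SNP / common
#'
#' Boundaries follow the convention common (AF > 0.05),
#' SNP (0.01 < AF <= 0.05), rare (AF <= 0.01).
#'
#' @param af Numeric vector of allele frequencies in `[0, 1]`.
#' @return Character vector with values `"rare"`, `"snp"`, `"common"`.
#' @export
classify_af <- function(af) {
  assert_fraction(af, "af")
  ifelse(af > 0.05, "common", ifelse(af > 0.01, "snp", "rare"))
}

#' Is a ref/alt allele pair an insertion or deletion?
#'
#' @param ref,alt Nonempty allele strings.
#' @return Logical: `TRUE` iff the allele lengths differ.
#' @export
is_indel <- function(ref, alt) {
  stopifnot(all(nzchar(ref)), all(nzchar(alt)))
  nchar(ref) != nchar(alt)
}

#' Transition-to-transversion ratio of a set of SNVs
#'
#' Transitions are A<->G and C<->T on the genomic (DNA) alleles. When an
#' AF ceiling is given, only variants with `af_joint <= af_max` enter the
#' ratio (cumulative AF bin). With zero transversions, or an empty
#' selection, `NA` is returned rather than an error.
#'
#' @param variants Variant table with `ref`, `alt` (single-base) and
#'   `af_joint` columns; InDels must be excluded beforehand.
#' @param af_max Optional AF ceiling, or `NULL` for all variants.
#' @return The Ti/Tv ratio, or `NA_real_` when undefined.
#' @export
titv_ratio <- function(variants, af_max = NULL) {
  if (any(is_indel(variants$ref, variants$alt))) {
    stop_valid("titv_ratio expects SNVs only; remove InDels first")
  }
  if (!is.null(af_max)) {
    variants <- variants[variants$af_joint <= af_max, , drop = FALSE]
  }
  if (nrow(variants) == 0L) return(NA_real_)
  ti <- is_transition(variants$ref, variants$alt)
  ntv <- sum(!ti)
  if (ntv == 0L) return(NA_real_)
  sum(ti) / ntv
}

is_transition <- function(ref, alt) {
  pur <- c("A", "G"); pyr <- c("C", "T")
  (ref %in% pur & alt %in% pur) | (ref %in% pyr & alt %in% pyr)
}

#' Classify an unordered ref:alt RNA base pair
#'
#' On miRNA-sense RNA alleles: `AG` (purine transition), `CU` (pyrimidine
#' transition), `GU` (wobble pair), otherwise `other`.
#'
#' @param ref_rna,alt_rna Single RNA bases on miRNA sense.
#' @return Character vector over `{"AG","CU","GU","other"}`.
#' @export
classify_pair <- function(ref_rna, alt_rna) {
  ref_rna <- toupper(ref_rna); alt_rna <- toupper(alt_rna)
  assert_rna(ref_rna, "ref_rna"); assert_rna(alt_rna, "alt_rna")
  stopifnot(all(nchar(ref_rna) == 1L), all(nchar(alt_rna) == 1L))
  key <- paste(pmin(ref_rna, alt_rna), pmax(ref_rna, alt_rna), sep = "")
  out <- rep("other", length(key))
  out[key == "AG"] <- "AG"
  out[key == "CU"] <- "CU"
  out[key == "GU"] <- "GU"
  out
}

#' Per-position variant counts over mature miRNAs
#'
#' Counts variants at each mature position (1..max length over the group)
#' together with the coverage fraction: the share of the group's miRNAs
#' whose mature length reaches that position. Deletions spanning several
#' mature positions increment every affected position. Coverage-normalized
#' counts are included for positions with nonzero coverage.
#'
#' @param mapped Mapped variants (mature-level rows are used).
#' @param loci Locus table; mature lengths are taken from the group.
#' @param group Optional character vector of mature locus names restricting
#'   both counts and the length distribution.
#' @return `data.frame` with columns `pos`, `count`, `coverage`,
#'   `count_normalized`.
#' @export
positional_counts <- function(mapped, loci, group = NULL) {
  mat <- loci[loci$feature_kind == "mature", , drop = FALSE]
  if (!is.null(group)) {
    mat <- mat[mat$name %in% group, , drop = FALSE]
    mapped <- mapped[mapped$mirna_name %in% group, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop_valid("empty miRNA group")
  mapped <- mapped[mapped$level == "mature", , drop = FALSE]
  lens <- mat$end - mat$start + 1L
  maxlen <- max(lens)
  counts <- integer(maxlen)
  for (i in seq_len(nrow(mapped))) {
    span <- seq(mapped$mature_pos[i], mapped$mature_last[i])
    span <- span[span >= 1L & span <= maxlen]
    counts[span] <- counts[span] + 1L
  }
  coverage <- vapply(seq_len(maxlen), function(p) mean(lens >= p), numeric(1))
  data.frame(
    pos = seq_len(maxlen),
    count = counts,
    coverage = coverage,
    count_normalized = ifelse(coverage > 0, counts / coverage, NA_real_)
  )
}

#' Variant density per region (base pairs per variant)
#'
#' @param mapped Mapped variant table with a `region` column (or a named
#'   integer vector of pre-tabulated per-region counts).
#' @param region_lengths Named numeric vector of total region lengths (bp).
#' @return `data.frame` with `region`, `n_variants`, `length_bp`,
#'   `bp_per_variant` (`NA` for zero-variant regions).
#' @export
region_density <- function(mapped, region_lengths) {
  regions <- names(region_lengths)
  stopifnot(!is.null(regions), all(region_lengths > 0))
  region_counts <- if (is.data.frame(mapped)) {
    table(mapped$region)
  } else mapped
  cnt <- ifelse(regions %in% names(region_counts),
                as.numeric(region_counts[regions]), 0)
  data.frame(
    region = regions,
    n_variants = cnt,
    length_bp = as.numeric(region_lengths),
    bp_per_variant = ifelse(cnt > 0, region_lengths / cnt, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Fisher exact test comparing two region variant densities
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[count_a, len_a - count_a], [count_b, len_b - count_b]]`, treating
#' each base pair of a region as variant-bearing or not.
#'
#' @param count_a,len_a Variant count and total bp of region A.
#' @param count_b,len_b Variant count and total bp of region B.
#' @return List with `odds_ratio` (sample odds ratio; `NA` when undefined)
#'   and `p_value`.
#' @export
density_fisher <- function(count_a, len_a, count_b, len_b) {
  tab <- matrix(c(count_a, len_a - count_a, count_b, len_b - count_b),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop_valid("negative cell in density table")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = if (is.finite(or)) or else NA_real_,
       p_value = ft$p.value)
}
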