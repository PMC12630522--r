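## Statistics downstream of conservation scoring: arm comparisons, APA
## analyses, AF-distribution tests, copy-number tests, coverage curves.

#' Build per-precursor arm records from a score table
#'
#' Joins 5p and 3p OCS values (and optional per-arm target counts) per
#' precursor for precursors with both arms scored.
#'
#' @param records Score table from [score_all()].
#' @param groups Collapsed groups from [collapse_identical_matures()].
#' @param loci Locus table (mature rows link arms to precursors).
#' @param target_counts Optional `data.frame` with `mirna`, `n_targets`.
#' @return `data.frame` with `precursor`, `ocs_5p`, `ocs_3p`, `delta`,
#'   `targets_5p`, `targets_3p`.
#' @export
arm_records <- function(records, groups, loci, target_counts = NULL) {
  mat <- loci[loci$feature_kind == "mature", , drop = FALSE]
  mat$group <- groups$group[match(mat$id, groups$id)]
  mat$ocs <- records$OCS[match(mat$group, records$name)]
  tc <- function(nm) {
    if (is.null(target_counts)) return(NA_integer_)
    i <- match(nm, target_counts$mirna)
    ifelse(is.na(i), NA_integer_, target_counts$n_targets[i])
  }
  pres <- unique(mat$derives_from)
  out <- lapply(pres, function(p) {
    kids <- mat[mat$derives_from == p, , drop = FALSE]
    a5 <- kids[kids$arm == "5p", , drop = FALSE]
    a3 <- kids[kids$arm == "3p", , drop = FALSE]
    if (nrow(a5) != 1L || nrow(a3) != 1L) return(NULL)
    if (is.na(a5$ocs) || is.na(a3$ocs)) return(NULL)
    data.frame(precursor = p, ocs_5p = a5$ocs, ocs_3p = a3$ocs,
               delta = a5$ocs - a3$ocs,
               targets_5p = tc(a5$group), targets_3p = tc(a3$group),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(precursor = character(0),
                                      ocs_5p = numeric(0), ocs_3p = numeric(0),
                                      delta = numeric(0),
                                      targets_5p = integer(0),
                                      targets_3p = integer(0))
  rownames(res) <- NULL
  res
}

#' Permutation test for balanced conservation between miRNA arms
#'
#' Observed statistic: mean |OCS_5p - OCS_3p| over precursors with both
#' arms. The null re-pairs 5p and 3p scores at random across precursors;
#' the lower-tail p-value `(1 + #{null <= observed}) / (n_perm + 1)` asks
#' whether arm differences are smaller than expected under random
#' pairing.
#'
#' @param arms Arm table from [arm_records()] (>= 10 rows).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `observed`, `p_value`, `n`, `n_perm`.
#' @export
arm_delta_permutation <- function(arms, n_perm = 999L, seed = 1L) {
  if (nrow(arms) < 10L) stop_valid("need >= 10 precursors with both arms")
  if (n_perm < 100L) stop_valid("n_perm must be >= 100")
  obs <- mean(abs(arms$ocs_5p - arms$ocs_3p))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(abs(arms$ocs_5p - sample(arms$ocs_3p)))
    }, numeric(1))
  })
  list(observed = obs,
       p_value = (1 + sum(nulls <= obs)) / (n_perm + 1),
       n = nrow(arms), n_perm = n_perm)
}

#' Do more-conserved arms have more targets? Binned counts + permutation
#'
#' Precursors with both arms are binned by |OCS delta| quantiles; within
#' each bin, the precursors where the more-conserved arm has strictly more
#' targets are counted against those where it has strictly fewer
#' (precursors with equal arm OCS are excluded). Significance of the
#' total more-conserved-wins count comes from randomly swapping the two
#' arms' target counts within each precursor (upper tail, add-one
#' estimator).
#'
#' @param arms Arm table with target counts.
#' @param n_bins Number of |delta| quantile bins.
#' @param n_perm Permutations.
#' @param seed RNG seed.
#' @return List with `bins` (per-bin `n`, `more`, `fewer`), `observed`
#'   (total more-conserved-wins), `p_value`.
#' @export
arm_target_bins <- function(arms, n_bins = 4L, n_perm = 999L, seed = 1L) {
  arms <- arms[!is.na(arms$targets_5p) & !is.na(arms$targets_3p), ,
               drop = FALSE]
  tied <- arms$delta == 0
  if (any(tied)) {
    message(sprintf("excluding %d precursor(s) with equal arm OCS",
                    sum(tied)))
    arms <- arms[!tied, , drop = FALSE]
  }
  if (nrow(arms) < n_bins) stop_valid("too few precursors for %d bins", n_bins)
  absd <- abs(arms$delta)
  br <- stats::quantile(absd, probs = seq(0, 1, length.out = n_bins + 1L))
  br[1L] <- -Inf; br[length(br)] <- Inf
  bin <- cut(absd, breaks = unique(br), labels = FALSE)
  win <- function(t5, t3) {
    tw <- ifelse(arms$delta > 0, t5, t3)   # targets of more-conserved arm
    tl <- ifelse(arms$delta > 0, t3, t5)
    cbind(more = tw > tl, fewer = tw < tl)
  }
  w <- win(arms$targets_5p, arms$targets_3p)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(bin = b, n = sum(bin == b),
               more = sum(w[bin == b, "more"]),
               fewer = sum(w[bin == b, "fewer"]))
  }))
  obs <- sum(w[, "more"])
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flip <- sample(c(TRUE, FALSE), nrow(arms), replace = TRUE)
      t5 <- ifelse(flip, arms$targets_3p, arms$targets_5p)
      t3 <- ifelse(flip, arms$targets_5p, arms$targets_3p)
      sum(win(t5, t3)[, "more"])
    }, numeric(1))
  })
  list(bins = bins, observed = obs,
       p_value = (1 + sum(nulls >= obs)) / (n_perm + 1))
}

#' Representative APA site per gene
#'
#' The representative alternative-polyadenylation site is the one with the
#' highest read support; ties break by the smallest UTR position.
#'
#' @param apa `data.frame` with `gene`, `utr_pos`, `read_support`.
#' @return `data.frame` with `gene`, `representative_pos`, `n_sites`.
#' @export
representative_apa <- function(apa) {
  apa <- apa[order(apa$gene, -apa$read_support, apa$utr_pos), , drop = FALSE]
  n <- table(apa$gene)
  rep1 <- apa[!duplicated(apa$gene), , drop = FALSE]
  data.frame(gene = rep1$gene, representative_pos = rep1$utr_pos,
             n_sites = as.integer(n[rep1$gene]), stringsAsFactors = FALSE)
}

#' Fraction of binding sites upstream of the representative APA site
#'
#' Pooled over the target genes of a miRNA group, restricted to genes with
#' >= 2 APA sites; a site counts as upstream when its start coordinate is
#' strictly smaller than the representative APA position.
#'
#' @param sites Site table (`gene`, `site_start`).
#' @param apa APA table (`gene`, `utr_pos`, `read_support`).
#' @return List with `ratio` (`NA` when no sites), `n_sites`, `n_genes`.
#' @export
apa_upstream_ratio <- function(sites, apa) {
  rep_apa <- representative_apa(apa)
  rep_apa <- rep_apa[rep_apa$n_sites >= 2L, , drop = FALSE]
  sites <- sites[sites$gene %in% rep_apa$gene, , drop = FALSE]
  if (nrow(sites) == 0L) {
    return(list(ratio = NA_real_, n_sites = 0L, n_genes = 0L))
  }
  rpos <- rep_apa$representative_pos[match(sites$gene, rep_apa$gene)]
  list(ratio = mean(sites$site_start < rpos),
       n_sites = nrow(sites),
       n_genes = length(unique(sites$gene)))
}

#' Fisher test: genes lacking APA among HC vs LC miRNA targets
#'
#' Two-sided Fisher exact test on
#' `[[hc_lacking, hc_total - hc_lacking], [lc_lacking, lc_total - lc_lacking]]`.
#'
#' @param hc_lacking,hc_total Counts for the highly conserved group.
#' @param lc_lacking,lc_total Counts for the least conserved group.
#' @return List with `prop_hc`, `prop_lc`, `odds_ratio`, `p_value`.
#' @export
apa_fisher <- function(hc_lacking, hc_total, lc_lacking, lc_total) {
  tab <- matrix(c(hc_lacking, hc_total - hc_lacking,
                  lc_lacking, lc_total - lc_lacking), nrow = 2L,
                byrow = TRUE)
  if (any(tab < 0)) stop_valid("negative cell in APA table")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(prop_hc = hc_lacking / hc_total,
       prop_lc = lc_lacking / lc_total,
       odds_ratio = if (is.finite(or)) or else NA_real_,
       p_value = ft$p.value)
}

#' Mann-Whitney comparison of AF distributions between two regions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on the allele
#' frequencies of mapped variants in two region sets, optionally for one
#' population's AF column.
#'
#' @param mapped Mapped variant table.
#' @param regions_a,regions_b Character vectors of region labels defining
#'   the two groups (e.g. `c("lower_stem_5p","lower_stem_3p",
#'   "terminal_loop")` vs `c("seed","non_seed")`).
#' @param population Population code or `"joint"`.
#' @param alternative Test sidedness (default two-sided).
#' @return List with `statistic` (U), `p_value`, `n_a`, `n_b`.
#' @export
af_region_comparison <- function(mapped, regions_a, regions_b,
                                 population = "joint",
                                 alternative = "two.sided") {
  af_col <- if (identical(population, "joint")) "af_joint" else
    paste0("af_", population)
  xa <- mapped[[af_col]][mapped$region %in% regions_a]
  xb <- mapped[[af_col]][mapped$region %in% regions_b]
  if (!identical(population, "joint")) {
    xa <- xa[xa > 0]; xb <- xb[xb > 0]
  }
  if (length(xa) == 0L || length(xb) == 0L) {
    stop_valid("both regions must contain variants")
  }
  wt <- suppressWarnings(stats::wilcox.test(xa, xb,
                                            alternative = alternative))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # fully tied samples carry no evidence
  list(statistic = unname(wt$statistic), p_value = p,
       n_a = length(xa), n_b = length(xb))
}

#' Rank-sum test of OCS between multi-copy and single-copy miRNAs
#'
#' @param records Score table with `OCS` and `n_copies` (zero-variant
#'   records are excluded).
#' @param alternative Test sidedness (default two-sided).
#' @return List with `statistic`, `p_value`, `n_multi`, `n_single`,
#'   `median_multi`, `median_single`.
#' @export
copy_number_test <- function(records, alternative = "two.sided") {
  records <- records[!records$zero_variant, , drop = FALSE]
  multi <- records$OCS[records$n_copies > 1L]
  single <- records$OCS[records$n_copies == 1L]
  if (length(multi) == 0L || length(single) == 0L) {
    stop_valid("both copy-number groups must be nonempty")
  }
  wt <- suppressWarnings(stats::wilcox.test(multi, single,
                                            alternative = alternative))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # fully tied samples carry no evidence
  list(statistic = unname(wt$statistic), p_value = p,
       n_multi = length(multi), n_single = length(single),
       median_multi = stats::median(multi),
       median_single = stats::median(single))
}

#' Cumulative confidence coverage along the OCS ranking
#'
#' Sorting miRNAs by descending OCS (ties by name), reports at each rank
#' the cumulative fraction of each label class (e.g. mirGeneDB
#' accepted/rejected) covered so far. Curves are monotone non-decreasing
#' and reach 1 for every class.
#'
#' @param records Score table (`name`, `OCS`).
#' @param labels Named character vector mapping miRNA name to class label
#'   for the labelled subset.
#' @return `data.frame` with `rank`, `name`, `OCS`, `label`, one cumulative
#'   fraction column per class.
#' @export
confidence_coverage_curve <- function(records, labels) {
  lab <- labels[names(labels) %in% records$name]
  if (length(lab) == 0L) stop_valid("no labelled miRNAs among the records")
  ord <- order(-records$OCS, records$name)
  rec <- records[ord, , drop = FALSE]
  rec$label <- ifelse(rec$name %in% names(lab), lab[rec$name], NA_character_)
  out <- data.frame(rank = seq_len(nrow(rec)), name = rec$name,
                    OCS = rec$OCS, label = rec$label,
                    stringsAsFactors = FALSE)
  for (cl in sort(unique(lab))) {
    tot <- sum(lab == cl)
    out[[paste0("cum_", cl)]] <-
      cumsum(!is.na(rec$label) & rec$label == cl) / tot
  }
  out
}
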