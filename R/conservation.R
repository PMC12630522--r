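## Component conservation scores and the weighted Overall Conservation
## Score (OCS) per mature miRNA, overall and per population.

#' Component conservation scores for one mature miRNA group
#'
#' Given the variants mapped onto one (possibly multi-locus) mature miRNA
#' of length `L`, computes
#' \itemize{
#'   \item SCS: `1 - sum(f_s)/n_s`, the mean-AF-based seed conservation
#'     over the `n_s` seed variants (positions 2-7);
#'   \item NSCS: the same over the `n_ns` non-seed variants;
#'   \item PCS: `1 - p_v/L`, where `p_v` is the number of distinct mature
#'     positions carrying at least one variant (a deletion spanning k
#'     positions contributes k positions);
#'   \item TVS: `1 - v_t/L`, where `v_t` is the total variant count.
#' }
#' With no seed (or non-seed) variants the corresponding score is 1:
#' absence of variants is maximal conservation. PCS and TVS are clamped to
#' `[0, 1]` (dense multiallelic sites can push `v_t` above `L`). An empty
#' variant set flags the record `zero_variant`.
#'
#' @param mapped Mature-level mapped variants of the group (may have 0
#'   rows); must carry `region`, `mature_pos`, `mature_last` and the AF
#'   column named by `af_col`.
#' @param L Mature length in nucleotides.
#' @param af_col Name of the AF column used as `f` (default joint AF).
#' @return One-row `data.frame` with the counts and component scores.
#' @export
component_scores <- function(mapped, L, af_col = "af_joint") {
  if (length(L) != 1L || !is.finite(L) || L <= 0) {
    stop_valid("mature length L must be a positive number")
  }
  v_t <- nrow(mapped)
  if (v_t == 0L) {
    return(data.frame(L = L, n_s = 0L, n_ns = 0L, p_v = 0L, v_t = 0L,
                      SCS = 1, NSCS = 1, PCS = 1, TVS = 1,
                      zero_variant = TRUE))
  }
  af <- mapped[[af_col]]
  seed <- mapped$region == "seed"
  n_s <- sum(seed); n_ns <- sum(!seed)
  scs <- if (n_s > 0) 1 - sum(af[seed]) / n_s else 1
  nscs <- if (n_ns > 0) 1 - sum(af[!seed]) / n_ns else 1
  pos <- unique(unlist(lapply(seq_len(v_t), function(i)
    seq(mapped$mature_pos[i], mapped$mature_last[i]))))
  pos <- pos[pos >= 1L & pos <= L]
  p_v <- length(pos)
  data.frame(
    L = L, n_s = n_s, n_ns = n_ns, p_v = p_v, v_t = v_t,
    SCS = clamp01(scs), NSCS = clamp01(nscs),
    PCS = clamp01(1 - p_v / L), TVS = clamp01(1 - v_t / L),
    zero_variant = FALSE
  )
}

#' Validate a weight combination for the OCS
#'
#' Weights `(alpha, beta, gamma, delta)` for SCS/NSCS/PCS/TVS must be
#' positive, sum to 1, and satisfy `alpha > beta` (the seed weight exceeds
#' the non-seed weight).
#'
#' @param weights Numeric vector of length 4 (alpha, beta, gamma, delta).
#' @return The weights, named, invisibly on success.
#' @export
validate_weights <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) != 4L || any(!is.finite(weights))) {
    stop_valid("weights must be 4 finite numbers (alpha, beta, gamma, delta)")
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights <= 0) ||
      weights[1L] <= weights[2L]) {
    stop_valid(paste0("invalid weights (%s): need sum 1, each > 0, ",
                      "and alpha > beta"),
               paste(weights, collapse = ", "))
  }
  names(weights) <- c("alpha", "beta", "gamma", "delta")
  invisible(weights)
}

#' Overall Conservation Score from component scores
#'
#' `OCS = alpha*SCS + beta*NSCS + gamma*PCS + delta*TVS`. Zero-variant
#' records receive OCS 1 regardless of weights (they are excluded from
#' downstream analyses).
#'
#' @param record Data frame of component scores (columns `SCS`, `NSCS`,
#'   `PCS`, `TVS`, `zero_variant`).
#' @param weights Weight vector, validated by [validate_weights()].
#' @return Numeric OCS in `[0, 1]`, vectorized over rows of `record`.
#' @export
ocs <- function(record, weights) {
  w <- validate_weights(weights)
  out <- w[["alpha"]] * record$SCS + w[["beta"]] * record$NSCS +
    w[["gamma"]] * record$PCS + w[["delta"]] * record$TVS
  out[record$zero_variant] <- 1
  out
}

#' Score all mature miRNA groups
#'
#' Computes component scores and OCS for every collapsed mature miRNA
#' name. In population mode (`population != "joint"`), only variants with
#' that population's AF > 0 are considered observed, and the population AF
#' replaces the joint AF in SCS/NSCS; a miRNA with no observed variants in
#' the population becomes `zero_variant` there (OCS 1, flagged excluded).
#' Multi-locus groups pool variants across loci, de-duplicated by
#' (locus, genomic position, ref, alt).
#'
#' @param mapped Mapped variants from [map_variants()].
#' @param groups Collapsed mature groups from
#'   [collapse_identical_matures()]; each locus `id` carries a `group`
#'   name, shared `sequence` and `n_copies`.
#' @param weights OCS weight vector.
#' @param population Population code (must have an `af_<population>`
#'   column) or `"joint"`.
#' @return `data.frame` with one row per group: `name`, counts, component
#'   scores, `OCS`, `zero_variant`, `n_copies`, `population`.
#' @export
score_all <- function(mapped, groups, weights, population = "joint") {
  validate_weights(weights)
  af_col <- if (identical(population, "joint")) "af_joint" else
    paste0("af_", population)
  if (!af_col %in% names(mapped) && nrow(mapped) > 0) {
    stop_valid("unknown population code '%s' (no column '%s')",
               population, af_col)
  }
  mm <- mapped[mapped$level == "mature", , drop = FALSE]
  mm <- mm[mm$mirna_id %in% groups$id, , drop = FALSE]
  mm$group <- groups$group[match(mm$mirna_id, groups$id)]
  if (!identical(population, "joint") && nrow(mm) > 0) {
    mm <- mm[mm[[af_col]] > 0, , drop = FALSE]
  }
  gnames <- sort(unique(groups$group))
  recs <- lapply(gnames, function(g) {
    ids <- groups$id[groups$group == g]
    L <- nchar(groups$sequence[groups$group == g][1L])
    gv <- mm[mm$group == g, , drop = FALSE]
    if (nrow(gv) > 1L) {
      gv <- gv[!duplicated(gv[, c("mirna_id", "pos", "ref", "alt")]), ,
               drop = FALSE]
    }
    rec <- component_scores(gv, L, af_col = af_col)
    rec$name <- g
    rec$n_copies <- length(ids)
    rec
  })
  res <- do.call(rbind, recs)
  res$OCS <- ocs(res, weights)
  res$population <- population
  res[, c("name", "L", "n_s", "n_ns", "p_v", "v_t",
          "SCS", "NSCS", "PCS", "TVS", "OCS",
          "zero_variant", "n_copies", "population")]
}

#' Top and bottom conserved miRNA groups by OCS
#'
#' Selects the highly conserved (HC) and least conserved (LC) fractions:
#' the top and bottom `floor(t * N)` miRNAs by OCS among the `N` records
#' with variant data (zero-variant records are excluded). Ties at the cut
#' are broken by lexicographic name order.
#'
#' @param records Score table from [score_all()].
#' @param fraction Fraction `t` in `(0, 0.5)` (default 0.05).
#' @return List with character vectors `hc` and `lc`.
#' @export
top_bottom_groups <- function(records, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5) {
    stop_valid("fraction must lie in (0, 0.5)")
  }
  records <- records[!records$zero_variant, , drop = FALSE]
  n <- nrow(records)
  k <- floor(fraction * n)
  if (k < 1L) stop_valid("fraction * N < 1: no miRNAs selected")
  ord_hi <- order(-records$OCS, records$name)
  ord_lo <- order(records$OCS, records$name)
  list(hc = records$name[ord_hi][seq_len(k)],
       lc = records$name[ord_lo][seq_len(k)])
}
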