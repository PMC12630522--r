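## Independent oracles and small in-code fixtures shared by the tests.

## Exact two-sided Fisher p by hypergeometric enumeration: sum the
## probabilities of all tables (at fixed margins) no more likely than the
## observed one. Independent of stats::fisher.test.
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  xs <- max(0L, k - n):min(k, m)
  probs <- vapply(xs, function(x) dhyper(x, m, n, k), numeric(1))
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Brute-force enumeration of weight compositions: all (a,b,c,d) in
## integer multiples of `step` summing to 1 with every part positive and
## a > b, by exhaustive scan.
grid_oracle <- function(step) {
  m <- round(1 / step)
  out <- list()
  for (a in 1:m) for (b in 1:m) for (cc in 1:m) for (d in 1:m) {
    if (a + b + cc + d == m && a > b) {
      out[[length(out) + 1L]] <- c(a, b, cc, d) * step
    }
  }
  out
}

## A minimal two-feature locus table: one plus-strand precursor with a
## 5p mature arm, in genomic coordinates.
tiny_loci <- function() {
  data.frame(
    id = c("MI1", "MAT1"),
    name = c("mir-x", "mir-x-5p"),
    chrom = "chr1",
    start = c(100L, 105L),
    end = c(179L, 126L),
    strand = "+",
    feature_kind = c("precursor", "mature"),
    derives_from = c("", "MI1"),
    arm = c("unknown", "5p"),
    stringsAsFactors = FALSE
  )
}

## Variant-table builder with per-population AF columns.
make_variants <- function(chrom, pos, ref, alt, af, pops = NULL) {
  v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  af_joint = af, stringsAsFactors = FALSE)
  if (!is.null(pops)) for (p in names(pops)) v[[paste0("af_", p)]] <- pops[[p]]
  v$pass_qc <- TRUE; v$in_wgs <- TRUE; v$in_wes <- FALSE
  v$af_discrepant <- FALSE
  v
}

## Mature-level mapped-variant rows for scoring tests, without running
## the genomic projection.
make_mapped <- function(mature_pos, af, region = NULL,
                        mature_last = mature_pos) {
  n <- length(mature_pos)
  region <- region %||% ifelse(mature_pos >= 2 & mature_pos <= 7,
                               "seed", "non_seed")
  data.frame(
    chrom = rep("chr1", n), pos = 1000L + seq_len(n),
    ref = rep("A", n), alt = rep("G", n), af_joint = af,
    mirna_id = rep("MAT1", n), mirna_name = rep("mir-x-5p", n),
    arm = rep("5p", n), level = rep("mature", n), region = region,
    mature_pos = as.integer(mature_pos),
    mature_last = as.integer(mature_last),
    ref_rna = rep("A", n), alt_rna = rep("G", n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Standard pipeline over a generated fixture.
run_scoring <- function(fx, weights = c(0.2, 0.1, 0.6, 0.1)) {
  t <- fx$tables
  mapped <- suppressMessages(map_variants(t$variants, t$loci))
  groups <- collapse_identical_matures(t$loci, t$sequences)
  rec <- score_all(mapped, groups, weights)
  list(mapped = mapped, groups = groups, records = rec)
}
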