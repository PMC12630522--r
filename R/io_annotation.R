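## Reading miRNA annotation and variants; projecting variants onto
## miRNA-sense coordinates and hairpin regions.

#' Read a miRBase-dialect GFF3 of miRNA annotations
#'
#' Parses `miRNA_primary_transcript` (precursor hairpin) and `miRNA`
#' (mature arm) features into a locus table. Arm labels (`5p`/`3p`) are
#' taken from a `-5p`/`-3p` suffix on the feature `Name` when present.
#' Mature-to-precursor links are resolved through the `Derives_from`
#' attribute and validated (same chromosome and strand, full containment).
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with one row per locus and columns
#'   `id`, `name`, `chrom`, `start`, `end` (1-based inclusive), `strand`,
#'   `feature_kind` (`"precursor"` or `"mature"`), `derives_from`, `arm`
#'   (`"5p"`, `"3p"` or `"unknown"`).
#' @export
read_mirna_gff <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop_valid("malformed GFF3 line %d in '%s': expected 9 tab-separated fields",
               bad, path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  kind <- as.character(gr$type)
  keep <- kind %in% c("miRNA_primary_transcript", "miRNA")
  gr <- gr[keep]
  kind <- kind[keep]
  if (length(gr) == 0L) stop_valid("no miRNA features found in '%s'", path)
  name <- as.character(gr$Name %||% gr$ID)
  derives <- if ("Derives_from" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Derives_from, function(x)
      if (length(x)) as.character(x)[1L] else "", character(1))
  } else rep("", length(gr))
  loci <- data.frame(
    id = as.character(gr$ID),
    name = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_kind = ifelse(kind == "miRNA", "mature", "precursor"),
    derives_from = ifelse(is.na(derives), "", derives),
    arm = ifelse(grepl("-5p$", name), "5p",
                 ifelse(grepl("-3p$", name), "3p", "unknown")),
    stringsAsFactors = FALSE
  )
  validate_loci(loci)
  loci
}

validate_loci <- function(loci) {
  stopifnot(all(loci$start <= loci$end))
  mat <- loci[loci$feature_kind == "mature" & nzchar(loci$derives_from), ]
  pre <- loci[loci$feature_kind == "precursor", ]
  if (nrow(mat)) {
    idx <- match(mat$derives_from, pre$id)
    if (anyNA(idx)) {
      stop_valid("mature locus '%s' has unresolvable Derives_from '%s'",
                 mat$id[which(is.na(idx))[1L]],
                 mat$derives_from[which(is.na(idx))[1L]])
    }
    ok <- mat$chrom == pre$chrom[idx] & mat$strand == pre$strand[idx] &
      mat$start >= pre$start[idx] & mat$end <= pre$end[idx]
    if (!all(ok)) {
      stop_valid("mature locus '%s' is not contained in its precursor '%s'",
                 mat$id[which(!ok)[1L]], mat$derives_from[which(!ok)[1L]])
    }
  }
  invisible(loci)
}

#' Write a locus table back to GFF3
#'
#' Inverse of [read_mirna_gff()]; a written file re-reads to an identical
#' locus table.
#'
#' @param loci Locus table from [read_mirna_gff()].
#' @param path Output path.
#' @export
write_mirna_gff <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(loci$start, loci$end),
    strand = loci$strand
  )
  gr$source <- "mirconserve"
  gr$type <- ifelse(loci$feature_kind == "mature",
                    "miRNA", "miRNA_primary_transcript")
  gr$ID <- loci$id
  gr$Name <- loci$name
  df <- ifelse(nzchar(loci$derives_from), loci$derives_from, NA_character_)
  gr$Derives_from <- df
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read genomic variants with joint and per-population allele frequencies
#'
#' Accepts a TSV with columns `chrom`, `pos`, `ref`, `alt`, `af_joint`,
#' optional QC flags (`pass_qc`, `in_wgs`, `in_wes`, `af_discrepant`) and
#' one `af_<pop>` column per population, or a VCF whose INFO fields carry
#' the same content (requires the VariantAnnotation package; multiallelic
#' records are split per alternate allele before filtering).
#'
#' Rows failing an enabled filter are dropped and the per-filter exclusion
#' counts are reported via `message()`.
#'
#' @param path Input TSV or VCF path.
#' @param require_pass Drop records with `pass_qc == FALSE` (quality control
#'   for genomes).
#' @param require_wgs Drop records absent from whole-genome sequencing data.
#' @param drop_discrepant Drop records flagged as having discrepant AF
#'   between WGS and WES call sets.
#' @param vcf_info INFO field names used when `path` is a VCF: a list with
#'   `af_joint`, `pop_prefix`, `wgs`, `wes`, `discrepant` entries.
#' @return A `data.frame` of variant records; the population codes found
#'   are attached as `attr(, "populations")`.
#' @export
read_variants <- function(path, require_pass = TRUE, require_wgs = FALSE,
                          drop_discrepant = FALSE,
                          vcf_info = list(af_joint = "AF", pop_prefix = "AF_",
                                          wgs = "WGS", wes = "WES",
                                          discrepant = "AF_DISCREPANT")) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext %in% c("vcf", "gz", "bgz")) {
    read_variants_vcf(path, vcf_info)
  } else {
    read_variants_tsv(path)
  }
  validate_variants(v)
  n0 <- nrow(v)
  drop_pass <- drop_wgs <- drop_disc <- 0L
  if (require_pass) {
    keep <- v$pass_qc
    drop_pass <- sum(!keep); v <- v[keep, , drop = FALSE]
  }
  if (require_wgs) {
    keep <- v$in_wgs
    drop_wgs <- sum(!keep); v <- v[keep, , drop = FALSE]
  }
  if (drop_discrepant) {
    keep <- !v$af_discrepant
    drop_disc <- sum(!keep); v <- v[keep, , drop = FALSE]
  }
  message(sprintf(
    "read %d variant records; excluded %d (pass_qc), %d (wgs), %d (discrepant AF); %d retained",
    n0, drop_pass, drop_wgs, drop_disc, nrow(v)))
  rownames(v) <- NULL
  v
}

read_variants_tsv <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("chrom", "pos", "ref", "alt", "af_joint")
  miss <- setdiff(mandatory, names(v))
  if (length(miss)) {
    stop_valid("variant table '%s' is missing mandatory column(s): %s",
               path, paste(miss, collapse = ", "))
  }
  for (fl in c("pass_qc", "in_wgs")) if (is.null(v[[fl]])) v[[fl]] <- TRUE
  for (fl in c("in_wes", "af_discrepant")) if (is.null(v[[fl]])) v[[fl]] <- FALSE
  reserved <- c("af_joint", "af_discrepant")
  popcols <- setdiff(grep("^af_", names(v), value = TRUE), reserved)
  attr(v, "populations") <- sub("^af_", "", popcols)
  v$chrom <- as.character(v$chrom)
  v
}

read_variants_vcf <- function(path, vcf_info) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_valid("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::expand(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  grab <- function(key, default) {
    if (!is.null(key) && key %in% names(info)) {
      x <- info[[key]]
      if (is.list(x) || methods::is(x, "List")) {
        x <- vapply(x, function(e) if (length(e)) e[[1L]] else default,
                    default)
      }
      x
    } else rep(default, length(rr))
  }
  popcols <- grep(paste0("^", vcf_info$pop_prefix), names(info), value = TRUE)
  popcols <- setdiff(popcols, c(vcf_info$af_joint, vcf_info$discrepant))
  v <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    af_joint = as.numeric(grab(vcf_info$af_joint, NA_real_)),
    stringsAsFactors = FALSE
  )
  for (pc in popcols) {
    pop <- tolower(sub(paste0("^", vcf_info$pop_prefix), "", pc))
    v[[paste0("af_", pop)]] <- as.numeric(grab(pc, 0))
  }
  v$pass_qc <- as.character(rr$FILTER) %in% c("PASS", ".", "")
  v$in_wgs <- as.logical(grab(vcf_info$wgs, TRUE))
  v$in_wes <- as.logical(grab(vcf_info$wes, FALSE))
  v$af_discrepant <- as.logical(grab(vcf_info$discrepant, FALSE))
  attr(v, "populations") <- tolower(sub(paste0("^", vcf_info$pop_prefix), "",
                                        popcols))
  v
}

validate_variants <- function(v) {
  if (any(!nzchar(v$ref)) || any(!nzchar(v$alt)) ||
      any(grepl("[^ACGT]", v$ref)) || any(grepl("[^ACGT]", v$alt))) {
    stop_valid("ref/alt alleles must be nonempty strings over {A,C,G,T}")
  }
  if (any(v$ref == v$alt)) stop_valid("ref and alt alleles must differ")
  assert_fraction(v$af_joint, "af_joint")
  for (pc in grep("^af_", names(v), value = TRUE)) {
    if (pc != "af_discrepant") assert_fraction(v[[pc]], pc)
  }
  invisible(v)
}

## ---- hairpin partition -----------------------------------------------

#' Partition a precursor hairpin into stems, loop and arms
#'
#' Splits the precursor span into `lower_stem_5p` (5' of the 5p arm),
#' `arm_5p`, `terminal_loop`, `arm_3p` and `lower_stem_3p`, in
#' transcription (miRNA-sense) order. When only one arm is annotated, the
#' opposite arm is inferred so that the miRNA duplex carries the canonical
#' 2-nt 3' overhang at both ends: an arm of equal length is placed with
#' its 3'-end offset from the precursor end two nucleotides smaller than
#' the annotated arm's 5'-start offset (and mirrored for a known 3p arm).
#' Inferred arms are flagged and occupy their own partition rows, so loop
#' and stem tallies never include them.
#'
#' @param precursor One-row locus table for the precursor.
#' @param matures Locus table of its annotated mature arms (1 or 2 rows).
#' @return A `data.frame` with columns `region`, `start`, `end` (genomic,
#'   1-based inclusive) and `inferred`.
#' @export
infer_hairpin_regions <- function(precursor, matures) {
  stopifnot(nrow(precursor) == 1L)
  if (nrow(matures) < 1L || nrow(matures) > 2L) {
    stop_valid("precursor '%s' needs 1 or 2 annotated mature arms, got %d",
               precursor$id, nrow(matures))
  }
  ps <- precursor$start; pe <- precursor$end; st <- precursor$strand
  Lp <- pe - ps + 1L
  if (any(matures$start < ps | matures$end > pe)) {
    stop_valid("mature arm not contained in precursor '%s'", precursor$id)
  }
  to_local <- function(g) if (st == "-") pe - g + 1L else g - ps + 1L
  ## local (sense) intervals, ascending
  li <- t(apply(cbind(to_local(matures$start), to_local(matures$end)), 1L,
                sort))
  ord <- order(li[, 1L])
  li <- li[ord, , drop = FALSE]
  arm_lab <- matures$arm[ord]
  inferred <- c(FALSE, FALSE)
  if (nrow(li) == 2L) {
    s5 <- li[1L, 1L]; e5 <- li[1L, 2L]; s3 <- li[2L, 1L]; e3 <- li[2L, 2L]
    if (e5 >= s3) stop_valid("mature arms of '%s' overlap", precursor$id)
  } else {
    La <- li[1L, 2L] - li[1L, 1L] + 1L
    is5p <- if (arm_lab[1L] == "5p") TRUE
            else if (arm_lab[1L] == "3p") FALSE
            else (li[1L, 1L] - 1L) < (Lp - li[1L, 2L])
    if (is5p) {
      s5 <- li[1L, 1L]; e5 <- li[1L, 2L]
      e3 <- min(Lp, Lp - (s5 - 1L) + 2L)
      s3 <- e3 - La + 1L
      inferred[2L] <- TRUE
    } else {
      s3 <- li[1L, 1L]; e3 <- li[1L, 2L]
      s5 <- max(1L, (Lp - e3) + 3L)
      e5 <- s5 + La - 1L
      inferred[1L] <- TRUE
    }
    if (e5 >= s3) {
      stop_valid("cannot infer opposite arm for '%s': arms would overlap",
                 precursor$id)
    }
  }
  rows <- list(
    c("lower_stem_5p", 1L, s5 - 1L, FALSE),
    c("arm_5p", s5, e5, inferred[1L]),
    c("terminal_loop", e5 + 1L, s3 - 1L, FALSE),
    c("arm_3p", s3, e3, inferred[2L]),
    c("lower_stem_3p", e3 + 1L, Lp, FALSE)
  )
  part <- do.call(rbind, lapply(rows, function(r) {
    data.frame(region = r[[1L]], lstart = as.integer(r[[2L]]),
               lend = as.integer(r[[3L]]),
               inferred = as.logical(r[[4L]]), stringsAsFactors = FALSE)
  }))
  part <- part[part$lstart <= part$lend, , drop = FALSE]
  from_local <- function(l) if (st == "-") pe - l + 1L else ps + l - 1L
  g1 <- from_local(part$lstart); g2 <- from_local(part$lend)
  part$start <- pmin(g1, g2)
  part$end <- pmax(g1, g2)
  part$lstart <- NULL; part$lend <- NULL
  rownames(part) <- NULL
  part[, c("region", "start", "end", "inferred")]
}

#' Flanking intervals of a precursor on its primary transcript
#'
#' Returns the upstream and downstream flank intervals in genomic
#' coordinates. "Upstream" is the 5' side in transcription sense, so for
#' minus-strand precursors it is the higher-coordinate side. When no
#' primary transcript is annotated, a fixed flank width is used per side.
#'
#' @param primary One-row locus table for the primary transcript, or `NULL`.
#' @param precursor One-row locus table for the precursor.
#' @param default_flank Flank width (nt) used when `primary` is `NULL`.
#' @return `data.frame` with columns `region` (`flank_up`/`flank_down`),
#'   `start`, `end`.
#' @export
flank_regions <- function(primary = NULL, precursor, default_flank = 25L) {
  ps <- precursor$start; pe <- precursor$end; st <- precursor$strand
  if (!is.null(primary)) {
    if (primary$start > ps || primary$end < pe ||
        primary$chrom != precursor$chrom || primary$strand != st) {
      stop_valid("precursor '%s' is not contained in its primary transcript",
                 precursor$id)
    }
    lo <- c(primary$start, ps - 1L)
    hi <- c(pe + 1L, primary$end)
  } else {
    lo <- c(ps - default_flank, ps - 1L)
    hi <- c(pe + 1L, pe + default_flank)
  }
  out <- data.frame(
    region = if (st == "-") c("flank_down", "flank_up") else
      c("flank_up", "flank_down"),
    start = c(lo[1L], hi[1L]),
    end = c(lo[2L], hi[2L]),
    stringsAsFactors = FALSE
  )
  out <- out[out$start <= out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- variant projection ----------------------------------------------

#' Project variants onto miRNA loci and hairpin regions
#'
#' Each variant is intersected with mature arms, precursor hairpins and
#' precursor flanks; one output row is emitted per overlapping context, so
#' a variant inside a mature arm also yields a precursor-context row for
#' precursor-level tallies. Mature positions are 1-based, 5'-to-3' on the
#' annotated strand; alleles are reported as miRNA-sense RNA
#' (reverse-complemented for minus-strand loci, T replaced by U). For
#' multi-nucleotide variants the first affected miRNA-sense position is
#' reported (`mature_pos`) together with the last (`mature_last`), and a
#' variant counts as a seed variant if any affected reference position
#' falls in mature positions 2-7.
#'
#' @param variants Variant table from [read_variants()].
#' @param loci Locus table from [read_mirna_gff()].
#' @param default_flank Flank width (nt) when no primary transcript exists.
#' @return `data.frame` of mapped variants with columns of `variants` plus
#'   `mirna_id`, `mirna_name`, `arm`, `level` (`mature`/`precursor`/`flank`),
#'   `region`, `mature_pos`, `mature_last`, `ref_rna`, `alt_rna`.
#' @export
map_variants <- function(variants, loci, default_flank = 25L) {
  validate_loci(loci)
  empty <- mapped_skeleton(variants)
  if (nrow(variants) == 0L || nrow(loci) == 0L) return(empty)
  vgr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L)
  )
  pre <- loci[loci$feature_kind == "precursor", , drop = FALSE]
  mat <- loci[loci$feature_kind == "mature", , drop = FALSE]
  out <- list()

  ## mature-level rows
  if (nrow(mat)) {
    mgr <- GenomicRanges::GRanges(mat$chrom,
                                  IRanges::IRanges(mat$start, mat$end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(vgr, mgr, ignore.strand = TRUE))
    if (length(ov)) {
      vi <- S4Vectors::queryHits(ov); mi <- S4Vectors::subjectHits(ov)
      rows <- variants[vi, , drop = FALSE]
      lstart <- mat$start[mi]; lend <- mat$end[mi]; lstr <- mat$strand[mi]
      span1 <- pmax(rows$pos, lstart)
      span2 <- pmin(rows$pos + nchar(rows$ref) - 1L, lend)
      p1 <- ifelse(lstr == "-", lend - span2 + 1L, span1 - lstart + 1L)
      p2 <- ifelse(lstr == "-", lend - span1 + 1L, span2 - lstart + 1L)
      rows$mirna_id <- mat$id[mi]
      rows$mirna_name <- mat$name[mi]
      rows$arm <- mat$arm[mi]
      rows$level <- "mature"
      rows$mature_pos <- p1
      rows$mature_last <- p2
      rows$region <- ifelse(p1 <= 7L & p2 >= 2L, "seed", "non_seed")
      rows$ref_rna <- allele_to_mirna_sense(rows$ref, lstr)
      rows$alt_rna <- allele_to_mirna_sense(rows$alt, lstr)
      out[[length(out) + 1L]] <- rows
    }
  }

  ## precursor-level and flank rows: assemble every region interval of
  ## every precursor, then overlap once
  if (nrow(pre)) {
    regions <- do.call(rbind, lapply(seq_len(nrow(pre)), function(k) {
      p <- pre[k, , drop = FALSE]
      kids <- mat[mat$derives_from == p$id, , drop = FALSE]
      part <- if (nrow(kids) >= 1L && nrow(kids) <= 2L) {
        infer_hairpin_regions(p, kids)[, c("region", "start", "end")]
      } else {
        data.frame(region = "terminal_loop", start = p$start, end = p$end,
                   stringsAsFactors = FALSE)
      }
      r <- rbind(part, flank_regions(NULL, p, default_flank = default_flank))
      r$pre_idx <- k
      r
    }))
    rgr <- GenomicRanges::GRanges(
      pre$chrom[regions$pre_idx],
      IRanges::IRanges(regions$start, regions$end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(vgr, rgr, ignore.strand = TRUE))
    if (length(ov)) {
      vi <- S4Vectors::queryHits(ov)
      ri <- S4Vectors::subjectHits(ov)
      pk <- regions$pre_idx[ri]
      rows <- variants[vi, , drop = FALSE]
      rows$mirna_id <- pre$id[pk]
      rows$mirna_name <- pre$name[pk]
      rows$arm <- "unknown"
      rows$region <- regions$region[ri]
      rows$level <- ifelse(rows$region %in% c("flank_up", "flank_down"),
                           "flank", "precursor")
      rows$mature_pos <- 0L
      rows$mature_last <- 0L
      rows$ref_rna <- allele_to_mirna_sense(rows$ref, pre$strand[pk])
      rows$alt_rna <- allele_to_mirna_sense(rows$alt, pre$strand[pk])
      out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "populations") <- attr(variants, "populations")
  res
}

mapped_skeleton <- function(variants) {
  res <- variants[0, , drop = FALSE]
  for (col in c("mirna_id", "mirna_name", "arm", "level", "region",
                "ref_rna", "alt_rna")) res[[col]] <- character(0)
  res$mature_pos <- integer(0)
  res$mature_last <- integer(0)
  attr(res, "populations") <- attr(variants, "populations")
  res
}

#' Collapse mature loci with identical sequence under one name
#'
#' Mature miRNAs encoded at multiple genomic loci with an identical
#' sequence are grouped under a single mature name (the lexicographically
#' smallest member name); the copy count distinguishes multi-copy from
#' single-copy miRNAs.
#'
#' @param loci Locus table (mature rows are used).
#' @param sequences Named character vector of miRNA-sense RNA sequences,
#'   names matching locus `id`s.
#' @return `data.frame` with columns `group` (collapsed mature name), `id`,
#'   `locus_name`, `n_copies`, `sequence`.
#' @export
collapse_identical_matures <- function(loci, sequences) {
  mat <- loci[loci$feature_kind == "mature", , drop = FALSE]
  if (!all(mat$id %in% names(sequences))) {
    stop_valid("missing sequence for mature locus '%s'",
               setdiff(mat$id, names(sequences))[1L])
  }
  seqs <- toupper(sequences[mat$id])
  len_ok <- nchar(seqs) == (mat$end - mat$start + 1L)
  if (!all(len_ok)) {
    stop_valid("sequence length mismatch with locus span for '%s'",
               mat$id[which(!len_ok)[1L]])
  }
  groups <- split(seq_len(nrow(mat)), seqs)
  out <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(group = min(mat$name[ix]), id = mat$id[ix],
               locus_name = mat$name[ix], n_copies = length(ix),
               sequence = seqs[ix][1L], stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  out <- out[order(out$group, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
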