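## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_valid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

assert_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_valid("%s must lie in [0, 1]; got %s", what,
               paste(utils::head(x[!is.finite(x) | x < 0 | x > 1], 3),
                     collapse = ", "))
  }
  invisible(x)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

## DNA -> miRNA-sense RNA. For minus-strand loci alleles are
## reverse-complemented before the T->U substitution.
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

revcomp_dna <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

## Allele string (DNA, genomic sense) -> miRNA-sense RNA string.
allele_to_mirna_sense <- function(allele, strand) {
  out <- allele
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp_dna(out[neg])
  dna_to_rna(out)
}

rna_complement <- function(base) {
  unname(c(A = "U", U = "A", G = "C", C = "G")[toupper(base)])
}

is_watson_crick <- function(a, b) {
  !is.na(a) & !is.na(b) & rna_complement(a) == b
}

assert_rna <- function(x, what) {
  bad <- grepl("[^ACGUacgu]", x)
  if (any(bad)) {
    stop_valid("%s contains non-RNA characters: %s", what,
               paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

## Deterministic seeded evaluation that does not disturb the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Sub-stream seeds derived from a master seed, kept within 32-bit range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + match(stream, c(
    "loci", "sequences", "variants", "expression_a", "expression_b",
    "utrs", "targets", "apa", "clinvar", "misc"
  )) * 7919L
}
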