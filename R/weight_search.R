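## Constrained weight-grid enumeration and selection of optimal OCS
## weights by conservation/expression overlap (F1, cross-threshold
## z-scores).

#' Enumerate the constrained OCS weight grid
#'
#' All weight combinations `(alpha, beta, gamma, delta)` on a grid of the
#' given step that sum to 1, with every weight positive and
#' `alpha > beta`. Enumeration uses integer multiples of the step (exact
#' rational arithmetic), in lexicographic order. With the default step of
#' 0.1 the grid has 34 combinations.
#'
#' @param step Grid increment; `1/step` must be an integer.
#' @return `data.frame` with columns `alpha`, `beta`, `gamma`, `delta`.
#' @export
enumerate_grid <- function(step = 0.1) {
  if (step <= 0 || step > 0.5) stop_valid("step must lie in (0, 0.5]")
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9) stop_valid("1/step must be an integer")
  m <- as.integer(round(m))
  out <- list()
  for (a in seq_len(m)) for (b in seq_len(m)) for (cc in seq_len(m)) {
    d <- m - a - b - cc
    if (d >= 1L && a > b) {
      out[[length(out) + 1L]] <- c(a, b, cc, d)
    }
  }
  if (!length(out)) {
    return(data.frame(alpha = numeric(0), beta = numeric(0),
                      gamma = numeric(0), delta = numeric(0)))
  }
  grid <- do.call(rbind, out)
  grid <- grid[order(grid[, 1L], grid[, 2L], grid[, 3L], grid[, 4L]), ,
               drop = FALSE]
  data.frame(alpha = grid[, 1L] * step, beta = grid[, 2L] * step,
             gamma = grid[, 3L] * step, delta = grid[, 4L] * step)
}

#' Top-expressed miRNAs from an expression table
#'
#' Computes mean expression across the value columns (tissues) and returns
#' the top `floor(t * N)` miRNA names within the given universe;
#' ties break by lexicographic name order.
#'
#' @param expression `data.frame` whose first column is the miRNA name and
#'   remaining columns are expression values (one or more tissues).
#' @param fraction Fraction `t` of the universe to select.
#' @param universe Optional character vector restricting the candidate
#'   names (e.g. the intersection with scored miRNAs).
#' @return Character vector of selected miRNA names.
#' @export
top_expressed <- function(expression, fraction, universe = NULL) {
  name <- as.character(expression[[1L]])
  vals <- as.matrix(expression[, -1L, drop = FALSE])
  mean_expr <- rowMeans(vals)
  if (!is.null(universe)) {
    keep <- name %in% universe
    name <- name[keep]; mean_expr <- mean_expr[keep]
  }
  if (length(name) == 0L) stop_valid("empty expression universe")
  k <- floor(fraction * length(name))
  if (k < 1L) stop_valid("fraction * N < 1 in top_expressed")
  name[order(-mean_expr, name)][seq_len(k)]
}

#' F1 overlap between a conserved set and an expressed set
#'
#' Precision is computed over the conserved set, recall over the expressed
#' set; `F1 = 2PR/(P+R)`, 0 when the sets are disjoint.
#'
#' @param conserved,expressed Nonempty character vectors from one universe.
#' @return F1 score in `[0, 1]`.
#' @export
overlap_f1 <- function(conserved, expressed) {
  if (length(conserved) == 0L || length(expressed) == 0L) {
    stop_valid("overlap_f1 requires nonempty sets")
  }
  i <- length(intersect(conserved, expressed))
  if (i == 0L) return(0)
  p <- i / length(conserved)
  r <- i / length(expressed)
  2 * p * r / (p + r)
}

#' Select optimal OCS weights on the constrained grid
#'
#' For every weight combination, the OCS is computed from the component
#' scores; at each conservation/expression threshold the overlap between
#' the top-conserved and top-expressed miRNAs is measured as the F1 score,
#' averaged over the expression datasets. Per threshold, each combination's
#' mean F1 is converted to a z-score across combinations (population
#' standard deviation; a degenerate threshold with zero spread contributes
#' z = 0 for all combinations). The combination with the highest average
#' absolute z-score across thresholds is selected; ties break by higher
#' grand-mean F1, then lexicographically smallest weights. A signed-z
#' selection (`selection = "signed"`) is available since |z| alone would
#' also reward consistent under-performers.
#'
#' Each expression dataset uses its own universe: the intersection of
#' scored (non-zero-variant) and expressed miRNA names, fixed before top
#' fractions are taken.
#'
#' @param components Component-score table from [score_all()] (any valid
#'   weights; only `SCS`/`NSCS`/`PCS`/`TVS`/`zero_variant` are used).
#' @param expression_list List of (typically two) expression tables, first
#'   column the miRNA name.
#' @param thresholds Conservation/expression fractions to test.
#' @param step Grid step for [enumerate_grid()].
#' @param selection `"abs"` (average |z|, default) or `"signed"` (average z).
#' @return List with `selected` (named weight vector), `audit` (combo x
#'   threshold table of mean F1 and z), `avg_abs_z`, `grand_mean_f1`, and
#'   `thresholds`.
#' @export
optimize_weights <- function(components,
                             expression_list,
                             thresholds = c(0.05, 0.1, 0.15, 0.2, 0.25),
                             step = 0.1,
                             selection = c("abs", "signed")) {
  selection <- match.arg(selection)
  grid <- enumerate_grid(step)
  if (nrow(grid) < 2L) stop_valid("weight grid must contain >= 2 combos")
  scored <- components[!components$zero_variant, , drop = FALSE]
  universes <- lapply(expression_list, function(ex)
    intersect(scored$name, as.character(ex[[1L]])))
  if (any(lengths(universes) == 0L)) {
    stop_valid("no shared miRNA names between scores and an expression dataset")
  }
  f1 <- matrix(NA_real_, nrow = nrow(grid), ncol = length(thresholds))
  for (ci in seq_len(nrow(grid))) {
    w <- as.numeric(grid[ci, ])
    score <- ocs(scored, w)
    for (ti in seq_along(thresholds)) {
      t <- thresholds[ti]
      f1s <- vapply(seq_along(expression_list), function(di) {
        uni <- universes[[di]]
        sub <- scored[scored$name %in% uni, , drop = FALSE]
        sc <- score[scored$name %in% uni]
        k <- floor(t * length(uni))
        if (k < 1L) stop_valid("threshold %.2f selects no miRNAs", t)
        conserved <- sub$name[order(-sc, sub$name)][seq_len(k)]
        expressed <- top_expressed(expression_list[[di]], t, universe = uni)
        overlap_f1(conserved, expressed)
      }, numeric(1))
      f1[ci, ti] <- mean(f1s)
    }
  }
  z <- apply(f1, 2L, function(col) {
    s <- stats::sd(col) * sqrt((length(col) - 1) / length(col))
    if (!is.finite(s) || s == 0) rep(0, length(col)) else
      (col - mean(col)) / s
  })
  z <- matrix(z, nrow = nrow(grid))
  crit <- if (selection == "abs") rowMeans(abs(z)) else rowMeans(z)
  grand <- rowMeans(f1)
  ord <- order(-crit, -grand, grid$alpha, grid$beta, grid$gamma, grid$delta)
  best <- ord[1L]
  audit <- cbind(grid,
                 as.data.frame(`colnames<-`(f1, paste0("f1_", thresholds))),
                 as.data.frame(`colnames<-`(z, paste0("z_", thresholds))),
                 avg_abs_z = rowMeans(abs(z)),
                 grand_mean_f1 = grand)
  list(
    selected = validate_weights(as.numeric(grid[best, ])),
    selected_index = best,
    audit = audit,
    avg_abs_z = crit[best],
    grand_mean_f1 = grand[best],
    thresholds = thresholds
  )
}
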