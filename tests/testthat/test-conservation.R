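test_that("component scores follow the defining formulas", {
  ## one seed variant (AF 0.1) + one non-seed variant (AF 0.02), L = 22
  m <- make_mapped(c(3, 15), c(0.1, 0.02))
  r <- component_scores(m, 22)
  expect_equal(r$SCS, 0.9)
  expect_equal(r$NSCS, 0.98)
  expect_equal(r$PCS, 1 - 2 / 22)
  expect_equal(r$TVS, 1 - 2 / 22)
  expect_equal(c(r$n_s, r$n_ns, r$p_v, r$v_t), c(1, 1, 2, 2))
  expect_false(r$zero_variant)

  ## two variants at one position: p_v counts unique positions
  r2 <- component_scores(make_mapped(c(5, 5), c(0.001, 0.002)), 20)
  expect_equal(c(r2$p_v, r2$v_t), c(1, 2))
  expect_equal(r2$PCS, 0.95)
  expect_equal(r2$TVS, 0.90)

  ## no variants: zero_variant flag, all components 1
  r3 <- component_scores(make_mapped(integer(0), numeric(0)), 22)
  expect_true(r3$zero_variant)
  expect_equal(unlist(r3[c("SCS", "NSCS", "PCS", "TVS")]),
               c(SCS = 1, NSCS = 1, PCS = 1, TVS = 1))

  ## a deletion spanning two positions adds both to p_v, one to v_t
  r4 <- component_scores(make_mapped(10, 0.001, mature_last = 11), 22)
  expect_equal(c(r4$p_v, r4$v_t), c(2, 1))

  expect_error(component_scores(make_mapped(1, 0.1), 0), "positive")
})

test_that("OCS is the weighted combination with the zero-variant rule", {
  r <- component_scores(make_mapped(c(3, 15), c(0.1, 0.02)), 22)
  w <- c(0.2, 0.1, 0.6, 0.1)
  expect_equal(ocs(r, w),
               0.2 * 0.9 + 0.1 * 0.98 + 0.7 * (1 - 2 / 22))
  expect_equal(ocs(r, w), 0.91436, tolerance = 1e-4)

  ones <- data.frame(SCS = 1, NSCS = 1, PCS = 1, TVS = 1,
                     zero_variant = FALSE)
  expect_equal(ocs(ones, c(0.4, 0.2, 0.3, 0.1)), 1)
  zeros <- within(ones, { SCS <- 0; NSCS <- 0; PCS <- 0; TVS <- 0 })
  expect_equal(ocs(zeros, w), 0)

  zv <- within(ones, zero_variant <- TRUE)
  expect_equal(ocs(zv, w), 1)

  expect_error(ocs(r, c(0.1, 0.2, 0.6, 0.1)), "alpha > beta")
  expect_error(ocs(r, c(0.5, 0.2, 0.3, 0.1)), "sum 1")
  expect_error(ocs(r, c(0.6, 0.4, 0.0, 0.0)), "each > 0")
})

test_that("OCS matches a direct formula oracle on random variant sets", {
  set.seed(21)
  grid <- enumerate_grid(0.1)
  for (rep in 1:200) {
    L <- sample(20:24, 1)
    n <- sample(0:8, 1)
    pos <- if (n > 0) sample(seq_len(L), n, replace = TRUE) else integer(0)
    af <- runif(n)
    m <- make_mapped(pos, af)
    r <- component_scores(m, L)
    w <- as.numeric(grid[sample(nrow(grid), 1), ])
    got <- ocs(r, w)
    ## independent evaluation
    seed <- pos >= 2 & pos <= 7
    scs <- if (any(seed)) 1 - sum(af[seed]) / sum(seed) else 1
    nscs <- if (any(!seed)) 1 - sum(af[!seed]) / sum(!seed) else 1
    pcs <- 1 - length(unique(pos)) / L
    tvs <- max(0, 1 - n / L)
    want <- if (n == 0) 1 else
      w[1] * scs + w[2] * nscs + w[3] * pcs + w[4] * tvs
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("score monotonicity: adding variants never raises PCS/TVS", {
  set.seed(31)
  for (rep in 1:20) {
    L <- 22
    pos <- sample(seq_len(L), 5, replace = TRUE)
    af <- runif(5, 0, 0.05)
    r1 <- component_scores(make_mapped(pos, af), L)
    extra_pos <- c(pos, sample(seq_len(L), 1))
    extra_af <- c(af, runif(1, 0, 0.05))
    r2 <- component_scores(make_mapped(extra_pos, extra_af), L)
    expect_lte(r2$PCS, r1$PCS)
    expect_lte(r2$TVS, r1$TVS)
  }
  ## a seed variant with AF above the current seed mean lowers SCS
  r1 <- component_scores(make_mapped(c(2, 3), c(0.01, 0.03)), 22)
  r2 <- component_scores(make_mapped(c(2, 3, 4), c(0.01, 0.03, 0.5)), 22)
  expect_lt(r2$SCS, r1$SCS)
})

test_that("score_all is reproducible, order-invariant and population-aware", {
  fx <- make_fixture(fixture_spec(seed = 7))
  out <- run_scoring(fx)
  rec <- out$records
  expect_equal(sort(rec$name), sort(unique(out$groups$group)))
  expect_true(all(rec$OCS >= 0 & rec$OCS <= 1))

  ## permutation invariance of the variant input order
  shuf <- out$mapped[sample(nrow(out$mapped)), ]
  rec2 <- score_all(shuf, out$groups, c(0.2, 0.1, 0.6, 0.1))
  expect_identical(rec, rec2)

  ## population mode: only variants observed in that population count,
  ## and the population AF replaces the joint AF
  p <- score_all(out$mapped, out$groups, c(0.2, 0.1, 0.6, 0.1),
                 population = "afr")
  expect_true(all(p$v_t <= rec$v_t))
  expect_equal(p$population[1], "afr")
  expect_error(score_all(out$mapped, out$groups, c(0.2, 0.1, 0.6, 0.1),
                         population = "atlantis"), "unknown population")

  ## joint mode equals population mode when one population carries the
  ## joint AF for every variant
  m <- make_mapped(c(3, 10), c(0.02, 0.004))
  m$af_only <- m$af_joint
  g <- data.frame(group = "mir-x-5p", id = "MAT1", locus_name = "mir-x-5p",
                  n_copies = 1L, sequence = strrep("A", 22))
  expect_equal(score_all(m, g, c(0.2, 0.1, 0.6, 0.1),
                         population = "only")$OCS,
               score_all(m, g, c(0.2, 0.1, 0.6, 0.1))$OCS)
})

test_that("multi-locus groups score identically to pooled mapping", {
  fx <- make_fixture(fixture_spec(seed = 11))
  out <- run_scoring(fx)
  multi <- out$groups[out$groups$n_copies > 1, ]
  expect_gt(nrow(multi), 0)
  g <- multi$group[1]
  ids <- multi$id[multi$group == g]
  ## per-locus mapping then merging equals the pooled computation
  pooled <- out$records[out$records$name == g, ]
  per_locus <- out$mapped[out$mapped$mirna_id %in% ids &
                            out$mapped$level == "mature", ]
  per_locus <- per_locus[!duplicated(
    per_locus[, c("mirna_id", "pos", "ref", "alt")]), ]
  rec <- component_scores(per_locus, nchar(multi$sequence[1]))
  expect_equal(pooled$OCS,
               ocs(rec, c(0.2, 0.1, 0.6, 0.1)))
})

test_that("top/bottom selection uses the floor rule and name tie-breaks", {
  rec <- data.frame(name = sprintf("m%02d", 1:40), OCS = seq(0, 1, length.out = 40),
                    zero_variant = FALSE)
  tb <- top_bottom_groups(rec, 0.05)
  expect_equal(length(tb$hc), 2L)
  expect_equal(length(tb$lc), 2L)
  expect_equal(tb$hc, c("m40", "m39"))

  ## ties at the cut resolve lexicographically
  rec2 <- data.frame(name = c("b", "a", "c", "d"), OCS = c(1, 1, 0, 0),
                     zero_variant = FALSE)
  tb2 <- top_bottom_groups(rec2, 0.25)
  expect_equal(tb2$hc, "a")
  expect_equal(tb2$lc, "c")

  ## zero-variant records are excluded before selection
  rec3 <- rbind(rec, data.frame(name = "zz", OCS = 1, zero_variant = TRUE))
  expect_false("zz" %in% top_bottom_groups(rec3, 0.05)$hc)

  expect_error(top_bottom_groups(rec[1:10, ], 0.05), "no miRNAs")
  expect_error(top_bottom_groups(rec, 0.6), "\\(0, 0.5\\)")
})
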