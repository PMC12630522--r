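make_arms <- function(n, matched = TRUE, seed = 1) {
  set.seed(seed)
  o5 <- runif(n, 0.5, 1)
  o3 <- if (matched) pmin(1, o5 + rnorm(n, 0, 0.005)) else
    runif(n, 0.5, 1)
  data.frame(precursor = sprintf("p%02d", seq_len(n)),
             ocs_5p = o5, ocs_3p = o3, delta = o5 - o3,
             targets_5p = NA_integer_, targets_3p = NA_integer_)
}

test_that("arm permutation test detects matched arm conservation", {
  ## degenerate null: every arm has the same OCS, so all null statistics
  ## are zero too and the tie-counting tail gives p = 1
  arms0 <- make_arms(12)
  arms0$ocs_5p <- arms0$ocs_3p <- 0.8
  arms0$delta <- 0
  r0 <- arm_delta_permutation(arms0, n_perm = 199, seed = 3)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$observed, 0)

  ## tightly matched arms vs shuffled: small p with the add-one estimator
  arms <- make_arms(40, matched = TRUE, seed = 8)
  r <- arm_delta_permutation(arms, n_perm = 999, seed = 3)
  expect_lte(r$p_value, 0.01)
  expect_gt(r$p_value, 0)

  ## fixed seed means bit-identical p
  r2 <- arm_delta_permutation(arms, n_perm = 999, seed = 3)
  expect_identical(r$p_value, r2$p_value)

  expect_error(arm_delta_permutation(make_arms(5), n_perm = 999), ">= 10")
  expect_error(arm_delta_permutation(make_arms(12), n_perm = 50), ">= 100")
})

test_that("arm/target bins count more-conserved-arm wins", {
  arms <- make_arms(8, matched = FALSE, seed = 2)
  ## plant: more conserved arm always has more targets
  more <- ifelse(arms$delta > 0, "5p", "3p")
  arms$targets_5p <- ifelse(more == "5p", 50L, 5L)
  arms$targets_3p <- ifelse(more == "3p", 50L, 5L)
  r <- arm_target_bins(arms, n_bins = 4, n_perm = 999, seed = 5)
  expect_equal(r$bins$n, rep(2L, 4))           # quantile split 8 -> 2 per bin
  expect_equal(r$bins$more, r$bins$n)
  expect_equal(sum(r$bins$fewer), 0L)
  expect_lte(r$p_value, 0.01)

  ## equal targets everywhere: nothing to count, p = 1
  arms$targets_5p <- arms$targets_3p <- 10L
  r2 <- arm_target_bins(arms, n_bins = 4, n_perm = 199, seed = 5)
  expect_equal(sum(r2$bins$more) + sum(r2$bins$fewer), 0L)
  expect_equal(r2$p_value, 1)

  ## zero-delta precursors are excluded with a message
  arms$delta[1] <- 0
  expect_message(arm_target_bins(arms, n_bins = 3, n_perm = 199, seed = 5),
                 "equal arm OCS")
})

test_that("APA upstream ratio counts sites before the representative site", {
  apa <- data.frame(gene = c("G1", "G1", "G2", "G2", "G3"),
                    utr_pos = c(100L, 300L, 80L, 20L, 50L),
                    read_support = c(90L, 10L, 5L, 60L, 99L))
  rep1 <- representative_apa(apa)
  expect_equal(rep1$representative_pos[rep1$gene == "G1"], 100L)
  expect_equal(rep1$representative_pos[rep1$gene == "G2"], 20L)
  expect_equal(rep1$n_sites[rep1$gene == "G3"], 1L)

  sites <- data.frame(gene = c("G1", "G1", "G3"),
                      site_start = c(50L, 150L, 10L))
  ## G3 has a single APA site, so only G1's two sites count
  r <- apa_upstream_ratio(sites, apa)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$n_sites, 2L)

  r_up <- apa_upstream_ratio(data.frame(gene = "G1", site_start = c(1L, 2L)),
                             apa)
  expect_equal(r_up$ratio, 1)
  r_down <- apa_upstream_ratio(data.frame(gene = "G1",
                                          site_start = c(100L, 200L)), apa)
  expect_equal(r_down$ratio, 0)      # strict inequality: 100 is not upstream
  expect_true(is.na(apa_upstream_ratio(sites[0, ], apa)$ratio))
})

test_that("APA Fisher test reproduces the reference proportions", {
  r <- apa_fisher(911, 7339, 50, 622)
  expect_equal(round(100 * r$prop_hc, 1), 12.4)
  expect_equal(round(100 * r$prop_lc, 1), 8.0)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$p_value, fisher_oracle_p(911, 7339 - 911, 50, 622 - 50),
               tolerance = 1e-9)
  expect_equal(apa_fisher(5, 100, 5, 100)$p_value, 1)
  expect_error(apa_fisher(10, 5, 1, 10), "negative")
})

test_that("AF comparisons between regions use Mann-Whitney U", {
  m <- rbind(make_mapped(rep(10, 30), runif(30, 0, 0.01)),
             make_mapped(rep(3, 30), runif(30, 0, 0.01)))
  m$region <- rep(c("non_seed", "seed"), each = 30)
  m$af_joint <- rep(c(0.005, 0.005), each = 30)   # identical multisets
  r <- af_region_comparison(m, "non_seed", "seed")
  expect_gt(r$p_value, 0.9)

  ## a planted shift is detected at n = 200 per side
  set.seed(9)
  m2 <- rbind(make_mapped(rep(10, 200), rbeta(200, 1, 50)),
              make_mapped(rep(3, 200), 0.02 + rbeta(200, 1, 50)))
  m2$region <- rep(c("non_seed", "seed"), each = 200)
  r2 <- af_region_comparison(m2, "non_seed", "seed")
  expect_lt(r2$p_value, 0.05)

  ## n = 1 vs 1 is valid with U in {0, 1}
  m3 <- rbind(make_mapped(10, 0.001), make_mapped(3, 0.002))
  m3$region <- c("non_seed", "seed")
  r3 <- af_region_comparison(m3, "non_seed", "seed")
  expect_true(r3$statistic %in% c(0, 1))
  expect_gt(r3$p_value, 0.5)

  expect_error(af_region_comparison(m3, "non_seed", "terminal_loop"),
               "must contain variants")
})

test_that("multi-copy miRNAs test uses a rank-sum comparison", {
  rec <- data.frame(name = sprintf("m%02d", 1:100),
                    OCS = rep(0.8, 100),
                    n_copies = rep(c(1L, 2L), 50),
                    zero_variant = FALSE)
  expect_equal(copy_number_test(rec)$p_value, 1)

  set.seed(13)
  rec$OCS <- runif(100, 0.6, 0.8) + ifelse(rec$n_copies > 1, 0.1, 0)
  r <- copy_number_test(rec)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$median_multi, r$median_single)

  expect_error(copy_number_test(rec[rec$n_copies == 1, ]), "nonempty")
})

test_that("confidence coverage curves are monotone and end at 1", {
  rec <- data.frame(name = sprintf("m%02d", 1:20),
                    OCS = seq(1, 0.5, length.out = 20),
                    zero_variant = FALSE)
  ## accepted miRNAs occupy the top ranks
  labels <- setNames(rep(c("accepted", "rejected"), each = 5),
                     c(sprintf("m%02d", 1:5), sprintf("m%02d", 16:20)))
  cc <- confidence_coverage_curve(rec, labels)
  expect_true(all(diff(cc$cum_accepted) >= 0))
  expect_true(all(diff(cc$cum_rejected) >= 0))
  expect_equal(cc$cum_accepted[nrow(cc)], 1)
  expect_equal(cc$cum_rejected[nrow(cc)], 1)
  expect_true(all(cc$cum_accepted >= cc$cum_rejected))

  ## single labelled miRNA: a step from 0 to 1 at its rank
  cc2 <- confidence_coverage_curve(rec, c(m10 = "accepted"))
  expect_equal(sort(unique(cc2$cum_accepted)), c(0, 1))
  expect_equal(cc2$cum_accepted[cc2$name == "m10"], 1)

  expect_error(confidence_coverage_curve(rec, c(zz = "accepted")),
               "no labelled")
})

test_that("arm records join 5p/3p scores per precursor", {
  fx <- make_fixture(fixture_spec(seed = 7))
  out <- run_scoring(fx)
  tc <- data.frame(mirna = out$records$name,
                   n_targets = seq_len(nrow(out$records)))
  arms <- arm_records(out$records, out$groups, fx$tables$loci,
                      target_counts = tc)
  two_arm <- sum(table(fx$tables$loci$derives_from[
    fx$tables$loci$feature_kind == "mature"]) == 2)
  expect_equal(nrow(arms), two_arm)
  expect_true(all(abs(arms$delta) <= 1))
  expect_equal(arms$delta, arms$ocs_5p - arms$ocs_3p)
  expect_false(any(is.na(arms$targets_5p)))
})
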