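test_that("group means average replicate counts within each group", {
  fx <- make_counts(bait = matrix(c(3, 3, 3, 2, 4, 6), nrow = 2, byrow = TRUE),
                    ctrl = matrix(c(0, 0, 0, 1, 1, 1), nrow = 2, byrow = TRUE))
  gm <- group_means(fx$counts, fx$samples)
  expect_equal(gm$mean_bait, c(3, 4))
  expect_equal(gm$mean_control, c(0, 1))

  no_bait <- fx$samples[fx$samples$group == "control", ]
  expect_error(group_means(fx$counts, no_bait),
               class = "proxitome_config_error")
})

test_that("pseudo-count fold change matches hand arithmetic", {
  expect_equal(fold_change(5, 5, 0.01),
               tibble::tibble(fold_change = 1, log2fc = 0))
  fc <- fold_change(1, 0, 0.01)
  expect_equal(fc$fold_change, 1.01 / 0.01)
  expect_equal(fc$log2fc, log2(101), tolerance = 1e-12)
  # a raw ratio of exactly 8 falls below the log2fc >= 3 cutoff once the
  # pseudo-count enters the ratio
  fc8 <- fold_change(8, 1, 0.01)
  expect_equal(fc8$fold_change, 8.01 / 1.01, tolerance = 1e-12)
  expect_lt(fc8$log2fc, 3)
  expect_equal(fc8$log2fc, log2(8.01 / 1.01), tolerance = 1e-12)

  expect_error(fold_change(-1, 0), class = "proxitome_value_error")
  expect_error(fold_change(1, 1, 0), class = "proxitome_value_error")
})

test_that("fold change is monotone in both means", {
  mb <- seq(0, 50, by = 2.5)
  expect_true(all(diff(fold_change(mb, 3)$fold_change) > 0))
  mc <- seq(0, 50, by = 2.5)
  expect_true(all(diff(fold_change(3, mc)$fold_change) < 0))
})

test_that("pooled one-tailed t agrees with stats::t.test", {
  expect_equal(
    pooled_t_test(c(10, 12, 11), c(1, 2, 1))$p_value,
    t.test(c(10, 12, 11), c(1, 2, 1), var.equal = TRUE,
           alternative = "greater")$p.value,
    tolerance = 1e-12
  )
  set.seed(41)
  for (i in 1:25) {
    x <- round(rgamma(3, 4, 0.5), 3)
    y <- round(rgamma(4, 4, 0.5), 3)
    for (tail in c("greater", "less", "two-sided")) {
      alt <- c(greater = "greater", less = "less",
               `two-sided` = "two.sided")[[tail]]
      expect_equal(pooled_t_test(x, y, tail = tail)$p_value,
                   t.test(x, y, var.equal = TRUE,
                          alternative = alt)$p.value,
                   tolerance = 1e-10)
      expect_equal(pooled_t_test(x, y, tail = tail,
                                 variance_model = "welch")$p_value,
                   t.test(x, y, var.equal = FALSE,
                          alternative = alt)$p.value,
                   tolerance = 1e-10)
    }
    # symmetry of the null t distribution
    p_ab <- pooled_t_test(x, y, tail = "greater")$p_value
    p_ba <- pooled_t_test(y, x, tail = "greater")$p_value
    expect_equal(p_ab + p_ba, 1, tolerance = 1e-10)
  }
})

test_that("zero pooled variance resolves to the t-statistic limits", {
  r <- pooled_t_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  r2 <- pooled_t_test(c(6, 6, 6), c(5, 5, 5))
  expect_true(r2$degenerate)
  expect_lte(r2$p_value, 1e-300)
  r3 <- pooled_t_test(c(4, 4, 4), c(5, 5, 5))
  expect_equal(r3$p_value, 1)
  expect_error(pooled_t_test(3, c(1, 2)), class = "proxitome_value_error")
})

test_that("enrichment calling flags by thresholds and sorts deterministically", {
  # identical groups: nothing can be called
  fx <- make_counts(bait = matrix(rep(c(4, 7, 2), 5), nrow = 5, byrow = TRUE),
                    ctrl = matrix(rep(c(4, 7, 2), 5), nrow = 5, byrow = TRUE))
  res <- call_enrichment(fx$counts, fx$samples)
  expect_equal(sum(res$enriched), 0L)
  expect_equal(res$protein_id, sort(res$protein_id))
  expect_true(all(c("log2fc", "neg_log10_p") %in% names(res)))

  # a clear spike is called; the flag obeys both thresholds jointly
  spec <- simulation_spec(seed = 11, n_proteins = 400, n_enriched = 50,
                          effect_fold = 16, dispersion = 50,
                          detection_zero_prob = 0)
  sim <- simulate_counts(spec)
  res2 <- call_enrichment(sim$counts, sim$samples)
  truth_enr <- sim$truth$protein_id[sim$truth$enriched]
  expect_setequal(enriched_ids(res2), truth_enr)
  expect_true(all(res2$enriched ==
                    (res2$log2fc >= 3 & res2$p_value < 0.05)))
})

test_that("enrichment table is invariant to sample order within groups", {
  spec <- simulation_spec(seed = 3, n_proteins = 150, n_enriched = 10)
  sim <- simulate_counts(spec)
  res1 <- call_enrichment(sim$counts, sim$samples)
  perm <- sim$samples[c(3, 1, 2, 5, 6, 4), ]
  res2 <- call_enrichment(sim$counts[sample(nrow(sim$counts)), ], perm)
  expect_equal(tibble::as_tibble(res1), tibble::as_tibble(res2))
})

test_that("config switches: BH column, pseudo-count scope, Welch", {
  spec <- simulation_spec(seed = 5, n_proteins = 200, n_enriched = 20)
  sim <- simulate_counts(spec)
  res_bh <- call_enrichment(sim$counts, sim$samples,
                            enrichment_config(p_adjust = "benjamini-hochberg"))
  expect_equal(res_bh$p_adjusted, p.adjust(res_bh$p_value, "BH"))
  res_raw <- call_enrichment(sim$counts, sim$samples)
  # the adjusted column never alters the default enriched flag
  expect_equal(res_bh$enriched, res_raw$enriched)
  expect_true(all(is.na(res_raw$p_adjusted)))

  res_scope <- call_enrichment(
    sim$counts, sim$samples,
    enrichment_config(pseudo_count_scope = "fold-change-and-test")
  )
  # adding a constant to every count shifts neither means' difference nor
  # variances: the pooled t is unchanged, fold change is not
  expect_equal(res_scope$p_value, res_raw$p_value, tolerance = 1e-9)
  expect_equal(res_scope$fold_change, res_raw$fold_change)

  expect_error(call_enrichment(sim$counts, sim$samples, config = list()),
               class = "proxitome_config_error")
})

test_that("venn intersection is exact set algebra", {
  v <- intersect_enrichment(letters[1:10], letters[1:10])
  expect_equal(v$both, 10L)
  expect_equal(v$union, 10L)
  v2 <- intersect_enrichment(c("1", "2", "3"), c("3", "4"))
  expect_equal(unlist(v2), c(only_a = 2L, only_b = 1L, both = 1L, union = 4L))
  set.seed(9)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    v3 <- intersect_enrichment(a, b)
    expect_equal(v3$only_a + v3$only_b + v3$both, v3$union)
  }
})

test_that("counts reader enforces the schema and round-trips", {
  fx <- make_counts(bait = matrix(c(2, 4, 6), 1), ctrl = matrix(c(1, 1, 1), 1))
  tmp_c <- tempfile(fileext = ".tsv")
  tmp_s <- tempfile(fileext = ".tsv")
  readr::write_tsv(fx$counts, tmp_c)
  readr::write_tsv(fx$samples, tmp_s)
  expect_equal(as.data.frame(read_counts(tmp_c)), as.data.frame(fx$counts))
  expect_equal(read_sample_sheet(tmp_s)$group, fx$samples$group)
  bad <- fx$counts[, c(2, 1, 3, 4, 5, 6, 7)]
  readr::write_tsv(bad, tmp_c)
  expect_error(read_counts(tmp_c), class = "proxitome_config_error")
})
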