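test_that("longest isoform wins per gene, ties broken lexicographically", {
  iso <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3", "g3"),
    isoform = c("g1a", "g1b", "g2a", "b1", "a1"),
    length = c(300, 450, 200, 200, 200)
  )
  out <- longest_isoforms(iso)
  expect_equal(nrow(out), 3L)
  expect_equal(out$isoform[out$gene == "g1"], "g1b")
  expect_equal(out$isoform[out$gene == "g2"], "g2a")
  expect_equal(out$isoform[out$gene == "g3"], "a1")

  with_empty <- rbind(iso, tibble::tibble(gene = "g4", isoform = "g4a",
                                          length = 0))
  expect_warning(out2 <- longest_isoforms(with_empty), "empty")
  expect_false("g4" %in% out2$gene)
  # one row per distinct gene, always
  expect_equal(nrow(out2), length(unique(iso$gene)))
})

test_that("proteome FASTA parsing feeds the isoform filter", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">abc-1a gene=abc-1", "MKV", ">abc-1b gene=abc-1",
               "MKVLL", ">xyz-9 gene=xyz-9", "MA"), fa)
  iso <- read_proteome_fasta(fa)
  expect_equal(sort(iso$gene), c("abc-1", "abc-1", "xyz-9"))
  out <- longest_isoforms(iso)
  expect_equal(out$length[out$gene == "abc-1"], 5L)
})

test_that("mean disorder is total score over length", {
  sc <- tibble::tibble(protein_id = rep(c("a", "b", "c"), c(100, 50, 3)),
                       position = c(1:100, 1:50, 1:3),
                       score = c(rep(0, 100), rep(1, 50), c(0.2, 0.4, 0.9)))
  out <- summarize_disorder(sc)
  expect_equal(out$mean, c(0, 1, 0.5))
  expect_equal(out$total, c(0, 50, 1.5))
  expect_equal(out$mean * out$length, out$total, tolerance = 1e-12)

  expect_error(summarize_disorder(sc[0, ]), class = "proxitome_value_error")
  bad <- sc
  bad$score[1] <- 1.2
  expect_error(summarize_disorder(bad), class = "proxitome_value_error")
  gap <- sc[-5, ]
  expect_error(summarize_disorder(gap), class = "proxitome_value_error")
})

test_that("adding a residue at the current mean leaves the mean unchanged", {
  set.seed(2)
  sc <- tibble::tibble(protein_id = "p", position = 1:30,
                       score = runif(30))
  m <- summarize_disorder(sc)$mean
  sc2 <- rbind(sc, tibble::tibble(protein_id = "p", position = 31,
                                  score = m))
  expect_equal(summarize_disorder(sc2)$mean, m, tolerance = 1e-12)
})

test_that("exact Wilcoxon path equals brute-force enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  set.seed(73)
  for (i in 1:60) {
    n1 <- sample(2:7, 1)
    n2 <- sample(2:7, 1)
    repeat {
      x <- round(rnorm(n1), 6)
      y <- round(rnorm(n2), 6)
      if (!anyDuplicated(c(x, y))) break
    }
    for (alt in c("two-sided", "greater", "less")) {
      got <- wilcoxon_rank_sum(x, y, alternative = alt)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, brute_force_wilcoxon(x, y, alt),
                   tolerance = 1e-12)
    }
    # stats::wilcox.test as a second, independent cross-check
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(19)
  x <- rpois(40, 10)
  y <- rpois(45, 12)
  got <- wilcoxon_rank_sum(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value)
  expect_equal(got$method, "normal-approximation")
  expect_equal(got$p_value, ref, tolerance = 1e-10)

  same <- rep(3, 10)
  deg <- wilcoxon_rank_sum(same, rep(3, 8))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3),
               class = "proxitome_value_error")
})

test_that("random-control comparison is seeded and reproducible", {
  spec <- simulation_spec(seed = 21, n_proteins = 150, n_enriched = 20)
  sim <- simulate_disorder(spec)
  c1 <- compare_to_random(sim$summaries, sim$target_ids, seed = 9)
  c2 <- compare_to_random(sim$summaries, sim$target_ids, seed = 9)
  expect_identical(glance(c1), glance(c2))
  expect_identical(c1$draws$control_ids, c2$draws$control_ids)
  expect_equal(c1$control_n, c1$target_n)
  # excluded targets never appear in their own control
  expect_length(intersect(c1$draws$control_ids[[1]], sim$target_ids), 0L)
  c3 <- compare_to_random(sim$summaries, sim$target_ids, seed = 10)
  expect_false(identical(c1$draws$control_ids, c3$draws$control_ids))
})

test_that("complete separation reaches the exact-test minimum", {
  summaries <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:20),
    mean = c(seq(0.85, 0.95, length.out = 6),
             seq(0.05, 0.18, length.out = 14))
  )
  targets <- sprintf("p%02d", 1:6)
  cmp <- compare_to_random(summaries, targets, seed = 1)
  # most extreme two-sided exact p at 6 vs 6: 2 / choose(12, 6)
  expect_equal(cmp$p_value, 2 / choose(12, 6), tolerance = 1e-12)

  expect_error(
    compare_to_random(summaries[1:8, ], targets, seed = 1),
    class = "proxitome_value_error"
  )
})

test_that("multiple draws report the median p and every draw", {
  spec <- simulation_spec(seed = 33, n_proteins = 150, n_enriched = 15,
                          disorder_shift = 0)
  sim <- simulate_disorder(spec)
  cmp <- compare_to_random(sim$summaries, sim$target_ids, seed = 4,
                           n_draws = 5)
  expect_equal(nrow(cmp$draws), 5L)
  expect_equal(cmp$p_value, median(cmp$draws$p_value))
  expect_equal(nrow(tidy(cmp)), 5L)
})
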