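test_that("burden comparison is Welch's t, with degenerate groups handled", {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    group = rep(c("case_ctd", "control"), each = 6),
    sex = rep(c("male", "female"), 6),
    ancestry = rep(c("CEU", "AFR"), each = 3, times = 2))

  # identical count vectors: mean difference 0, p = 1
  counts <- stats::setNames(rep(c(1L, 2L, 3L), 4), samples$sample_id)
  res <- compare_burden(counts, samples)
  expect_equal(res$mean_case - res$mean_control, 0)
  expect_equal(res$p, 1)

  # non-degenerate data agrees with the closed-form Welch oracle
  counts2 <- stats::setNames(c(0L, 1L, 2L, 3L, 1L, 2L, 2L, 3L, 4L, 5L, 3L, 4L),
                             samples$sample_id)
  res2 <- compare_burden(counts2, samples)
  ora <- oracle_welch(counts2[1:6], counts2[7:12])
  expect_equal(res2$statistic, ora$statistic, tolerance = 1e-12)
  expect_equal(res2$df, ora$df, tolerance = 1e-12)
  expect_equal(res2$p, ora$p, tolerance = 1e-12)

  # constant groups with different means: infinitely separated
  counts3 <- stats::setNames(rep(c(0L, 3L), each = 6), samples$sample_id)
  expect_equal(compare_burden(counts3, samples)$p, 0)

  # stratified run: one overall row plus one per stratum
  res4 <- compare_burden(counts2, samples, stratify_by = "ancestry")
  expect_equal(res4$stratum, c("overall", "AFR", "CEU"))
})

test_that("burden p-values are uniform under label permutation", {
  withr::with_seed(5, {
    n <- 160
    counts <- stats::setNames(rpois(n, 1.8), sprintf("s%03d", 1:n))
    ps <- replicate(500, {
      samples <- data.frame(sample_id = names(counts),
                            group = sample(rep(c("case_ctd", "control"),
                                               each = n / 2)),
                            sex = "unknown", ancestry = "CEU")
      compare_burden(counts, samples)$p
    })
    # ties are expected in permutation p-values; the asymptotic KS is fine
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  })
})

test_that("expression filter applies the mean-RPM cutoff and reports the fraction", {
  expr <- data.frame(gene = sprintf("g%02d", 1:20))
  # 7 of 20 genes (35%) at mean >= 25, including one exactly at the cutoff
  means <- c(25, 25.1, 30, 40, 50, 60, 100, 24.9, rep(5, 12))
  for (t in c("PA2_6", "OFT_RV", "LV_atria")) expr[[t]] <- means
  res <- expressed_genes(expr)
  expect_true("g01" %in% res$genes)    # boundary: exactly 25 is expressed
  expect_false("g08" %in% res$genes)   # 24.9 is not
  expect_equal(res$achieved_fraction, 0.35)
})

test_that("recurrence rule needs >= 2 case carriers and 0 control carriers", {
  mdrvs <- rbind(make_variant("v1", gene = "A"),
                 make_variant("v2", gene = "A", pos = 2000L),
                 make_variant("v3", gene = "B", pos = 3000L),
                 make_variant("v4", gene = "C", pos = 4000L),
                 make_variant("v5", gene = "C", pos = 5000L),
                 make_variant("v6", gene = "D", pos = 6000L))
  samples <- data.frame(sample_id = sprintf("s%d", 1:8),
                        group = rep(c("case_ctd", "control"), each = 4),
                        sex = "unknown", ancestry = "CEU")
  carriers <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5", "v4", "v6", "v6"),
    sample_id  = c("s1", "s2", "s1", "s1", "s2", "s5", "s5", "s6"),
    allele_count = 1L)
  rec <- select_recurrent(mdrvs, carriers, samples, expressed = c("A", "B"))
  rec <- rec[match(c("A", "B", "C", "D"), rec$gene), ]
  expect_equal(rec$recurrent_in, c("cases", "neither", "neither", "controls"))
  expect_equal(rec$n_case_carriers, c(2L, 1L, 2L, 0L))
  expect_equal(rec$n_control_carriers, c(0L, 0L, 1L, 2L))
  expect_equal(rec$expressed, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("a subject with two MDRVs in one gene counts once for that gene", {
  mdrvs <- rbind(make_variant("v1", gene = "A"),
                 make_variant("v2", gene = "A", pos = 2000L))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        group = c("case_ctd", "case_ctd", "control"),
                        sex = "unknown", ancestry = "CEU")
  carriers <- data.frame(variant_id = c("v1", "v2"), sample_id = c("s1", "s1"),
                         allele_count = 1L)
  rec <- select_recurrent(mdrvs, carriers, samples)
  expect_equal(rec$n_case_carriers, 1L)
  expect_equal(rec$recurrent_in, "neither")
})

test_that("the worked-example fixture yields 12 recurrent expressed genes from 26 carriers", {
  fx <- simulate_table1_fixture()
  mdrvs <- select_mdrv(fx$variants)$mdrvs
  expect_equal(nrow(mdrvs), nrow(fx$variants))  # every fixture variant is an MDRV
  expressed <- expressed_genes(fx$expression)$genes
  rec <- select_recurrent(mdrvs, fx$carriers, fx$samples, expressed)
  expect_equal(sum(rec$recurrent_in == "cases"), 31L)
  hits <- rec[rec$recurrent_in == "cases" & rec$expressed, ]
  expect_equal(nrow(hits), 12L)
  expect_setequal(hits$gene, fx$table1_genes)
  # published counts, genes in alphabetical order (CACNA1D and FBLN2 have 3)
  expect_equal(hits$n_case_carriers[order(hits$gene)],
               c(3L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
  expect_equal(sum(hits$n_case_carriers), 26L)
})
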