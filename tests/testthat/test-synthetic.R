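test_that("the same seed yields a byte-identical on-disk bundle", {
  cfg <- small_synth_config(seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # different seed changes the bundle
  d3 <- withr::local_tempdir()
  simulate_cohort(small_synth_config(seed = 8), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "variants.tsv"))),
                         unname(tools::md5sum(file.path(d3, "variants.tsv")))))
})

test_that("written bundles re-ingest through the readers unchanged", {
  cfg <- small_synth_config(seed = 3)
  d <- withr::local_tempdir()
  b <- simulate_cohort(cfg, d)
  v <- read_variant_table(file.path(d, "variants.tsv"))
  k <- read_carrier_table(file.path(d, "carriers.tsv"))
  s <- read_sample_sheet(file.path(d, "samples.tsv"))
  e <- read_expression(file.path(d, "expression.tsv"))
  g <- read_gmt(file.path(d, "gene_sets.gmt"))
  gc <- read_genotype_counts(file.path(d, "genotype_counts.tsv"))
  expect_true(validate_bundle(v, k, s))
  expect_equal(v, b$variants)
  expect_equal(k, b$carriers)
  expect_equal(s, b$samples)
  expect_equal(gc, b$genotype_counts)
  expect_equal(lapply(g, identity)[names(b$gene_sets)],
               lapply(b$gene_sets, identity))
  expect_equal(as.matrix(e[, -1]), as.matrix(b$expression[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulated per-subject MDRV burden converges to the configured rate", {
  b <- simulate_cohort(synthetic_config(seed = 19))
  sel <- select_mdrv(b$variants)
  mc <- b$carriers[b$carriers$variant_id %in% sel$mdrvs$variant_id, ]
  counts <- per_subject_burden(sel$mdrvs, mc, b$samples)
  n <- length(counts)
  se <- sqrt(b$config$lambda / n)   # Poisson-scale standard error
  expect_lt(abs(mean(counts) - b$config$lambda), 3 * se)
  # sparsity profile: ~83% of affected genes carry a single MDRV
  per_gene <- table(sel$mdrvs$gene)
  expect_lt(abs(mean(per_gene == 1) - 0.83), 0.05)
})

test_that("decoy variants fail the cascade and simulated MDRVs pass it", {
  b <- simulate_cohort(small_synth_config(seed = 23))
  sel <- select_mdrv(b$variants)
  frac <- b$config$decoy_variant_frac
  n_decoy_expected <- 5 * round(frac * (nrow(b$variants) /
                                          (1 + 5 * frac)))
  expect_equal(nrow(b$variants) - nrow(sel$mdrvs), n_decoy_expected)
  # expression calibration: the RPM >= 25 cutoff lands near the top 35%
  ex <- expressed_genes(b$expression)
  expect_lt(abs(ex$achieved_fraction - 0.35), 0.05)
})

test_that("under the null, case and control carriage is exchangeable in the designated set", {
  withr::with_seed(29, {
    rejections <- 0L
    for (i in 1:30) {
      b <- simulate_cohort(small_synth_config(rho = 1, seed = 1000 + i))
      sel <- select_mdrv(b$variants)
      mc <- b$carriers[b$carriers$variant_id %in% sel$mdrvs$variant_id, ]
      gc <- unique(data.frame(
        gene = sel$mdrvs$gene[match(mc$variant_id, sel$mdrvs$variant_id)],
        sample_id = mc$sample_id))
      # carriage events inside the designated set should split between
      # groups in proportion to group size (here 100/100)
      in_set <- gc$gene %in% b$gene_sets$designated_set
      cases <- b$samples$sample_id[b$samples$group == "case_ctd"]
      n_case_events <- sum(gc$sample_id[in_set] %in% cases)
      pt <- stats::binom.test(n_case_events, sum(in_set), p = 0.5)$p.value
      if (pt < 0.01) rejections <- rejections + 1L
    }
    expect_lte(rejections, 2L)  # >= 99% non-rejection up to MC noise
  })
})

test_that("the enriched configuration concentrates extra carriage in cases", {
  b0 <- simulate_cohort(small_synth_config(rho = 1, seed = 55))
  b4 <- simulate_cohort(small_synth_config(rho = 4, seed = 55))
  events_in_set <- function(b) {
    sel <- select_mdrv(b$variants)
    mc <- b$carriers[b$carriers$variant_id %in% sel$mdrvs$variant_id, ]
    gene <- sel$mdrvs$gene[match(mc$variant_id, sel$mdrvs$variant_id)]
    cases <- b$samples$sample_id[b$samples$group == "case_ctd"]
    sum(gene %in% b$gene_sets$designated_set & mc$sample_id %in% cases)
  }
  expect_gt(events_in_set(b4), 2 * events_in_set(b0))
})
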