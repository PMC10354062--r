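test_that("exact HWE test matches the enumeration oracle on canonical cases", {
  # monomorphic: single attainable configuration
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  # all-heterozygote extreme, checked against full enumeration
  expect_equal(hwe_exact_test(0, 100, 0), oracle_hwe(0, 100, 0),
               tolerance = 1e-12)
  # equilibrium-looking configuration: large p
  p_eq <- hwe_exact_test(25, 50, 25)
  expect_equal(p_eq, oracle_hwe(25, 50, 25), tolerance = 1e-12)
  expect_gt(p_eq, 0.5)
  expect_error(hwe_exact_test(0, 0, 0), "no called genotypes")
})

test_that("exact HWE test equals the enumeration oracle for all totals <= 30", {
  for (n in 1:30) {
    for (het in 0:n) {
      for (hom_alt in 0:(n - het)) {
        hom_ref <- n - het - hom_alt
        expect_equal(hwe_exact_test(hom_ref, het, hom_alt),
                     oracle_hwe(hom_ref, het, hom_alt),
                     tolerance = 1e-10,
                     label = sprintf("hwe(%d,%d,%d)", hom_ref, het, hom_alt))
      }
    }
  }
})

test_that("variant QC removes by region, class-specific rate and HWE thresholds", {
  v <- rbind(
    make_variant("snv_ok", pos = 500L),
    make_variant("snv_lowrate", pos = 600L),
    make_variant("indel_lowrate", pos = 700L, ref = "AT", alt = "A",
                 consequence = "frameshift"),
    make_variant("snv_region", chrom = "22", pos = 19000000L),
    make_variant("snv_hwe", pos = 800L),
    make_variant("snv_mono", pos = 900L))
  n <- 200L
  gc <- data.frame(
    variant_id = v$variant_id,
    n_hom_ref = c(190L, 188L, 188L, 190L, 150L, 200L),
    n_het = c(10L, 4L, 4L, 10L, 0L, 0L),
    n_hom_alt = c(0L, 0L, 0L, 0L, 50L, 0L),
    n_missing = c(0L, 8L, 8L, 0L, 0L, 0L))
  regions <- data.frame(chrom = "22", start = 18000000L, end = 21000000L)
  res <- apply_variant_qc(v, gc, qc_config(excluded_regions = regions))
  # rate 192/200 = 0.96: passes the SNV 0.95 floor, fails the indel 0.97 floor
  expect_true("snv_lowrate" %in% res$retained)
  expect_false("indel_lowrate" %in% res$retained)
  expect_false("snv_region" %in% res$retained)
  expect_false("snv_hwe" %in% res$retained)   # 150/0/50 wildly off HWE
  expect_false("snv_mono" %in% res$retained)
  expect_true("snv_ok" %in% res$retained)
  # tallies account for every input variant
  expect_equal(sum(res$tally$n), nrow(v))

  # a genuinely low-rate SNV is removed at the rate stage
  gc$n_missing[1] <- 12L; gc$n_hom_ref[1] <- 178L
  res2 <- apply_variant_qc(v, gc, qc_config(excluded_regions = regions))
  expect_false("snv_ok" %in% res2$retained)

  expect_error(apply_variant_qc(v, gc[-1, ], qc_config()),
               "without genotype counts")
})

test_that("variant QC retained set is invariant to input row order", {
  withr::with_seed(11, {
    v <- random_variant_table(40)
    n <- 100L
    gc <- data.frame(variant_id = v$variant_id,
                     n_het = rbinom(40, 8, 0.5))
    gc$n_hom_alt <- rbinom(40, 2, 0.2)
    gc$n_missing <- rbinom(40, 10, 0.3)
    gc$n_hom_ref <- n - gc$n_het - gc$n_hom_alt - gc$n_missing
    res1 <- apply_variant_qc(v, gc, qc_config())
    perm <- sample(nrow(v))
    res2 <- apply_variant_qc(v[perm, ], gc, qc_config())
    expect_setequal(res1$retained, res2$retained)
    expect_equal(sum(res1$tally$n), nrow(v))
  })
})

test_that("cross-caller concordance validates SNVs exactly and indels by span overlap", {
  a <- rbind(make_variant("a1", chrom = "1", pos = 100L),
             make_variant("a2", chrom = "1", pos = 100L,
                          ref = strrep("A", 21), alt = "A",
                          consequence = "frameshift"),
             make_variant("a3", chrom = "2", pos = 100L,
                          ref = strrep("C", 11), alt = "C",
                          consequence = "frameshift"))
  b <- rbind(make_variant("b1", chrom = "1", pos = 100L),
             make_variant("b2", chrom = "1", pos = 110L,
                          ref = strrep("A", 21), alt = "A",
                          consequence = "frameshift"),
             make_variant("b3", chrom = "2", pos = 109L,
                          ref = strrep("C", 42), alt = "C",
                          consequence = "frameshift"))
  res <- cross_caller_concordance(a, b)
  expect_true("a1" %in% res$validated_a)           # identical SNV tuple
  # spans [100,120] vs [110,130]: 11/31 = 0.355 >= 0.10
  expect_true("a2" %in% res$validated_a)
  # spans [100,110] vs [109,150]: 2/51 = 0.039 < 0.10
  expect_false("a3" %in% res$validated_a)

  # symmetry: swapping callsets exchanges the validated sets
  swapped <- cross_caller_concordance(b, a)
  expect_setequal(res$validated_a, swapped$validated_b)
  expect_setequal(res$validated_b, swapped$validated_a)
})
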