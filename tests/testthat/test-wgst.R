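test_that("gene-level Fisher z handles null, enumerable and symmetric tables", {
  # no carriers anywhere: p = 1, z = 0
  res <- gene_fet_z(0, 456, 0, 537)
  expect_equal(res$p, 1)
  expect_equal(res$z, 0)

  # small table against the margin-enumeration oracle
  res2 <- gene_fet_z(3, 2, 0, 5)
  expect_equal(res2$p, oracle_fet2(3, 2, 0, 5), tolerance = 1e-12)
  expect_gt(res2$z, 0)

  # swapping case and control rows flips the sign of z only
  res3 <- gene_fet_z(0, 5, 3, 2)
  expect_equal(res3$p, res2$p, tolerance = 1e-12)
  expect_equal(res3$z, -res2$z, tolerance = 1e-12)

  expect_error(gene_fet_z(-1, 2, 3, 4), "non-negative")
  expect_error(gene_fet_z(0, 0, 1, 4), "both groups")
})

test_that("gene-level Fisher p agrees with stats::fisher.test on random tables", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
      a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
      ours <- gene_fet_z(a, n1 - a, c_, n2 - c_)
      ref <- stats::fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2,
                                       byrow = TRUE))$p.value
      expect_equal(ours$p, ref, tolerance = 1e-9,
                   label = sprintf("fet(%d,%d,%d,%d)", a, n1 - a, c_, n2 - c_))
      expect_equal(ours$p, oracle_fet2(a, n1 - a, c_, n2 - c_),
                   tolerance = 1e-12)
    }
  })
})

test_that("the quadratic form statistic matches its closed form and projection identities", {
  expect_equal(t_statistic(c(1, -1), c(1, 1)), 0)   # cancellation
  expect_equal(t_statistic(3, 2), 9)                # (2*3)^2 / 4
  withr::with_seed(9, {
    for (i in 1:50) {
      k <- sample(1:20, 1)
      Z <- rnorm(k); w <- runif(k)
      w[sample(k, 1)] <- max(w)  # ensure a positive weight
      T1 <- t_statistic(Z, w)
      J <- (w %*% t(w)) / sum(w^2)
      expect_equal(T1, drop(t(Z) %*% J %*% Z), tolerance = 1e-10)
      expect_equal(J %*% J, J, tolerance = 1e-10)      # idempotent
      expect_equal(sum(diag(J)), 1, tolerance = 1e-12) # trace one
      expect_equal(t_statistic(Z, 3.7 * w), T1, tolerance = 1e-10)
      perm <- sample(k)
      expect_equal(t_statistic(Z[perm], w[perm]), T1, tolerance = 1e-10)
    }
  })
  expect_error(t_statistic(c(1, 2), c(0, 0)), "all-zero")
  expect_error(t_statistic(c(1, 2), c(1, -1)), "non-negative")
})

make_wgst_data <- function(n_case = 30, n_ctrl = 30, genes = sprintf("g%d", 1:6)) {
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_case + n_ctrl)),
    group = rep(c("case_ctd", "control"), c(n_case, n_ctrl)),
    sex = "unknown", ancestry = "CEU")
  carr <- do.call(rbind, lapply(seq_along(genes), function(i) {
    who <- sample(samples$sample_id, sample(1:6, 1))
    data.frame(gene = genes[i], sample_id = who)
  }))
  list(samples = samples, gene_carriers = unique(carr), genes = genes)
}

test_that("the permutation test is seed-deterministic with an observed-inclusive floor", {
  withr::with_seed(21, {
    d <- make_wgst_data()
    w <- stats::setNames(runif(length(d$genes), 1, 3), d$genes)
    r1 <- wgst_permutation_test(d$gene_carriers, d$samples, d$genes, w,
                                n_perm = 100, seed = 5)
    r2 <- wgst_permutation_test(d$gene_carriers, d$samples, d$genes, w,
                                n_perm = 100, seed = 5)
    expect_identical(r1$p_emp, r2$p_emp)
    expect_identical(r1$T_obs, r2$T_obs)
    expect_gte(r1$p_emp, 1 / 100)
    expect_equal(r1$n_extreme / 100, r1$p_emp)
  })

  # extreme enrichment: every carrier is a case, no permuted T can exceed
  samples <- data.frame(sample_id = sprintf("s%02d", 1:40),
                        group = rep(c("case_ctd", "control"), each = 20),
                        sex = "unknown", ancestry = "CEU")
  gc <- data.frame(gene = rep(c("gA", "gB"), each = 15),
                   sample_id = rep(sprintf("s%02d", 1:15), 2))
  r <- wgst_permutation_test(gc, samples, c("gA", "gB"),
                             c(gA = 2, gB = 1), n_perm = 200, seed = 1)
  expect_equal(r$p_emp, 1 / 200)

  expect_error(wgst_permutation_test(gc, samples[1:21, ], c("gA", "gB"),
                                     c(gA = 2, gB = 1), n_perm = 10, seed = 1),
               "2 subjects per group")
  expect_error(wgst_permutation_test(gc, samples, "absent_gene",
                                     c(absent_gene = 1), n_perm = 10, seed = 1),
               "no gene in the set")
})

test_that("equal weights reduce T to k times the squared mean z", {
  withr::with_seed(31, {
    d <- make_wgst_data(genes = sprintf("g%d", 1:5))
    w_eq <- stats::setNames(rep(2, 5), d$genes)
    r <- wgst_permutation_test(d$gene_carriers, d$samples, d$genes, w_eq,
                               n_perm = 50, seed = 3)
    expect_equal(r$T_obs, length(r$Z) * mean(r$Z)^2, tolerance = 1e-12)
  })
})

test_that("run_wgst shares one shuffle stream across sets and skips carrier-free sets", {
  withr::with_seed(41, {
    mdrvs <- do.call(rbind, lapply(1:8, function(i) {
      make_variant(sprintf("v%d", i), gene = sprintf("g%d", i), pos = i * 100L)
    }))
    samples <- data.frame(sample_id = sprintf("s%03d", 1:60),
                          group = rep(c("case_ctd", "control"), each = 30),
                          sex = "unknown", ancestry = "CEU")
    carriers <- data.frame(
      variant_id = sprintf("v%d", sample(1:8, 25, replace = TRUE)),
      sample_id = sample(samples$sample_id, 25, replace = TRUE),
      allele_count = 1L)
    carriers <- unique(carriers)
    expr <- data.frame(gene = sprintf("g%d", 1:8), PA2_6 = 40, OFT_RV = 30,
                       LV_atria = 20)
    sets <- list(all = sprintf("g%d", 1:8), half = sprintf("g%d", 1:4),
                 empty_set = c("nope1", "nope2"))
    res <- run_wgst(mdrvs, carriers, samples, sets, expression = expr,
                    n_perm = 100, seed = 17)
    expect_true(res$skipped[res$set_name == "empty_set"])
    expect_equal(sum(!res$skipped), 2L)
    expect_equal(res$q[!res$skipped], bh_fdr(res$p_emp[!res$skipped]))

    # the single-set entry point sees the same stream: identical p for 'all'
    gc <- unique(data.frame(
      gene = mdrvs$gene[match(carriers$variant_id, mdrvs$variant_id)],
      sample_id = carriers$sample_id))
    single <- wgst_permutation_test(gc, samples, sets$all,
                                    expression_weights(expr),
                                    n_perm = 100, seed = 17)
    expect_identical(single$p_emp, res$p_emp[res$set_name == "all"])
  })
})
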