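#' Variant QC configuration
#'
#' Thresholds for the variant-level quality-control cascade. Defaults follow
#' the study conditions: SNVs require genotype rate >= 0.95 and exact
#' Hardy-Weinberg p >= 1e-6; indels, being harder to call, use the stricter
#' 0.97 / 1e-5; variants in configured excluded regions (low-copy repeats,
#' the 3-Mb 22q11.2 LCR22A-LCR22D deletion interval) are dropped outright;
#' cross-caller indel validation requires a reference-span Jaccard overlap of
#' at least 0.10.
#'
#' @param genotype_rate_min_snv,genotype_rate_min_indel Minimum fraction of
#'   non-missing genotypes, per variant class.
#' @param hwe_min_snv,hwe_min_indel Minimum exact HWE p-value, per class.
#' @param excluded_regions `data.frame` with `chrom`, `start`, `end`
#'   (1-based closed intervals), or `NULL` for none.
#' @param indel_overlap_min Minimum Jaccard overlap of indel reference spans
#'   for cross-caller validation.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(genotype_rate_min_snv = 0.95,
                      genotype_rate_min_indel = 0.97,
                      hwe_min_snv = 1e-6,
                      hwe_min_indel = 1e-5,
                      excluded_regions = NULL,
                      indel_overlap_min = 0.10) {
  stopifnot(genotype_rate_min_snv > 0, genotype_rate_min_snv <= 1,
            genotype_rate_min_indel > 0, genotype_rate_min_indel <= 1,
            hwe_min_snv > 0, hwe_min_snv <= 1,
            hwe_min_indel > 0, hwe_min_indel <= 1,
            indel_overlap_min > 0, indel_overlap_min <= 1)
  if (!is.null(excluded_regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(excluded_regions)),
              all(excluded_regions$start <= excluded_regions$end))
  }
  structure(list(genotype_rate_min_snv = genotype_rate_min_snv,
                 genotype_rate_min_indel = genotype_rate_min_indel,
                 hwe_min_snv = hwe_min_snv,
                 hwe_min_indel = hwe_min_indel,
                 excluded_regions = excluded_regions,
                 indel_overlap_min = indel_overlap_min),
            class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for a biallelic variant: conditional on the
#' observed allele counts, the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed configuration. Missing genotypes are ignored. A monomorphic
#' variant has a single attainable configuration and p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative integers).
#' @return Exact p-value in `[0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(100, 0, 0)   # monomorphic: p = 1
#' hwe_exact_test(25, 50, 25)  # equilibrium-looking: large p
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop_ctd("negative genotype count")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) stop_ctd("no called genotypes: HWE test undefined")
  n_alt <- 2L * n_hom_alt + n_het
  n_ref <- 2L * n_hom_ref + n_het
  if (n_alt == 0L || n_ref == 0L) return(1)
  # attainable het counts share the parity of the minor allele count
  m <- min(n_alt, n_ref)
  h <- seq.int(m %% 2L, m, by = 2L)
  # log P(het = h | n, n_alt), up to a shared constant:
  #   P ~ 2^h * n! / (hom_ref! h! hom_alt!)
  logp <- h * log(2) - lgamma((n_alt - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_ref - h) / 2 + 1)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_het, h)]
  if (is.na(obs)) stop_ctd("observed het count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

variant_span <- function(pos, ref) cbind(pos, pos + nchar(ref) - 1L)

in_excluded_region <- function(variants, regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    return(rep(FALSE, nrow(variants)))
  }
  span <- variant_span(variants$pos, variants$ref)
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (variants$chrom == regions$chrom[i] &
                    span[, 1L] <= regions$end[i] &
                    span[, 2L] >= regions$start[i])
  }
  hit
}

#' Apply variant-level QC filters
#'
#' Removes variants in this order: (1) inside an excluded region,
#' (2) genotype rate below the class threshold, (3) exact HWE p below the
#' class threshold, (4) monomorphic among called genotypes. Each variant is
#' removed by the first filter it fails, so the tally depends on the order
#' while the retained set does not.
#'
#' @param variants Variant table (see [read_variant_table()]).
#' @param genotype_counts Per-variant counts (see [read_genotype_counts()]);
#'   every variant must have a row.
#' @param config A [qc_config()].
#' @return A list with `retained` (variant ids), `tally` (a `data.frame`
#'   with removal counts per filter plus the retained count), `hwe_p`
#'   (named vector) and `sex_chrom_flagged` (ids of X/Y variants, which are
#'   tested like autosomes and flagged rather than special-cased).
#' @export
apply_variant_qc <- function(variants, genotype_counts, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  idx <- match(variants$variant_id, genotype_counts$variant_id)
  if (anyNA(idx)) {
    stop_ctd("variant without genotype counts: %s",
             variants$variant_id[is.na(idx)][1L])
  }
  gc <- genotype_counts[idx, , drop = FALSE]
  total <- gc$n_hom_ref + gc$n_het + gc$n_hom_alt + gc$n_missing
  if (any(total == 0L)) stop_ctd("variant with all-zero genotype counts")
  rate <- (total - gc$n_missing) / total
  is_indel <- variants$variant_class == "indel"
  rate_min <- ifelse(is_indel, config$genotype_rate_min_indel,
                     config$genotype_rate_min_snv)
  hwe_min <- ifelse(is_indel, config$hwe_min_indel, config$hwe_min_snv)

  region_fail <- in_excluded_region(variants, config$excluded_regions)
  rate_fail <- rate < rate_min
  called <- total - gc$n_missing
  hwe_p <- rep(NA_real_, nrow(variants))
  testable <- called > 0L
  hwe_p[testable] <- mapply(hwe_exact_test,
                            gc$n_hom_ref[testable], gc$n_het[testable],
                            gc$n_hom_alt[testable])
  hwe_fail <- !is.na(hwe_p) & hwe_p < hwe_min
  mono <- (gc$n_het + gc$n_hom_alt == 0L) | (gc$n_het + gc$n_hom_ref == 0L) |
    called == 0L

  removed_by <- rep(NA_character_, nrow(variants))
  removed_by[mono] <- "monomorphic"
  removed_by[hwe_fail] <- "hwe"
  removed_by[rate_fail] <- "genotype_rate"
  removed_by[region_fail] <- "excluded_region"

  filters <- c("excluded_region", "genotype_rate", "hwe", "monomorphic")
  tally <- data.frame(
    filter = c(filters, "retained"),
    n = c(vapply(filters, function(f) sum(removed_by == f, na.rm = TRUE),
                 integer(1L)),
          sum(is.na(removed_by))),
    stringsAsFactors = FALSE
  )
  list(retained = variants$variant_id[is.na(removed_by)],
       tally = tally,
       hwe_p = stats::setNames(hwe_p, variants$variant_id),
       sex_chrom_flagged = variants$variant_id[
         variants$chrom %in% c("X", "Y", "chrX", "chrY")])
}

jaccard_span <- function(a1, a2, b1, b2) {
  inter <- pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
  union <- (a2 - a1 + 1L) + (b2 - b1 + 1L) - inter
  inter / union
}

#' Cross-caller concordance validation
#'
#' Validates variants seen by two independent calling pipelines. SNVs are
#' validated iff `(chrom, pos, ref, alt)` match exactly (optionally also the
#' `genotype` column); indels are validated iff the Jaccard overlap of their
#' reference spans `[pos, pos + nchar(ref) - 1]` on the same chromosome is at
#' least `config$indel_overlap_min`. The relation is symmetric: swapping the
#' callsets exchanges `validated_a` and `validated_b`.
#'
#' @param callset_a,callset_b Variant tables (same coordinate convention).
#' @param config A [qc_config()].
#' @param genotype_mode If `TRUE`, SNV validation additionally requires equal
#'   `genotype` columns (both callsets must carry one).
#' @return List with `validated_a`, `validated_b` (variant ids validated in
#'   each callset).
#' @export
cross_caller_concordance <- function(callset_a, callset_b,
                                     config = qc_config(),
                                     genotype_mode = FALSE) {
  key <- function(cs) paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = "\r")
  keep_gt <- function(cs) if (genotype_mode) {
    if (is.null(cs$genotype)) stop_ctd("genotype_mode requires a 'genotype' column")
    paste(key(cs), cs$genotype, sep = "\r")
  } else key(cs)
  is_indel_a <- callset_a$variant_class == "indel"
  is_indel_b <- callset_b$variant_class == "indel"

  snv_match_a <- !is_indel_a & keep_gt(callset_a) %in% keep_gt(callset_b[!is_indel_b, , drop = FALSE])
  snv_match_b <- !is_indel_b & keep_gt(callset_b) %in% keep_gt(callset_a[!is_indel_a, , drop = FALSE])

  ia <- which(is_indel_a); ib <- which(is_indel_b)
  ind_match_a <- rep(FALSE, nrow(callset_a))
  ind_match_b <- rep(FALSE, nrow(callset_b))
  if (length(ia) > 0L && length(ib) > 0L) {
    sa <- variant_span(callset_a$pos[ia], callset_a$ref[ia])
    sb <- variant_span(callset_b$pos[ib], callset_b$ref[ib])
    for (i in seq_along(ia)) {
      same <- callset_b$chrom[ib] == callset_a$chrom[ia[i]]
      if (!any(same)) next
      j <- jaccard_span(sa[i, 1L], sa[i, 2L], sb[same, 1L], sb[same, 2L])
      ok <- j >= config$indel_overlap_min
      if (any(ok)) {
        ind_match_a[ia[i]] <- TRUE
        ind_match_b[ib[same][ok]] <- TRUE
      }
    }
  }
  list(validated_a = callset_a$variant_id[snv_match_a | ind_match_a],
       validated_b = callset_b$variant_id[snv_match_b | ind_match_b])
}
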