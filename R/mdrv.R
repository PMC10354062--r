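#' MDRV filter configuration
#'
#' Thresholds of the most-damaging-rare-variant (MDRV) cascade: gnomAD
#' alternative allele frequency < 1% (absent AAF = novel, which passes),
#' a damaging functional class, and the conservation/deleteriousness/
#' constraint filters phastCons >= 0.5, CADD >= 10 and CCRS >= 80.
#'
#' Functional classes: loss-of-function (LoF) consequences are frameshift,
#' stop gain, splice donor, splice acceptor, stop loss and start loss;
#' damaging missense (D-mis) requires a MetaSVM "D" call; damaging splicing
#' (D-splicing) requires spliceAI >= 0.5 or both dbscSNV ensemble scores
#' (ada and rf) >= 0.6 — the tools' conventional operating points, since no
#' cutoff is universal.
#'
#' @param aaf_max Maximum gnomAD AAF (exclusive).
#' @param phastcons_min,cadd_min,ccrs_min Score thresholds (inclusive).
#' @param metasvm_damaging_call MetaSVM label treated as damaging.
#' @param spliceai_min SpliceAI delta-score cutoff.
#' @param dbscsnv_min Cutoff applied to both dbscSNV `ada` and `rf` scores.
#' @param lof_consequences Consequence labels treated as loss of function.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(aaf_max = 0.01,
                          phastcons_min = 0.5,
                          cadd_min = 10,
                          ccrs_min = 80,
                          metasvm_damaging_call = "D",
                          spliceai_min = 0.5,
                          dbscsnv_min = 0.6,
                          lof_consequences = c("frameshift", "stop_gain",
                                               "splice_donor", "splice_acceptor",
                                               "stop_loss", "start_loss")) {
  stopifnot(aaf_max > 0, aaf_max <= 1,
            phastcons_min >= 0, phastcons_min <= 1,
            cadd_min >= 0, ccrs_min >= 0, ccrs_min <= 100,
            spliceai_min >= 0, spliceai_min <= 1,
            dbscsnv_min >= 0, dbscsnv_min <= 1)
  structure(list(aaf_max = aaf_max, phastcons_min = phastcons_min,
                 cadd_min = cadd_min, ccrs_min = ccrs_min,
                 metasvm_damaging_call = metasvm_damaging_call,
                 spliceai_min = spliceai_min, dbscsnv_min = dbscsnv_min,
                 lof_consequences = lof_consequences),
            class = "filter_config")
}

#' Classify variants into damaging functional classes
#'
#' Assigns each variant one of `LoF`, `D-mis`, `D-splicing` or `none`, with
#' precedence LoF > D-mis > D-splicing. Missing scores fail their clause
#' (they never qualify a variant).
#'
#' @param variants Variant table (one or more rows).
#' @param config A [filter_config()].
#' @return Character vector, one class label per row.
#' @export
#' @examples
#' v <- data.frame(consequence = c("stop_gain", "missense", "splice_region"),
#'                 metasvm = c(NA, "D", NA),
#'                 spliceai = c(NA, NA, NA),
#'                 ada = c(NA, NA, 0.95), rf = c(NA, NA, 0.9))
#' classify_functional(v)
classify_functional <- function(variants, config = filter_config()) {
  if (is.null(variants$consequence) || anyNA(variants$consequence)) {
    stop_ctd("classify_functional: 'consequence' must be present for every row")
  }
  n <- nrow(variants)
  num <- function(col) {
    x <- variants[[col]]
    if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  }
  metasvm <- variants$metasvm
  if (is.null(metasvm)) metasvm <- rep(NA_character_, n)
  lof <- variants$consequence %in% config$lof_consequences
  dmis <- variants$consequence == "missense" &
    !is.na(metasvm) & metasvm == config$metasvm_damaging_call
  spliceai <- num("spliceai"); ada <- num("ada"); rf <- num("rf")
  dspl <- (!is.na(spliceai) & spliceai >= config$spliceai_min) |
    (!is.na(ada) & !is.na(rf) &
       ada >= config$dbscsnv_min & rf >= config$dbscsnv_min)
  out <- rep("none", n)
  out[dspl] <- "D-splicing"
  out[dmis] <- "D-mis"
  out[lof] <- "LoF"
  out
}

#' Select MDRVs through the filter cascade
#'
#' Retains variants that simultaneously pass every cascade stage: gnomAD
#' rarity (AAF absent or < `aaf_max`), a damaging functional class,
#' phastCons >= `phastcons_min`, CADD >= `cadd_min` and CCRS >= `ccrs_min`.
#' Missing phastCons/CADD/CCRS fail their filter (the high-confidence set
#' excludes unscorable variants). Each stage is a pure predicate, so the
#' retained set does not depend on the order in which stages are applied;
#' the survivor tally is reported in cascade order.
#'
#' @param variants Variant table (assumed to have passed QC).
#' @param config A [filter_config()].
#' @return A list with `mdrvs` (the retained rows plus a `functional_class`
#'   column) and `tally` (`data.frame` of survivors after each stage, in
#'   cascade order).
#' @export
select_mdrv <- function(variants, config = filter_config()) {
  fclass <- classify_functional(variants, config)
  pass_num <- function(col, min) {
    x <- as.numeric(variants[[col]])
    !is.na(x) & x >= min
  }
  stages <- list(
    rarity = is.na(variants$aaf_gnomad) | variants$aaf_gnomad < config$aaf_max,
    functional_class = fclass != "none",
    phastcons = pass_num("phastcons", config$phastcons_min),
    cadd = pass_num("cadd", config$cadd_min),
    ccrs = pass_num("ccrs", config$ccrs_min)
  )
  keep <- rep(TRUE, nrow(variants))
  survivors <- integer(length(stages))
  for (i in seq_along(stages)) {
    keep <- keep & stages[[i]]
    survivors[i] <- sum(keep)
  }
  mdrvs <- variants[keep, , drop = FALSE]
  mdrvs$functional_class <- fclass[keep]
  rownames(mdrvs) <- NULL
  list(mdrvs = mdrvs,
       tally = data.frame(stage = c("input", names(stages)),
                          n = c(nrow(variants), survivors),
                          stringsAsFactors = FALSE))
}

#' Per-subject MDRV burden
#'
#' Counts, for every sample in the sheet, the number of distinct MDRVs
#' carried. A homozygous carrier counts the variant once (it is a variant
#' count, not an allele count); subjects absent from the carrier table get 0.
#'
#' @param mdrvs MDRV table (as `select_mdrv()$mdrvs`).
#' @param carriers Carrier table restricted to MDRV ids; a row referencing a
#'   variant absent from `mdrvs` is an error.
#' @param samples Sample sheet.
#' @return Named integer vector over `samples$sample_id`.
#' @export
per_subject_burden <- function(mdrvs, carriers, samples) {
  unknown <- setdiff(carriers$variant_id, mdrvs$variant_id)
  if (length(unknown) > 0L) {
    stop_ctd("carrier table references non-MDRV variant_id: %s", unknown[1L])
  }
  counts <- stats::setNames(integer(nrow(samples)), samples$sample_id)
  if (nrow(carriers) > 0L) {
    tab <- table(carriers$sample_id)
    hit <- intersect(names(tab), samples$sample_id)
    counts[hit] <- as.integer(tab[hit])
  }
  counts
}
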