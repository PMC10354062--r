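# Small in-code fixtures shared across test files.

variant_header <- function() {
  paste("variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
        "aaf_gnomad", "metasvm", "spliceai", "ada", "rf", "phastcons",
        "cadd", "ccrs", sep = "\t")
}

write_variant_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(variant_header(), rows), path)
  path
}

# a fully passing MDRV row as a data frame, with overridable fields
make_variant <- function(variant_id = "v1", chrom = "1", pos = 100L,
                         ref = "A", alt = "G", gene = "GENE1",
                         consequence = "missense", aaf_gnomad = NA_real_,
                         metasvm = "D", spliceai = NA_real_, ada = NA_real_,
                         rf = NA_real_, phastcons = 0.9, cadd = 25,
                         ccrs = 90) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             aaf_gnomad = aaf_gnomad, metasvm = metasvm, spliceai = spliceai,
             ada = ada, rf = rf, phastcons = phastcons, cadd = cadd,
             ccrs = ccrs,
             variant_class = if (nchar(ref) != nchar(alt)) "indel" else "SNV",
             stringsAsFactors = FALSE)
}

# random variant table spanning all cascade thresholds (scores straddle the
# cutoffs so every stage has passes and failures)
random_variant_table <- function(n = 30) {
  cons <- sample(c("frameshift", "stop_gain", "missense", "splice_region",
                   "other"), n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(
      variant_id = sprintf("rv%03d", i),
      pos = i * 10L,
      gene = sprintf("G%02d", sample.int(10L, 1L)),
      consequence = cons[i],
      aaf_gnomad = if (runif(1) < 0.3) NA_real_ else runif(1, 0, 0.05),
      metasvm = sample(c("D", "T", NA_character_), 1L),
      spliceai = if (runif(1) < 0.5) NA_real_ else runif(1),
      ada = if (runif(1) < 0.5) NA_real_ else runif(1),
      rf = if (runif(1) < 0.5) NA_real_ else runif(1),
      phastcons = if (runif(1) < 0.1) NA_real_ else runif(1),
      cadd = runif(1, 0, 40),
      ccrs = if (runif(1) < 0.1) NA_real_ else runif(1, 0, 100))
  }))
}

small_synth_config <- function(...) {
  synthetic_config(n_cases = 100, n_controls = 100, n_genes = 1200,
                   enriched_set_size = 150, decoy_size_range = c(50, 400),
                   ...)
}
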