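#' Read an annotated variant table
#'
#' Reads one row per annotated variant from a TSV file (or, optionally, the
#' INFO fields of a VCF) into a typed data frame. Empty cells, `"."` and
#' `"NA"` in score columns become `NA` ("absent"); an absent gnomAD allele
#' frequency means the variant is novel. The variant class (`SNV` vs `indel`)
#' is derived from the allele lengths: an indel iff `nchar(ref) != nchar(alt)`.
#'
#' Required TSV columns: `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `aaf_gnomad`, `metasvm`, `spliceai`, `ada`, `rf`,
#' `phastcons`, `cadd`, `ccrs`. The VCF dialect maps INFO keys of the same
#' names (requires the \pkg{vcfR} package); `gene` etc. must be plain INFO
#' annotations, one gene symbol per record.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return A `data.frame` with one row per variant: character columns
#'   `variant_id`, `chrom`, `ref`, `alt`, `gene`, `consequence`, `metasvm`,
#'   `variant_class`; integer `pos`; numeric score columns.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
#'         "aaf_gnomad", "metasvm", "spliceai", "ada", "rf", "phastcons",
#'         "cadd", "ccrs", sep = "\t"),
#'   "v1\t1\t100\tA\tT\tGENE1\tmissense\t9.14E-06\tD\t\t\t\t0.9\t26.2\t98.5"
#' ), tsv)
#' read_variant_table(tsv)
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ctd("variant table not found: %s", path)
  if (dialect == "vcf") return(read_variant_vcf(path))
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = character(), check.names = FALSE)
  require_columns(df, variant_columns(), "variant table")
  as_variant_table(df)
}

variant_columns <- function() {
  c("variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
    "aaf_gnomad", "metasvm", "spliceai", "ada", "rf", "phastcons",
    "cadd", "ccrs")
}

consequence_levels <- function() {
  c("frameshift", "stop_gain", "splice_donor", "splice_acceptor",
    "stop_loss", "start_loss", "missense", "splice_region", "other")
}

# Validate and type a character-mode variant table (shared by TSV and VCF).
as_variant_table <- function(df) {
  n <- nrow(df)
  rows <- seq_len(n)
  out <- data.frame(
    variant_id = trimws(df$variant_id),
    chrom      = trimws(df$chrom),
    pos        = rep(NA_integer_, n),
    ref        = trimws(df$ref),
    alt        = trimws(df$alt),
    gene       = trimws(df$gene),
    consequence = trimws(df$consequence),
    stringsAsFactors = FALSE
  )
  pos <- parse_score_column(df$pos, "pos", rows)
  if (anyNA(pos)) stop_ctd("column 'pos': missing position")
  if (any(pos < 1 | pos != floor(pos))) {
    stop_ctd("column 'pos': positions must be integers >= 1 (1-based)")
  }
  out$pos <- as.integer(pos)
  if (anyDuplicated(out$variant_id)) {
    stop_ctd("duplicate variant_id: %s",
             out$variant_id[anyDuplicated(out$variant_id)])
  }
  if (any(out$ref == out$alt)) {
    stop_ctd("ref equals alt for variant %s", out$variant_id[out$ref == out$alt][1L])
  }
  bad_cons <- !out$consequence %in% consequence_levels()
  if (any(bad_cons)) {
    stop_ctd("unknown consequence '%s' (allowed: %s)",
             out$consequence[bad_cons][1L],
             paste(consequence_levels(), collapse = ", "))
  }
  metasvm <- trimws(df$metasvm)
  metasvm[metasvm %in% c("", ".", "NA")] <- NA_character_
  if (any(!is.na(metasvm) & !metasvm %in% c("D", "T"))) {
    stop_ctd("column 'metasvm': values must be D, T or absent")
  }
  out$metasvm <- metasvm
  out$aaf_gnomad <- parse_score_column(df$aaf_gnomad, "aaf_gnomad", rows)
  check_in_range(out$aaf_gnomad, 0, 1, "aaf_gnomad")
  for (col in c("spliceai", "ada", "rf", "phastcons")) {
    out[[col]] <- parse_score_column(df[[col]], col, rows)
    check_in_range(out[[col]], 0, 1, col)
  }
  out$cadd <- parse_score_column(df$cadd, "cadd", rows)
  if (any(!is.na(out$cadd) & out$cadd < 0)) stop_ctd("column 'cadd': negative score")
  out$ccrs <- parse_score_column(df$ccrs, "ccrs", rows)
  check_in_range(out$ccrs, 0, 100, "ccrs")
  out$variant_class <- ifelse(nchar(out$ref) != nchar(out$alt), "indel", "SNV")
  out[, c(variant_columns(), "variant_class")]
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_ctd("reading VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_keys <- c("gene", "consequence", "aaf_gnomad", "metasvm", "spliceai",
                 "ada", "rf", "phastcons", "cadd", "ccrs")
  info <- lapply(info_keys, function(k) {
    x <- vcfR::extract.info(v, element = k)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  })
  names(info) <- info_keys
  id <- fix$ID
  if (is.null(id) || all(is.na(id) | id == ".")) {
    id <- paste0(fix$CHROM, "_", fix$POS, "_", fix$REF, "_", fix$ALT)
  }
  df <- data.frame(variant_id = id, chrom = fix$CHROM, pos = fix$POS,
                   ref = fix$REF, alt = fix$ALT, info,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  require_columns(df, variant_columns(), "VCF-derived variant table")
  as_variant_table(df)
}

#' Read a long-format carrier table
#'
#' A carrier table links variants to subjects: one row per
#' (variant, sample) pair with `allele_count` 1 (heterozygous) or 2
#' (homozygous alternate). Pairs absent from the table are non-carriers.
#'
#' @param path TSV with columns `variant_id`, `sample_id`, `allele_count`.
#' @return A `data.frame` with those three columns, `allele_count` integer.
#' @export
read_carrier_table <- function(path) {
  if (!file.exists(path)) stop_ctd("carrier table not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  require_columns(df, c("variant_id", "sample_id", "allele_count"),
                  "carrier table")
  ac <- parse_score_column(df$allele_count, "allele_count")
  if (any(is.na(ac) | !ac %in% c(1, 2))) {
    stop_ctd("column 'allele_count': values must be 1 or 2")
  }
  out <- data.frame(variant_id = trimws(df$variant_id),
                    sample_id = trimws(df$sample_id),
                    allele_count = as.integer(ac),
                    stringsAsFactors = FALSE)
  key <- paste(out$variant_id, out$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop_ctd("duplicate (variant, sample) pair: (%s, %s)",
             out$variant_id[i], out$sample_id[i])
  }
  out
}

#' Read the sample sheet
#'
#' @param path TSV with columns `sample_id`, `group`, `sex`, `ancestry`.
#'   `group` must be one of `case_ctd`, `control`, `other_chd`, `excluded`;
#'   `sex` one of `male`, `female`, `unknown`; `ancestry` is a free stratum
#'   label.
#' @return A `data.frame` of sample records.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_ctd("sample sheet not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  require_columns(df, c("sample_id", "group", "sex", "ancestry"),
                  "sample sheet")
  out <- data.frame(sample_id = trimws(df$sample_id),
                    group = trimws(df$group),
                    sex = trimws(df$sex),
                    ancestry = trimws(df$ancestry),
                    stringsAsFactors = FALSE)
  validate_samples(out)
  out
}

sample_groups <- function() c("case_ctd", "control", "other_chd", "excluded")

validate_samples <- function(samples) {
  if (anyDuplicated(samples$sample_id)) {
    stop_ctd("duplicate sample_id: %s",
             samples$sample_id[duplicated(samples$sample_id)][1L])
  }
  bad <- !samples$group %in% sample_groups()
  if (any(bad)) {
    stop_ctd("unknown group label '%s' (allowed: %s)",
             samples$group[bad][1L], paste(sample_groups(), collapse = ", "))
  }
  bad_sex <- !samples$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop_ctd("unknown sex label '%s' (allowed: male, female, unknown)",
             samples$sex[bad_sex][1L])
  }
  invisible(TRUE)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated; sets are order-insensitive.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of gene symbols, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ctd("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_ctd("GMT file is empty: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    stop_ctd("GMT line %d has %d field(s); need name, description and >= 1 gene",
             which(nfield < 3L)[1L], nfield[nfield < 3L][1L])
  }
  names_ <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names_)) {
    stop_ctd("duplicate gene-set name: %s", names_[duplicated(names_)][1L])
  }
  desc <- vapply(parts, `[[`, character(1L), 2L)
  sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  sets <- lapply(sets, function(g) g[nzchar(g)])
  if (any(lengths(sets) == 0L)) {
    stop_ctd("gene set '%s' is empty", names_[lengths(sets) == 0L][1L])
  }
  names(sets) <- names_
  names(desc) <- names_
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (as from [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x tissue expression matrix
#'
#' @param path TSV with a `gene` column plus one numeric column per tissue
#'   (reads per million, non-negative). Default tissue panel elsewhere in the
#'   package: pharyngeal arches 2-6 (`PA2_6`), outflow tract + right
#'   ventricle (`OFT_RV`), left ventricle + atria (`LV_atria`).
#' @return A `data.frame` with `gene` and the tissue columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_ctd("expression table not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  require_columns(df, "gene", "expression table")
  tissues <- setdiff(names(df), "gene")
  if (length(tissues) == 0L) stop_ctd("expression table has no tissue columns")
  out <- data.frame(gene = trimws(df$gene), stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    stop_ctd("duplicate gene symbol in expression table: %s",
             out$gene[duplicated(out$gene)][1L])
  }
  for (t in tissues) {
    out[[t]] <- parse_score_column(df[[t]], t)
    if (any(is.na(out[[t]]))) stop_ctd("column '%s': missing RPM value", t)
    if (any(out[[t]] < 0)) stop_ctd("column '%s': negative RPM", t)
  }
  out
}

#' Per-gene mean expression across tissues
#' @param expr Expression data frame as from [read_expression()].
#' @return Named numeric vector of per-gene mean RPM.
#' @export
expression_means <- function(expr) {
  tissues <- setdiff(names(expr), "gene")
  stats::setNames(rowMeans(as.matrix(expr[, tissues, drop = FALSE])), expr$gene)
}

#' Read excluded genomic regions
#'
#' BED-like TSV with columns `chrom`, `start`, `end`; coordinates are
#' interpreted as 1-based, fully closed intervals after parsing.
#'
#' @param path Path to the region file.
#' @return A `data.frame` with `chrom` (character), `start`, `end` (integer).
#' @export
read_excluded_regions <- function(path) {
  if (!file.exists(path)) stop_ctd("region file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  require_columns(df, c("chrom", "start", "end"), "excluded regions")
  start <- as.integer(parse_score_column(df$start, "start"))
  end <- as.integer(parse_score_column(df$end, "end"))
  if (any(start > end)) stop_ctd("excluded region with start > end")
  data.frame(chrom = trimws(df$chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read per-variant genotype counts
#'
#' @param path TSV with columns `variant_id`, `n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n_missing` (non-negative integers).
#' @return A typed `data.frame`.
#' @export
read_genotype_counts <- function(path) {
  if (!file.exists(path)) stop_ctd("genotype count table not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  cols <- c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")
  require_columns(df, c("variant_id", cols), "genotype counts")
  out <- data.frame(variant_id = trimws(df$variant_id),
                    stringsAsFactors = FALSE)
  for (col in cols) {
    v <- parse_score_column(df[[col]], col)
    if (any(is.na(v) | v < 0 | v != floor(v))) {
      stop_ctd("column '%s': values must be non-negative integers", col)
    }
    out[[col]] <- as.integer(v)
  }
  if (anyDuplicated(out$variant_id)) stop_ctd("duplicate variant_id in genotype counts")
  out
}

#' Cross-validate a loaded input bundle
#'
#' Checks referential integrity between the carrier table, variant table and
#' sample sheet (every carrier row must reference a known variant and a known
#' sample; no duplicate pairs).
#'
#' @param variants,carriers,samples Data frames as returned by the readers.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validate_bundle <- function(variants, carriers, samples) {
  validate_samples(samples)
  unknown_v <- setdiff(carriers$variant_id, variants$variant_id)
  if (length(unknown_v) > 0L) {
    stop_ctd("carrier table references unknown variant_id: %s", unknown_v[1L])
  }
  unknown_s <- setdiff(carriers$sample_id, samples$sample_id)
  if (length(unknown_s) > 0L) {
    stop_ctd("carrier table references unknown sample_id: %s", unknown_s[1L])
  }
  invisible(TRUE)
}

# Deterministic TSV writer: fixed column order, no quoting, full precision
# (15 significant digits, so numeric round trips are exact to >= 12 digits).
write_tsv <- function(df, path) {
  df2 <- df
  num <- vapply(df2, is.numeric, logical(1L)) &
    !vapply(df2, is.integer, logical(1L))
  df2[num] <- lapply(df2[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.15g", x))
  })
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Writes one TSV per result table (deterministic column order) plus a
#' `summary.json` carrying the seed, the thresholds in force and per-stage
#' counts, so a run is auditable from its outputs alone.
#'
#' @param results Named list of data frames (e.g. `ora`, `wgst`,
#'   `recurrence`, `burden`, `mdrv_tally`).
#' @param out_dir Output directory (created if needed).
#' @param summary Named list appended to `summary.json` (seed, configs,
#'   stage counts). Optional.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir, summary = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(is.list(results), !is.null(names(results)))
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) write_tsv(x, file.path(out_dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
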