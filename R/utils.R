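# internal helpers shared across readers and stats

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_ctd <- function(...) stop(sprintf(...), call. = FALSE)

# Parse a character column of scores: "", ".", "NA" -> NA; anything else must
# be a finite number (scientific notation accepted). Errors name the column
# and the offending 1-based data row.
parse_score_column <- function(x, column, lines = seq_along(x)) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | x == "." | x == "NA"
  out <- rep(NA_real_, length(x))
  if (any(!miss)) {
    val <- suppressWarnings(as.numeric(x[!miss]))
    bad <- is.na(val)
    if (any(bad)) {
      i <- which(!miss)[which(bad)[1L]]
      stop_ctd("column '%s': unparsable value '%s' at data row %d",
               column, x[i], lines[i])
    }
    out[!miss] <- val
  }
  out
}

require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_ctd("%s: missing mandatory column(s): %s",
             what, paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

check_in_range <- function(x, lo, hi, name, na_ok = TRUE) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop_ctd("column '%s': value %g outside [%g, %g]", name, x[which(bad)[1L]], lo, hi)
  }
  if (!na_ok && anyNA(x)) stop_ctd("column '%s': missing value not allowed", name)
  invisible(TRUE)
}

# Seed handling: set the RNG reproducibly inside a function without
# clobbering the caller's stream, unless seed is NULL.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}
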