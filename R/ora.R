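#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` genes from a set of size `M` when `n`
#' genes are drawn without replacement from a background of `N`, i.e.
#' \deqn{p = 1 - \sum_{i=0}^{k-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}.}
#' Computed in log space via the hypergeometric tail, numerically stable for
#' backgrounds up to at least 1e5. `k = 0` gives p = 1 (the empty sum).
#'
#' @param N Background size (total genes in the analysis).
#' @param M Genes of the set inside the background.
#' @param n Genes drawn (e.g. recurrently affected genes).
#' @param k Drawn genes inside the set.
#' @return Upper-tail probability `P(X >= k)`. Vectorized over arguments.
#' @export
#' @examples
#' ora_pvalue(5, 2, 2, 2)  # = choose(2,2)/choose(5,2) = 0.1
ora_pvalue <- function(N, M, n, k) {
  args <- cbind(N, M, n, k)
  N <- args[, 1L]; M <- args[, 2L]; n <- args[, 3L]; k <- args[, 4L]
  if (any(args < 0) || any(args != floor(args))) {
    stop_ctd("ora_pvalue: arguments must be non-negative integers")
  }
  if (any(M > N) || any(n > N) || any(k > pmin(n, M))) {
    stop_ctd("ora_pvalue: need k <= min(n, M), M <= N, n <= N")
  }
  unname(ifelse(k == 0L, 1,
                stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity; output order matches input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (q-values), same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_ctd("bh_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run over-representation analysis across gene sets and scenarios
#'
#' For each scenario (e.g. cases/controls with and without the
#' cardiac-expression filter) and each gene set, computes the hypergeometric
#' tail with `N` = number of MDRV-affected genes in the scenario (the
#' background), `M` = affected genes inside the set, `n` = recurrently
#' affected genes, `k` = recurrent genes inside the set. BH correction is
#' applied over the whole family (all sets x all scenarios; the study family
#' is 19 sets x 4 scenarios = 76 tests).
#'
#' @param scenarios Named list; each element a list with `recurrent` and
#'   `affected` character vectors of gene symbols, `recurrent` a subset of
#'   `affected`. A single scenario may be passed as
#'   `list(default = list(...))`.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @return A `data.frame` of class `ctd_ora`: one row per scenario x set
#'   with `scenario`, `set_name`, `N`, `M`, `n`, `k`, `p`, `q`.
#' @export
run_ora <- function(scenarios, gene_sets) {
  stopifnot(is.list(scenarios), length(scenarios) > 0L,
            !is.null(names(scenarios)),
            is.list(gene_sets), !is.null(names(gene_sets)))
  rows <- list()
  for (sc in names(scenarios)) {
    affected <- unique(scenarios[[sc]]$affected)
    recurrent <- unique(scenarios[[sc]]$recurrent)
    if (length(affected) == 0L) stop_ctd("scenario '%s': empty background", sc)
    if (!all(recurrent %in% affected)) {
      stop_ctd("scenario '%s': recurrent genes must be a subset of affected genes", sc)
    }
    for (set_name in names(gene_sets)) {
      set <- gene_sets[[set_name]]
      M <- sum(affected %in% set)
      k <- sum(recurrent %in% set)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, set_name = set_name,
        N = length(affected), M = M, n = length(recurrent), k = k,
        p = ora_pvalue(length(affected), M, length(recurrent), k),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  class(out) <- c("ctd_ora", "data.frame")
  out
}

#' @export
print.ctd_ora <- function(x, ...) {
  cat("Over-representation analysis:",
      length(unique(x$set_name)), "gene set(s) x",
      length(unique(x$scenario)), "scenario(s);",
      "BH family of", nrow(x), "tests\n")
  sig <- x[x$q <= 0.05, , drop = FALSE]
  if (nrow(sig) > 0L) {
    cat("Significant after FDR (q <= 0.05):\n")
    print.data.frame(sig, row.names = FALSE, digits = 4)
  } else {
    cat("No set significant after FDR (q <= 0.05)\n")
  }
  invisible(x)
}
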