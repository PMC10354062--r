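# Weighted gene-set permutation test: per-gene Fisher-exact z statistics
# combined through the expression-weighted quadratic form T = Z'JZ with
# J = ww'/(w'w), and an empirical permutation null.

# Conditional 2x2 lookup for a gene with m carriers among n1 cases and n2
# controls. Under case/control label shuffles m is fixed, so the two-sided
# Fisher p and the signed z depend only on the number of case carriers a.
# Returns the support (amin..amax) with p and z per attainable a.
fet_support_table <- function(m, n1, n2) {
  amin <- max(0L, m - n2)
  amax <- min(m, n1)
  a <- amin:amax
  d <- stats::dhyper(a, n1, n2, m)
  # fisher.test's two-sided rule: sum point probabilities <= obs * (1 + 1e-7)
  p <- vapply(seq_along(a),
              function(i) min(1, sum(d[d <= d[i] * (1 + 1e-7)])),
              numeric(1L))
  frac_case <- a / n1
  frac_ctrl <- (m - a) / n2
  sgn <- sign(frac_case - frac_ctrl)
  z <- ifelse(p >= 1, 0, sgn * stats::qnorm(p / 2, lower.tail = FALSE))
  list(amin = amin, amax = amax, p = p, z = z)
}

#' Gene-level Fisher exact test and signed z statistic
#'
#' Two-sided Fisher exact p for the 2x2 carrier table
#' (`a` case carriers, `b` non-carrier cases, `c` control carriers, `d`
#' non-carrier controls), the sample odds ratio, and the signed
#' inverse-normal transform \eqn{z = s \Phi^{-1}(1 - p/2)} with
#' `s = +1` when the case carrier fraction exceeds the control fraction,
#' `-1` when it is smaller and `0` when equal; p = 1 maps to z = 0.
#'
#' @param a,b,c,d Non-negative cell counts; `a + b > 0` and `c + d > 0`.
#' @return List with `p`, `odds_ratio` and `z`.
#' @export
#' @examples
#' gene_fet_z(0, 456, 0, 537)  # no carriers: p = 1, z = 0
gene_fet_z <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop_ctd("gene_fet_z: cells must be non-negative integers")
  }
  n1 <- a + b; n2 <- c + d
  if (n1 == 0 || n2 == 0) stop_ctd("gene_fet_z: need subjects in both groups")
  tab <- fet_support_table(a + c, n1, n2)
  i <- a - tab$amin + 1L
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p = tab$p[i], odds_ratio = or, z = tab$z[i])
}

#' Expression-weighted quadratic-form statistic
#'
#' \eqn{T = Z^T J Z} with the rank-one projection
#' \eqn{J = ww^T / (w^Tw)}, computed in its algebraically identical scalar
#' form \eqn{T = (\sum_i w_i z_i)^2 / \sum_i w_i^2 \ge 0}. T is invariant to
#' positive rescaling of `w` and to simultaneous permutation of `Z` and `w`.
#'
#' @param Z Numeric vector of gene-level z statistics (length k >= 1).
#' @param w Non-negative weights, same length, at least one positive.
#' @return The scalar statistic T.
#' @export
#' @examples
#' t_statistic(c(1, -1), c(1, 1))  # cancellation: 0
#' t_statistic(3, 2)               # 36 / 4 = 9
t_statistic <- function(Z, w) {
  if (length(Z) != length(w) || length(Z) < 1L) {
    stop_ctd("t_statistic: Z and w must be equal-length vectors, k >= 1")
  }
  if (any(w < 0)) stop_ctd("t_statistic: weights must be non-negative")
  if (all(w == 0)) stop_ctd("t_statistic: all-zero weight vector")
  sum(w * Z)^2 / sum(w^2)
}

#' Expression weights for the weighted gene-set test
#'
#' Natural log of (mean RPM across the tissue panel + 1); the pseudocount
#' guards genes with zero measured expression.
#'
#' @param expr Expression data frame (see [read_expression()]).
#' @param pseudocount Added before the log (default 1).
#' @return Named non-negative weight vector over the genes of `expr`.
#' @export
expression_weights <- function(expr, pseudocount = 1) {
  m <- expression_means(expr)
  log(m + pseudocount)
}

# Distinct gene-level carriage: data.frame(gene, sample_id) pairs.
as_gene_carriers <- function(mdrvs, carriers) {
  gene_of <- stats::setNames(mdrvs$gene, mdrvs$variant_id)
  unknown <- setdiff(carriers$variant_id, names(gene_of))
  if (length(unknown) > 0L) {
    stop_ctd("carrier table references non-MDRV variant_id: %s", unknown[1L])
  }
  unique(data.frame(gene = unname(gene_of[carriers$variant_id]),
                    sample_id = carriers$sample_id,
                    stringsAsFactors = FALSE))
}

# Shared permutation engine. gene_carriers: distinct (gene, sample_id)
# pairs over case_ctd/control subjects; sets: named list of gene vectors;
# weights: named vector (missing genes get weight 0). One label-shuffle
# stream is drawn once and evaluates every set, so set-level statistics are
# comparable across sets replicate by replicate.
wgst_engine <- function(gene_carriers, samples, sets, weights,
                        n_perm = 2000, seed = NULL) {
  keep <- samples$group %in% c("case_ctd", "control")
  samples <- samples[keep, , drop = FALSE]
  y <- samples$group == "case_ctd"
  if (sum(y) < 2L || sum(!y) < 2L) {
    stop_ctd("weighted gene-set test needs at least 2 subjects per group")
  }
  gene_carriers <- gene_carriers[
    gene_carriers$sample_id %in% samples$sample_id, , drop = FALSE]
  carried <- sort(unique(gene_carriers$gene))
  set_genes <- lapply(sets, function(s) intersect(carried, s))
  genes <- sort(unique(unlist(set_genes, use.names = FALSE)))

  results <- vector("list", length(sets))
  names(results) <- names(sets)
  if (length(genes) > 0L) {
    gi <- match(gene_carriers$gene, genes)
    si <- match(gene_carriers$sample_id, samples$sample_id)
    ok <- !is.na(gi)
    M <- Matrix::sparseMatrix(i = gi[ok], j = si[ok], x = 1,
                              dims = c(length(genes), nrow(samples)))
    m_g <- as.integer(Matrix::rowSums(M))
    n1 <- sum(y); n2 <- sum(!y)
    tabs <- lapply(m_g, fet_support_table, n1 = n1, n2 = n2)

    perm <- with_seed(seed, {
      Yp <- vapply(seq_len(n_perm), function(i) sample(y), logical(nrow(samples)))
      storage.mode(Yp) <- "double"
      Yp
    })
    a_obs <- as.vector(M %*% as.numeric(y))
    A <- as.matrix(M %*% perm)
    z_obs <- numeric(length(genes))
    Zp <- matrix(0, nrow = length(genes), ncol = n_perm)
    for (g in seq_along(genes)) {
      tab <- tabs[[g]]
      z_obs[g] <- tab$z[a_obs[g] - tab$amin + 1L]
      Zp[g, ] <- tab$z[A[g, ] - tab$amin + 1L]
    }
  }

  w_all <- stats::setNames(numeric(length(genes)), genes)
  known <- intersect(genes, names(weights))
  w_all[known] <- weights[known]
  if (any(w_all < 0)) stop_ctd("weights must be non-negative")

  for (s in names(sets)) {
    gs <- set_genes[[s]]
    if (length(gs) == 0L) {
      results[[s]] <- list(set_name = s, skipped = TRUE,
                           reason = "no gene in the set carries an MDRV")
      next
    }
    idx <- match(gs, genes)
    w <- w_all[idx]
    if (all(w == 0)) {
      results[[s]] <- list(set_name = s, skipped = TRUE,
                           reason = "all genes in the set have zero weight")
      next
    }
    denom <- sum(w^2)
    T_obs <- sum(w * z_obs[idx])^2 / denom
    T_perm <- as.vector(crossprod(w, Zp[idx, , drop = FALSE]))^2 / denom
    n_extreme <- 1L + sum(T_perm >= T_obs)
    results[[s]] <- list(set_name = s, skipped = FALSE,
                         genes = gs, Z = unname(z_obs[idx]), w = unname(w),
                         T_obs = T_obs, T_perm = T_perm,
                         n_extreme = n_extreme, N_perm = n_perm,
                         p_emp = min(1, n_extreme / n_perm))
  }
  results
}

#' Weighted gene-set permutation test for one gene set
#'
#' Computes the observed statistic \eqn{T = Z^T J Z} for the genes of the
#' set that carry at least one MDRV, then shuffles case/control labels
#' `n_perm` times, recomputing every per-gene Fisher-exact z and T per
#' replicate. The empirical p-value is `n / N` with the observed statistic
#' counted among the extremes (`n = 1 + #\{T_perm >= T_obs\}`), so the
#' smallest reportable value is `1 / n_perm`.
#'
#' @param gene_carriers `data.frame` with `gene` and `sample_id` columns:
#'   distinct gene-level carriage pairs (see [run_wgst()] for the
#'   variant-level entry point).
#' @param samples Sample sheet; `case_ctd` vs `control` labels are shuffled.
#' @param gene_set Character vector of gene symbols; must contain at least
#'   one gene with a carrier.
#' @param weights Named non-negative weight vector (log mean expression;
#'   see [expression_weights()]). Genes without a weight get 0.
#' @param n_perm Number of permutation replicates (study default 2000).
#' @param seed Integer seed; fully determines the replicate stream.
#' @return An object of class `wgst_result`: `set_name`, `genes`, `Z`, `w`,
#'   `T_obs`, `n_extreme`, `N_perm`, `p_emp`.
#' @export
wgst_permutation_test <- function(gene_carriers, samples, gene_set, weights,
                                  n_perm = 2000, seed = NULL) {
  res <- wgst_engine(gene_carriers, samples, sets = list(set = gene_set),
                     weights = weights, n_perm = n_perm, seed = seed)$set
  if (isTRUE(res$skipped)) stop_ctd("weighted gene-set test: %s", res$reason)
  res$T_perm <- NULL
  class(res) <- "wgst_result"
  res
}

#' @export
print.wgst_result <- function(x, ...) {
  cat(sprintf("Weighted gene-set test '%s': k = %d genes, T = %.4g\n",
              x$set_name, length(x$genes), x$T_obs))
  cat(sprintf("empirical P = %.3g (%d of %d statistics >= observed, observed included)\n",
              x$p_emp, x$n_extreme, x$N_perm))
  invisible(x)
}

#' Run the weighted gene-set test over a gene-set collection
#'
#' Builds distinct gene-level carriage from the MDRV and carrier tables,
#' derives expression weights, and evaluates every gene set against one
#' shared permutation stream (the same label shuffles score all sets).
#' BH correction is applied over the non-skipped sets (the study family is
#' the 19 sets).
#'
#' @param mdrvs MDRV table (`variant_id`, `gene`).
#' @param carriers Carrier table restricted to MDRV ids.
#' @param samples Sample sheet.
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]).
#' @param expression Expression data frame, or `NULL` if `weights` given.
#' @param n_perm Permutation replicates (default 2000).
#' @param seed Integer seed for the shared shuffle stream.
#' @param weights Optional named weight vector overriding `expression`.
#' @return A `data.frame` of class `ctd_wgst`: per set `set_name`, `k`,
#'   `T_obs`, `n_extreme`, `N_perm`, `p_emp`, `q`, `skipped`, `reason`;
#'   full per-set results in `attr(, "details")`.
#' @export
run_wgst <- function(mdrvs, carriers, samples, gene_sets, expression = NULL,
                     n_perm = 2000, seed = NULL, weights = NULL) {
  if (is.null(weights)) {
    if (is.null(expression)) stop_ctd("run_wgst: need 'expression' or 'weights'")
    weights <- expression_weights(expression)
  }
  gene_carriers <- as_gene_carriers(mdrvs, carriers)
  res <- wgst_engine(gene_carriers, samples, sets = gene_sets,
                     weights = weights, n_perm = n_perm, seed = seed)
  skipped <- vapply(res, function(r) isTRUE(r$skipped), logical(1L))
  out <- data.frame(
    set_name = names(res),
    k = vapply(res, function(r) if (isTRUE(r$skipped)) NA_integer_
               else length(r$genes), integer(1L)),
    T_obs = vapply(res, function(r) r$T_obs %||% NA_real_, numeric(1L)),
    n_extreme = vapply(res, function(r) r$n_extreme %||% NA_integer_,
                       integer(1L)),
    N_perm = n_perm,
    p_emp = vapply(res, function(r) r$p_emp %||% NA_real_, numeric(1L)),
    skipped = unname(skipped),
    reason = vapply(res, function(r) r$reason %||% "", character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- NA_real_
  if (any(!skipped)) out$q[!skipped] <- bh_fdr(out$p_emp[!skipped])
  attr(out, "details") <- res
  class(out) <- c("ctd_wgst", "data.frame")
  out
}

#' @export
print.ctd_wgst <- function(x, ...) {
  cat("Weighted gene-set permutation test:", nrow(x), "set(s),",
      x$N_perm[1L], "permutations\n")
  show <- x[order(x$p_emp), c("set_name", "k", "T_obs", "p_emp", "q"),
            drop = FALSE]
  print.data.frame(utils::head(show, 10L), row.names = FALSE, digits = 4)
  if (any(x$skipped)) {
    cat("skipped:", paste(x$set_name[x$skipped], collapse = ", "), "\n")
  }
  invisible(x)
}
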