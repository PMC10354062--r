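#' Hypergeometric significance of a gene-list overlap
#'
#' Upper-tail probability of observing at least `|A intersect B|` shared
#' genes when a list of size `|A|` is drawn from the background. Equivalent
#' to [ora_pvalue()] with `N = |background|`, `M = |B|`, `n = |A|`,
#' `k = |A intersect B|`; symmetric in the two lists. The background
#' universe must be supplied explicitly — there is no defensible implicit
#' default, and the choice drives the p-value.
#'
#' @param list_a,list_b Character vectors of gene symbols, both subsets of
#'   `background` (an element outside it is an error naming the element).
#' @param background Character vector: the gene universe.
#' @return List with `list_a_size`, `list_b_size`, `background_size`,
#'   `overlap_size`, `overlap` (the shared symbols) and `p`.
#' @export
overlap_hypergeom <- function(list_a, list_b, background) {
  background <- unique(background)
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  out_a <- setdiff(list_a, background)
  if (length(out_a) > 0L) {
    stop_ctd("overlap_hypergeom: '%s' (list A) is not in the background", out_a[1L])
  }
  out_b <- setdiff(list_b, background)
  if (length(out_b) > 0L) {
    stop_ctd("overlap_hypergeom: '%s' (list B) is not in the background", out_b[1L])
  }
  ov <- intersect(list_a, list_b)
  list(list_a_size = length(list_a),
       list_b_size = length(list_b),
       background_size = length(background),
       overlap_size = length(ov),
       overlap = sort(ov),
       p = ora_pvalue(length(background), length(list_b),
                      length(list_a), length(ov)))
}

#' Two-proportions z-test
#'
#' Pooled-proportion two-sided z-test of `x1/n1` vs `x2/n2`:
#' \deqn{z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}. No continuity correction by
#' default (set `correct = TRUE` for the Yates-corrected version). Equal
#' observed proportions give z = 0, p = 1.
#'
#' @param x1,n1,x2,n2 Successes and totals for the two samples; `n1, n2 > 0`
#'   and `0 <= x <= n`.
#' @param correct Apply the continuity correction.
#' @return List with `z` and `p` (two-sided).
#' @export
#' @examples
#' two_proportion_ztest(14, 24, 3, 42)
two_proportion_ztest <- function(x1, n1, x2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop_ctd("two_proportion_ztest: zero denominator")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop_ctd("two_proportion_ztest: need 0 <= x <= n in both samples")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  diff <- p1 - p2
  if (correct) {
    cc <- min(abs(diff), 0.5 * (1 / n1 + 1 / n2))
    diff <- sign(diff) * (abs(diff) - cc)
  }
  z <- if (se == 0) 0 else diff / se
  list(z = z, p = if (z == 0) 1 else 2 * stats::pnorm(-abs(z)))
}
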