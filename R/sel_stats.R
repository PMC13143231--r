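## Post-processing statistics: branch-site LRT mixture p-values, BH FDR and
## hypergeometric enrichment with a custom background.

#' Branch-site LRT p-value under the 50:50 mixture null
#'
#' The null distribution of the statistic `x = 2 * (lnL_alt - lnL_null)` is
#' a 50:50 mixture of a chi-square with one degree of freedom and a point
#' mass at zero, so `p = 1` at `x = 0` and `p = 0.5 * Pr(chisq_1 >= x)` for
#' `x > 0`. Negative inputs (numerical noise from the external ML fits) are
#' clamped to zero with a warning.
#'
#' @param x LRT statistic(s), `2 * delta lnL`.
#' @return p-value(s) in `[0, 1]`.
#' @export
lrt_pvalue_mixture <- function(x) {
  if (any(!is.finite(x))) stop("non-finite LRT statistic")
  if (any(x < 0)) {
    warning("negative LRT statistic clamped to 0")
    x[x < 0] <- 0
  }
  ifelse(x == 0, 1, 0.5 * stats::pchisq(x, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min over j >= i of m * p_(j) / j`, returned in input order.
#' @param p p-values in `[0, 1]`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Assemble an LRT results table from external log-likelihood fits
#'
#' @param fits data frame with columns `gene`, `lnl_null`, `lnl_alt` (the
#'   branch-site null and alternative log-likelihoods from an external ML
#'   fit), or a path to such a TSV.
#' @param fdr significance cutoff on the q-value.
#' @return data frame `gene`, `two_delta_lnl`, `p`, `q`, `significant`.
#' @export
lrt_table <- function(fits, fdr = 0.05) {
  if (is.character(fits)) fits <- utils::read.delim(fits, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "lnl_null", "lnl_alt") %in% names(fits)))
  x <- 2 * (fits$lnl_alt - fits$lnl_null)
  p <- lrt_pvalue_mixture(x)
  q <- bh_fdr(p)
  data.frame(gene = fits$gene, two_delta_lnl = pmax(x, 0), p = p, q = q,
             significant = q <= fdr, stringsAsFactors = FALSE)
}

#' Hypergeometric (classical) term enrichment with a custom background
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen number of study genes annotated to the term, given the
#' term size within the background, the background size, and the study size.
#' The background should be customized to the gene universe actually tested
#' (e.g. all single-copy genes). Only the classical algorithm is provided;
#' no graph decorrelation across terms is attempted, and term-to-gene
#' propagation over an ontology graph is the caller's responsibility.
#'
#' @param study character vector of study genes (must be within `background`).
#' @param background character vector, the gene universe.
#' @param term_map named list (term -> character vector of genes) or a data
#'   frame with columns `term` and `gene`.
#' @return data frame `term`, `k` (study hits), `K` (term size in
#'   background), `expected`, `p`, `q` (BH across terms).
#' @export
enrich_hypergeom <- function(study, background, term_map) {
  study <- unique(study); background <- unique(background)
  if (length(setdiff(study, background)))
    stop("study genes not contained in background")
  if (is.data.frame(term_map)) {
    stopifnot(all(c("term", "gene") %in% names(term_map)))
    term_map <- split(term_map$gene, term_map$term)
  }
  N <- length(background)
  n <- length(study)
  res <- lapply(names(term_map), function(tm) {
    genes <- intersect(unique(term_map[[tm]]), background)
    K <- length(genes)
    k <- length(intersect(study, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, expected = n * K / N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}
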