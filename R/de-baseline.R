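#' Wilcoxon rank-sum differential expression baseline
#'
#' Per-gene two-sided Wilcoxon rank-sum (Mann-Whitney) test between the two
#' classes, with Benjamini-Hochberg adjustment across genes and a
#' pseudocount log2 fold change. The exact null distribution is used when
#' `n_case * n_control <= 400` and the gene has no cross-class ties;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used.
#'
#' @param x An [expression_set()].
#' @param pseudocount Added to both class means before the log2 ratio
#'   (default 1).
#' @return A `de_table` tibble (`gene_id`, `logfc`, `pvalue`, `padj`,
#'   `direction`), method label `"wrst"`.
#' @examples
#' sim <- simulate_expression(n_case = 10, n_control = 10,
#'                            pos_block_size = 5, neg_block_size = 5,
#'                            null_block_size = 5, seed = 1)
#' head(wrst_de(sim$expr))
#' @export
wrst_de <- function(x, pseudocount = 1) {
  ca_idx <- case_cols(x); co_idx <- control_cols(x)
  exact_ok <- length(ca_idx) * length(co_idx) <= 400
  res <- apply(x$values, 1, function(v) {
    ca <- v[ca_idx]; co <- v[co_idx]
    mc <- mean(ca); mn <- mean(co)
    if (mc + pseudocount <= 0 || mn + pseudocount <= 0) {
      abort("class mean + pseudocount <= 0; increase `pseudocount`")
    }
    if (all(ca == co[1]) && all(co == co[1])) {
      return(c(p = 1, logfc = log2((mc + pseudocount) / (mn + pseudocount))))
    }
    ties <- any(duplicated(c(ca, co)))
    p <- suppressWarnings(
      stats::wilcox.test(ca, co, alternative = "two.sided",
                         exact = exact_ok && !ties,
                         correct = TRUE)$p.value
    )
    c(p = p, logfc = log2((mc + pseudocount) / (mn + pseudocount)))
  })
  p <- pmin(unname(res["p", ]), 1)
  out <- tibble(
    gene_id = gene_ids(x),
    logfc = unname(res["logfc", ]),
    pvalue = p,
    padj = stats::p.adjust(p, method = "BH")
  )
  as_de_table(out, "wrst")
}

#' Align several DE tables on their common gene universe
#'
#' Inner-joins two or more DE tables on gene id, flags per-method
#' significance (`padj < alpha` and `|logfc| > lfc_min`), and reports the
#' per-method significant sets together with their intersection.
#'
#' @param tables List of `de_table` objects (>= 2). Unnamed entries take
#'   their `method_label` attribute as name.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param lfc_min Absolute log fold change threshold (default 1).
#' @return A list with `aligned` (tibble: `gene_id` plus
#'   `logfc_<m>`, `padj_<m>`, `sig_<m>` per method), `significant` (named
#'   list of per-method significant gene sets), `intersection` (genes
#'   significant in every method) and `params`.
#' @export
harmonize_de <- function(tables, alpha = 0.05, lfc_min = 1) {
  if (length(tables) < 2) abort("need at least two DE tables")
  nms <- names(tables) %||% rep("", length(tables))
  nms[nms == ""] <- vapply(tables[nms == ""], function(t) {
    attr(t, "method_label") %||% "unnamed"
  }, character(1))
  if (anyDuplicated(nms)) abort("duplicate method labels")
  slim <- purrr::map2(tables, nms, function(t, m) {
    tibble(gene_id = t$gene_id,
           "logfc_{m}" := t$logfc,
           "padj_{m}" := t$padj,
           "sig_{m}" := t$padj < alpha & abs(t$logfc) > lfc_min)
  })
  aligned <- purrr::reduce(slim, inner_join, by = "gene_id")
  if (!nrow(aligned)) abort("empty intersection of gene universes")
  significant <- stats::setNames(lapply(nms, function(m) {
    aligned$gene_id[aligned[[paste0("sig_", m)]]]
  }), nms)
  list(
    aligned = aligned,
    significant = significant,
    intersection = sort(purrr::reduce(significant, intersect)),
    params = list(alpha = alpha, lfc_min = lfc_min)
  )
}
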