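#' Core-enriched gene accounting for one method
#'
#' Summarizes the leading-edge ("core-enriched") genes of a set of
#' enrichment records, per direction: the deduplicated gene union, the
#' non-deduplicated multiset total (sum of leading-edge sizes over
#' pathways), and the super-core genes -- genes recurring in two or more
#' pathways of the same direction, whose recurrence inflates the
#' non-deduplicated counts relative to the deduplicated ones. Directional
#' ratios (activated / suppressed) are reported for both accountings; a
#' zero denominator yields `NaN`, never an error.
#'
#' @param records An `enrichment_record` tibble from one method, target and
#'   collection (typically the FDR-passing subset).
#' @param method Method label carried into the output.
#' @return A list of class `core_stats`: `by_direction` (tibble:
#'   `method`, `direction`, `n_dedup`, `n_nondedup`, `dedup_genes` and
#'   `super_core` list-columns -- the latter a tibble of `gene_id`,
#'   `recurrence`), `ratio_dedup`, `ratio_nondedup`.
#' @export
quantify_core <- function(records, method = "method") {
  dirs <- c("activated", "suppressed")
  per_dir <- purrr::map_dfr(dirs, function(d) {
    edges <- records$leading_edge[records$direction == d]
    genes <- unlist(edges)
    tab <- table(genes)
    super <- tibble(gene_id = names(tab)[tab >= 2],
                    recurrence = as.integer(tab[tab >= 2]))
    tibble(method = method, direction = d,
           n_pathways = length(edges),
           n_dedup = length(tab),
           n_nondedup = length(genes),
           dedup_genes = list(sort(names(tab))),
           super_core = list(super))
  })
  n_act <- per_dir$n_dedup[per_dir$direction == "activated"]
  n_sup <- per_dir$n_dedup[per_dir$direction == "suppressed"]
  nn_act <- per_dir$n_nondedup[per_dir$direction == "activated"]
  nn_sup <- per_dir$n_nondedup[per_dir$direction == "suppressed"]
  if (n_sup == 0 || nn_sup == 0) {
    inform("no suppressed core genes: directional ratios undefined (NaN)")
  }
  structure(list(
    by_direction = per_dir,
    ratio_dedup = if (n_sup > 0) n_act / n_sup else NaN,
    ratio_nondedup = if (nn_sup > 0) nn_act / nn_sup else NaN
  ), class = "core_stats")
}

#' @export
print.core_stats <- function(x, ...) {
  cat("<core_stats> method '", x$by_direction$method[1], "'\n", sep = "")
  print(x$by_direction[, c("direction", "n_pathways", "n_dedup",
                           "n_nondedup")])
  cat("ratio (act/sup): dedup ", signif(x$ratio_dedup, 4),
      ", non-dedup ", signif(x$ratio_nondedup, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy core_stats
#' @export
tidy.core_stats <- function(x, ...) {
  x$by_direction |>
    mutate(ratio_dedup = x$ratio_dedup,
           ratio_nondedup = x$ratio_nondedup)
}

#' Unique versus shared core genes across methods
#'
#' For two or more methods' core-enriched gene sets, computes the shared
#' core (intersection of all methods), each method's unique genes (present
#' in no other method) and the unique proportion per method.
#'
#' @param per_method Named list (>= 2) of character gene-id vectors.
#' @return A list: `shared` (sorted character), `per_method` tibble
#'   (`method`, `n_total`, `n_unique`, `prop_unique`, `unique_genes`
#'   list-column).
#' @export
unique_vs_shared <- function(per_method) {
  if (length(per_method) < 2) abort("need at least two methods")
  if (is.null(names(per_method)) || any(names(per_method) == "")) {
    abort("`per_method` must be a fully named list")
  }
  sets <- lapply(per_method, unique)
  shared <- sort(purrr::reduce(sets, intersect))
  tab <- purrr::imap_dfr(sets, function(g, m) {
    others <- unique(unlist(sets[setdiff(names(sets), m)]))
    uniq <- sort(setdiff(g, others))
    tibble(method = m, n_total = length(g), n_unique = length(uniq),
           prop_unique = if (length(g)) length(uniq) / length(g) else NaN,
           unique_genes = list(uniq))
  })
  list(shared = shared, per_method = tab)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (delegates to [stats::kruskal.test()]). All-identical
#' observations give H = 0, p = 1.
#'
#' @param groups List (>= 2) of numeric vectors.
#' @return Tibble: `statistic` (H), `df`, `pvalue`, `n_groups`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) abort("need at least two groups")
  if (any(lengths(groups) < 1)) abort("every group needs an observation")
  values <- unlist(groups)
  if (length(unique(values)) == 1L) {
    return(tibble(statistic = 0, df = length(groups) - 1L, pvalue = 1,
                  n_groups = length(groups)))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         pvalue = kt$p.value, n_groups = length(groups))
}

#' All-pairs Wilcoxon rank-sum comparisons
#'
#' Two-sided rank-sum tests for every pair of groups, adjusted across
#' pairs (Benjamini-Hochberg by default). Identical groups give p = 1.
#'
#' @param groups Named or unnamed list (>= 2) of numeric vectors.
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @return A symmetric matrix of adjusted p-values with unit diagonal.
#' @export
wilcoxon_pairwise <- function(groups, adjust = "BH") {
  if (length(groups) < 2) abort("need at least two groups")
  k <- length(groups)
  nms <- names(groups) %||% paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  raw <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    if (length(a) == length(b) && all(sort(a) == sort(b)) &&
        length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(a, b,
                                        alternative = "two.sided")$p.value)
  })
  adj <- stats::p.adjust(raw, method = adjust)
  m <- diag(1, k)
  dimnames(m) <- list(nms, nms)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    m[i, j] <- m[j, i] <- adj[c]
  }
  m
}

#' Composite per-dataset method score
#'
#' Aggregates gene-level and pathway-level direction balance into a single
#' score per method and gene set collection. For each target gene and
#' repeated enrichment run, the contribution is 0 when the run produced no
#' enriched pathway (failed enrichment is penalized, matching the
#' observation that methods differ most where enrichment fails outright);
#' otherwise it is `c * b`, where `c = 1 - |f_pathway - f_gene|` rewards
#' concordance between the pathway-level activated fraction and the
#' gene-level positive-correlate fraction, and `b = 1 - 2 |f_pathway -
#' 0.5|` rewards directional balance. The score is the mean contribution
#' over all targets and repeats and lies in \[0, 1\]; 1 requires perfect
#' balance and concordance with no failures. This scoring rule is this
#' package's own composite definition (version 1) and is labeled as such
#' in all outputs.
#'
#' @param per_gene Tibble with one row per (target, repeat): columns
#'   `target`, `fraction_activated` (pathway level, `NaN` for a failed
#'   run) and `pos_fraction` (gene level, recycled within target).
#' @param collection Label for the collection being scored.
#' @return One-row tibble: `collection`, `score`, `n_contributions`,
#'   `n_failed`, `score_version`.
#' @export
composite_score <- function(per_gene, collection = "custom") {
  req <- c("target", "fraction_activated", "pos_fraction")
  missing_cols <- setdiff(req, names(per_gene))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(per_gene)) abort("no targets to score")
  contrib <- purrr::pmap_dbl(
    per_gene[, c("fraction_activated", "pos_fraction")],
    function(fraction_activated, pos_fraction) {
      if (is.nan(fraction_activated) || is.nan(pos_fraction)) return(0)
      conc <- 1 - abs(fraction_activated - pos_fraction)
      bal <- 1 - 2 * abs(fraction_activated - 0.5)
      conc * bal
    }
  )
  tibble(collection = collection,
         score = mean(contrib),
         n_contributions = length(contrib),
         n_failed = sum(is.nan(per_gene$fraction_activated)),
         score_version = "coexbalance-composite-v1")
}
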