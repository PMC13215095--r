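#' Oriented single-feature AUC
#'
#' Computes the two-class rank-sum AUC of one gene and orients it: the raw
#' AUC is the fraction of (case, control) sample pairs in which the case
#' value exceeds the control value, counting ties as one half; the oriented
#' AUC is `max(raw, 1 - raw)` together with the direction that achieved it.
#' A constant gene has AUC 0.5 and is reported `up-in-case` by convention.
#'
#' @param x An [expression_set()].
#' @param gene Gene identifier.
#' @return One-row tibble: `gene_id`, `auc` (in \[0.5, 1\]), `orientation`
#'   (`"up-in-case"` or `"down-in-case"`), `raw_auc`.
#' @examples
#' sim <- simulate_expression(seed = 1)
#' feature_auc(sim$expr, "ANCHOR001")
#' @export
feature_auc <- function(x, gene) {
  if (!gene %in% gene_ids(x)) abort(paste0("gene not in matrix: ", gene))
  v <- x$values[gene, ]
  ca <- v[case_cols(x)]
  co <- v[control_cols(x)]
  raw <- raw_auc(ca, co)
  orientation <- if (raw >= 0.5) "up-in-case" else "down-in-case"
  tibble(gene_id = gene, auc = max(raw, 1 - raw),
         orientation = orientation, raw_auc = raw)
}

# Raw AUC by pair counting (ties get half credit); O(n log n) via ranks.
raw_auc <- function(ca, co) {
  r <- rank(c(ca, co))
  n1 <- length(ca); n2 <- length(co)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Per-pair credit vector of one oriented feature over all case x control
# pairs (pair order: control index fastest). Credit 1 = pair strictly
# correctly ordered under the feature's orientation, 0.5 = tied, 0 = wrong.
pair_credit <- function(ca, co) {
  d <- rep(ca, each = length(co)) - rep.int(co, length(ca))
  raw <- (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
  credit <- ifelse(d > 0, 1, ifelse(d == 0, 0.5, 0))
  if (raw < 0.5) credit <- 1 - credit
  credit
}

# Credit matrix for a vector of genes: genes x pairs.
credit_matrix <- function(x, genes) {
  ca_idx <- case_cols(x); co_idx <- control_cols(x)
  t(vapply(genes, function(g) {
    pair_credit(x$values[g, ca_idx], x$values[g, co_idx])
  }, numeric(length(ca_idx) * length(co_idx))))
}

#' Multivariate AUC of a feature set
#'
#' The mvAUC of a gene set is the mean, over all case x control sample
#' pairs, of the best credit any oriented member feature earns on that pair
#' (1 if some member strictly orders it correctly, 0.5 if the best member
#' ties, 0 otherwise). It reduces exactly to the oriented AUC for a
#' singleton and is monotone under feature addition, which makes
#' complementarity literal: a gene's marginal mvAUC gain is the mass of
#' pairs it orders that the current set misses.
#'
#' @param x An [expression_set()].
#' @param genes Character vector of member gene ids (duplicates ignored).
#' @return A single number in \[0.5, 1\] for non-empty sets of genes with
#'   oriented AUC >= 0.5 (always the case); errors on an empty set.
#' @examples
#' sim <- simulate_expression(seed = 1)
#' mvauc(sim$expr, c("ANCHOR001", "POS001"))
#' @export
mvauc <- function(x, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) abort("empty gene set")
  cm <- credit_matrix(x, genes)
  mean(apply(cm, 2, max))
}

finish_trace <- function(selected, weights, cumulative, seed_set) {
  out <- tibble(
    rank = seq_along(selected),
    gene_id = selected,
    weight = weights,
    cumulative_mvauc = cumulative,
    seeded = selected %in% seed_set
  )
  attr(out, "seed_set") <- seed_set
  class(out) <- c("macfc_trace", class(out))
  out
}

# Shared greedy engine. `cover` is the running best-credit-per-pair vector
# (NULL means nothing covered yet and the first pick is by oriented AUC).
greedy_complement <- function(x, candidates, cover, max_features, min_gain,
                              auc_tab) {
  selected <- character()
  weights <- numeric()
  cumulative <- numeric()
  cm <- credit_matrix(x, candidates)
  current <- if (is.null(cover)) rep(0, ncol(cm)) else cover
  base <- mean(current)
  remaining <- candidates
  while (length(selected) < max_features && length(remaining)) {
    rows <- cm[remaining, , drop = FALSE]
    scores <- rowMeans(pmax(rows, rep(current, each = nrow(rows))))
    best <- max(scores)
    gain <- best - base
    # First unseeded pick follows the oriented-AUC ranking; thereafter the
    # pick maximizes the mvAUC of the augmented set. Ties break to the
    # lexicographically smallest gene id for cross-platform determinism.
    if (is.null(cover) && !length(selected)) {
      aucs <- auc_tab$auc[match(remaining, auc_tab$gene_id)]
      top <- remaining[aucs == max(aucs)]
      pick <- top[lex_order(top)[1]]
      gain <- auc_tab$auc[auc_tab$gene_id == pick] - 0.5
    } else {
      if (gain <= min_gain) break
      top <- remaining[scores >= best - 1e-12]
      pick <- top[lex_order(top)[1]]
      gain <- scores[match(pick, remaining)] - base
    }
    current <- pmax(current, cm[pick, ])
    base <- mean(current)
    selected <- c(selected, pick)
    weights <- c(weights, gain)
    cumulative <- c(cumulative, base)
    remaining <- setdiff(remaining, pick)
    if (base >= 1 - 1e-12) break
    if (length(selected) > 1 && weights[length(weights)] <= min_gain) break
  }
  list(selected = selected, weights = weights, cumulative = cumulative,
       cover = current)
}

#' Greedy complementary selection by marginal mvAUC gain
#'
#' Forward selection for weakly associated data: the first pick is the gene
#' with the highest oriented AUC; each subsequent pick maximizes the mvAUC
#' of the augmented set. Selection stops when the marginal gain drops to
#' `min_gain` or below, when mvAUC reaches 1, or at `max_features`.
#' Weights are the marginal mvAUC gains (the first weight is the top
#' oriented AUC minus 0.5, the gain over an uninformative baseline).
#'
#' @param x An [expression_set()].
#' @param max_features Maximum number of genes to select (default 50).
#' @param min_gain Stop when the marginal mvAUC gain is <= this (default
#'   1e-6).
#' @return A `macfc_trace` tibble: `rank`, `gene_id`, `weight`,
#'   `cumulative_mvauc` (nondecreasing), `seeded` (all `FALSE` here).
#' @examples
#' sim <- simulate_expression(n_case = 10, n_control = 10,
#'                            pos_block_size = 5, neg_block_size = 5,
#'                            null_block_size = 10, seed = 1)
#' macfc_main(sim$expr, max_features = 5)
#' @export
macfc_main <- function(x, max_features = 50, min_gain = 1e-6) {
  stopifnot(max_features >= 1, min_gain >= 0)
  genes <- gene_ids(x)
  if (!length(genes)) abort("empty expression matrix")
  auc_tab <- feature_auc_all(x)
  res <- greedy_complement(x, genes, cover = NULL, max_features, min_gain,
                           auc_tab)
  finish_trace(res$selected, res$weights, res$cumulative,
               seed_set = character())
}

# Oriented AUC for every gene at once.
feature_auc_all <- function(x) {
  ca_idx <- case_cols(x); co_idx <- control_cols(x)
  raw <- apply(x$values, 1, function(v) raw_auc(v[ca_idx], v[co_idx]))
  tibble(gene_id = gene_ids(x), raw_auc = raw,
         auc = pmax(raw, 1 - raw),
         orientation = ifelse(raw >= 0.5, "up-in-case", "down-in-case"))
}

#' High-AUC-seeded complementary selection
#'
#' Variant for strongly associated data: all genes whose oriented AUC
#' strictly exceeds `auc_threshold` are retained up front as
#' high-confidence discriminatory features (ordered by decreasing AUC, ties
#' lexicographic); the remaining genes are then added greedily by marginal
#' mvAUC gain over the coverage already achieved by the seeds. The final
#' selection is the seeds followed by the complementary picks. When no
#' gene clears the threshold this reduces exactly to [macfc_main()].
#'
#' @inheritParams macfc_main
#' @param auc_threshold Oriented-AUC seed threshold in (0.5, 1\] (default
#'   0.95).
#' @return A `macfc_trace` tibble; `seeded` marks the threshold-passing
#'   genes and `attr(, "seed_set")` lists them.
#' @export
macfc_v2 <- function(x, auc_threshold = 0.95, max_features = 50,
                     min_gain = 1e-6) {
  stopifnot(auc_threshold > 0.5, auc_threshold <= 1,
            max_features >= 1, min_gain >= 0)
  genes <- gene_ids(x)
  if (!length(genes)) abort("empty expression matrix")
  auc_tab <- feature_auc_all(x)
  seeds <- auc_tab |>
    filter(.data$auc > auc_threshold) |>
    arrange(desc(.data$auc), .data$gene_id) |>
    pull("gene_id") |>
    utils::head(max_features)
  if (!length(seeds)) {
    out <- macfc_main(x, max_features, min_gain)
    return(out)
  }
  # Add seeds in AUC order, recording their marginal gains so the trace
  # invariants (nondecreasing cumulative mvAUC, aligned weights) hold.
  cm <- credit_matrix(x, seeds)
  current <- rep(0, ncol(cm))
  sel <- character(); w <- numeric(); cum <- numeric()
  base <- 0.5  # uninformative baseline for the first weight
  for (i in seq_along(seeds)) {
    newcov <- pmax(current, cm[i, ])
    m <- mean(newcov)
    w <- c(w, m - if (i == 1) 0.5 else mean(current))
    current <- newcov
    cum <- c(cum, m)
    sel <- c(sel, seeds[i])
  }
  remaining <- setdiff(genes, seeds)
  if (mean(current) < 1 - 1e-12 && length(remaining) &&
      length(sel) < max_features) {
    res <- greedy_complement(x, remaining, cover = current,
                             max_features - length(sel), min_gain, auc_tab)
    sel <- c(sel, res$selected)
    w <- c(w, res$weights)
    cum <- c(cum, res$cumulative)
  }
  finish_trace(sel, w, cum, seed_set = seeds)
}

#' @method tidy macfc_trace
#' @export
tidy.macfc_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "gene_id", "weight",
                                 "cumulative_mvauc", "seeded")])
}

#' @method glance macfc_trace
#' @export
glance.macfc_trace <- function(x, ...) {
  tibble(n_selected = nrow(x),
         n_seed = length(attr(x, "seed_set")),
         final_mvauc = if (nrow(x)) x$cumulative_mvauc[nrow(x)] else NA_real_)
}

#' Plot the cumulative mvAUC of a selection trace
#'
#' @param object A `macfc_trace`.
#' @param ... Unused.
#' @return A ggplot: selection step versus cumulative mvAUC, seeded picks
#'   marked.
#' @method autoplot macfc_trace
#' @export
autoplot.macfc_trace <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rank, y = .data$cumulative_mvauc)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$seeded)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "selection step", y = "cumulative mvAUC",
                  shape = "seeded") +
    ggplot2::ylim(0.5, 1)
}
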