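#' GSEA configuration
#'
#' Collects the tunables of the preranked enrichment engine. Defaults
#' follow common GSEA practice: weight exponent 1, 1000 gene permutations,
#' set-size window \[5, 500\], 20 repeated runs, and an FDR gate of
#' q < 0.25 for calling a pathway enriched when counting directions.
#'
#' @param weight_exponent Hit-weight exponent `p` (>= 0; 0 gives the
#'   classical unweighted Kolmogorov-Smirnov statistic).
#' @param n_permutations Random member sets per observed set.
#' @param min_set_size,max_set_size Overlap-size window for analysed sets.
#' @param n_repeats Number of reseeded repeat runs in [repeat_fraction()].
#' @param alpha_q FDR threshold used when classifying records as enriched.
#' @param seed Integer seed; every permutation draw derives from it.
#' @return A list of class `gsea_config`.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 1000,
                        min_set_size = 5, max_set_size = 500,
                        n_repeats = 20, alpha_q = 0.25, seed = 1) {
  stopifnot(weight_exponent >= 0, n_permutations >= 1,
            min_set_size >= 1, max_set_size > min_set_size,
            n_repeats >= 1, alpha_q > 0, alpha_q <= 1)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 n_repeats = as.integer(n_repeats),
                 alpha_q = alpha_q, seed = as.integer(seed)),
            class = "gsea_config")
}

#' Rank the gene universe by Spearman correlation with a target gene
#'
#' Every other gene is scored by its Spearman correlation with the target
#' and sorted in descending score order; ties break lexicographically by
#' gene id and the target is excluded from its own list. Genes with
#' undefined correlation (constant vectors) are dropped.
#'
#' @param x An [expression_set()].
#' @param target Target gene id.
#' @param universe Optional restriction of the ranked universe.
#' @return A `ranked_list` tibble: `gene_id`, `score` (nonincreasing).
#' @export
rank_by_target <- function(x, target, universe = NULL) {
  prof <- profile_target(x, target, universe = universe)
  if (prof$degenerate) abort(paste0("constant target gene: ", target))
  out <- prof$rho |>
    filter(!is.nan(.data$rho)) |>
    rename(score = "rho") |>
    arrange(desc(.data$score), .data$gene_id)
  class(out) <- c("ranked_list", class(out))
  out
}

# Enrichment score from sorted hit positions. `sp` = |score|^p over the
# whole ranked universe. Running sum rises by normalized hit weight at each
# hit and falls by 1/(N - k) per miss; the ES is the extremum. Local maxima
# occur exactly at hit positions and local minima just before hits, so an
# O(k) sweep suffices.
es_from_positions <- function(pos, sp, N) {
  k <- length(pos)
  s <- sp[pos]
  tot <- sum(s)
  W <- if (tot == 0) seq_len(k) / k else cumsum(s) / tot
  miss <- 1 / (N - k)
  drop <- (pos - seq_len(k)) * miss
  top <- W - drop
  bot <- c(0, W[-k]) - drop
  mx <- max(top)
  mn <- min(bot)
  if (mx >= -mn) {
    list(es = mx, idx = which.max(top), positive = TRUE)
  } else {
    list(es = mn, idx = which.min(bot), positive = FALSE)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score with leading edge
#'
#' Walks the ranked list: at each member ("hit") the running statistic
#' rises by that gene's weight `|score|^p` (normalized over all hits), at
#' each non-member it falls by `1/(N - n_hits)`. The enrichment score is
#' the signed maximum deviation from zero; the leading edge is the member
#' genes at or before the extremum (at or after it, for a negative ES).
#'
#' @param ranked A [rank_by_target()] result (or any tibble with
#'   `gene_id`, `score` sorted by nonincreasing score).
#' @param members Character vector of set members.
#' @param p Weight exponent (default 1; 0 recovers the classical KS
#'   statistic).
#' @return List: `es` in \[-1, 1\], `leading_edge` (character vector, empty
#'   only when `es == 0`), `n_hits`.
#' @export
enrichment_score <- function(ranked, members, p = 1) {
  universe <- ranked$gene_id
  N <- length(universe)
  pos <- which(universe %in% members)
  k <- length(pos)
  if (!k) abort("no overlap between set and ranked universe")
  if (k == N) abort("set covers the entire ranked universe")
  sp <- abs(ranked$score)^p
  r <- es_from_positions(pos, sp, N)
  leading <- if (r$es == 0) {
    character()
  } else if (r$positive) {
    universe[pos[seq_len(r$idx)]]
  } else {
    universe[pos[seq(r$idx, k)]]
  }
  list(es = r$es, leading_edge = leading, n_hits = k)
}

# Null ES values for a set of size k under gene permutation.
null_es <- function(sp, N, k, B) {
  vapply(seq_len(B), function(b) {
    pos <- sort.int(sample.int(N, k))
    es_from_positions(pos, sp, N)$es
  }, numeric(1))
}

# Normalize an observed ES against a null sample: divide by the mean |ES|
# of the same-sign null values. NA when no same-sign null exists.
normalize_es <- function(es, nulls) {
  same <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
  if (!length(same) || mean(abs(same)) == 0) return(NA_real_)
  es / mean(abs(same))
}

#' Permutation significance of one gene set
#'
#' Draws `n_permutations` random member sets of the same overlap size from
#' the ranked universe (gene permutation, the appropriate scheme for a
#' preranked list), normalizes the observed ES by the mean |ES| of
#' same-sign null values (NES), and reports the same-sign permutation
#' p-value. For a single set the FDR q equals the p-value; use
#' [gsea_collection()] for a collection-wide, sign-stratified FDR.
#'
#' @inheritParams enrichment_score
#' @param config A [gsea_config()].
#' @param set_name,collection_label Labels carried into the record.
#' @return One-row `enrichment_record` tibble: `set_name`, `es`, `nes`,
#'   `pvalue`, `fdr_q`, `direction` (`activated` / `suppressed` / `none`),
#'   `leading_edge` (list-column), `n_hits`, `collection_label`. `NULL`
#'   (with a warning) when the NES is undefined because no same-sign null
#'   ES exists.
#' @export
gsea_significance <- function(ranked, members, config = gsea_config(),
                              set_name = "set", collection_label = "custom") {
  set.seed(config$seed)
  rec <- significance_impl(ranked, members, config, set_name,
                           collection_label)
  if (is.null(rec$record)) {
    warn(paste0("undefined NES for set '", set_name, "' (no same-sign null)"))
    return(NULL)
  }
  rec$record
}

significance_impl <- function(ranked, members, config, set_name,
                              collection_label) {
  obs <- enrichment_score(ranked, members, p = config$weight_exponent)
  sp <- abs(ranked$score)^config$weight_exponent
  N <- length(ranked$gene_id)
  nulls <- null_es(sp, N, obs$n_hits, config$n_permutations)
  nes <- normalize_es(obs$es, nulls)
  if (is.na(nes)) return(list(record = NULL, null_nes = numeric()))
  same <- if (obs$es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
  pval <- mean(abs(same) >= abs(obs$es))
  null_nes <- vapply_dbl(nulls, normalize_es, nulls = nulls)
  record <- tibble(
    set_name = set_name,
    es = obs$es,
    nes = nes,
    pvalue = pval,
    fdr_q = pval,
    direction = if (obs$es > 0) "activated"
                else if (obs$es < 0) "suppressed" else "none",
    leading_edge = list(obs$leading_edge),
    n_hits = obs$n_hits,
    collection_label = collection_label
  )
  class(record) <- c("enrichment_record", class(record))
  list(record = record, null_nes = null_nes[!is.na(null_nes)])
}

#' Run preranked GSEA over a whole collection
#'
#' Applies [gsea_significance()] to every set whose overlap with the
#' ranked universe falls inside the configured size window, then computes
#' a sign-stratified FDR q: for a record with NES* > 0, q is the fraction
#' of pooled positive null NES values >= NES* divided by the fraction of
#' observed positive NES values >= NES* (symmetrically for negative),
#' clipped to \[0, 1\]. Seed-deterministic: sets are processed in
#' collection order under a single seed from `config`.
#'
#' @param ranked A [rank_by_target()] result.
#' @param collection A `gene_sets` collection.
#' @param config A [gsea_config()].
#' @return An `enrichment_record` tibble, one row per analysed set (sets
#'   with undefined NES are dropped with a warning).
#' @export
gsea_collection <- function(ranked, collection, config = gsea_config()) {
  label <- attr(collection, "collection_label") %||% "custom"
  universe <- ranked$gene_id
  overlap <- vapply(collection$members, function(m) {
    sum(m %in% universe)
  }, integer(1))
  keep <- overlap >= config$min_set_size & overlap <= config$max_set_size &
    overlap < length(universe)
  sets <- collection[keep, ]
  if (!nrow(sets)) {
    out <- empty_records(label)
    return(out)
  }
  set.seed(config$seed)
  runs <- purrr::map2(sets$set_name, sets$members, function(nm, m) {
    significance_impl(ranked, m, config, nm, label)
  })
  records <- purrr::map_dfr(runs, "record")
  dropped <- vapply(runs, function(r) is.null(r$record), logical(1))
  if (any(dropped)) {
    warn(paste0(sum(dropped), " set(s) dropped: undefined NES"))
  }
  if (!nrow(records)) return(empty_records(label))
  pooled <- unlist(purrr::map(runs, "null_nes"))
  records$fdr_q <- fdr_from_null(records$nes, pooled)
  class(records) <- c("enrichment_record", class(records))
  records
}

empty_records <- function(label) {
  out <- tibble(set_name = character(), es = numeric(), nes = numeric(),
                pvalue = numeric(), fdr_q = numeric(),
                direction = character(), leading_edge = list(),
                n_hits = integer(), collection_label = character())
  class(out) <- c("enrichment_record", class(out))
  out
}

# Sign-stratified GSEA-style FDR from a pooled null NES sample.
fdr_from_null <- function(nes, pooled) {
  vapply_dbl(seq_along(nes), function(i) {
    v <- nes[i]
    if (v >= 0) {
      null_pos <- pooled[pooled >= 0]
      obs_pos <- nes[nes >= 0]
      num <- if (length(null_pos)) mean(null_pos >= v) else 0
      den <- mean(obs_pos >= v)
    } else {
      null_neg <- pooled[pooled < 0]
      obs_neg <- nes[nes < 0]
      num <- if (length(null_neg)) mean(null_neg <= v) else 0
      den <- mean(obs_neg <= v)
    }
    min(1, num / max(den, .Machine$double.eps))
  })
}

#' Activated-pathway fraction over repeated GSEA runs
#'
#' Repeats the full collection analysis `n_repeats` times with derived
#' seeds (to average out permutation stochasticity) and reports, per
#' repeat, the fraction of activated pathways among all pathways passing
#' the FDR gate. A repeat with no passing record yields `NaN`, never 0:
#' failed enrichment is missing, not evidence of suppression.
#'
#' @param x An [expression_set()].
#' @param target Target gene id (the ranking metric is Spearman
#'   correlation with this gene).
#' @param collection A `gene_sets` collection.
#' @param config A [gsea_config()]; `n_repeats` and `alpha_q` control the
#'   protocol.
#' @param universe Optional ranked-universe restriction.
#' @return Tibble: `repeat_id`, `n_significant`, `n_activated`,
#'   `n_suppressed`, `fraction_activated` (`NaN` allowed).
#' @export
repeat_fraction <- function(x, target, collection, config = gsea_config(),
                            universe = NULL) {
  ranked <- rank_by_target(x, target, universe = universe)
  purrr::map_dfr(seq_len(config$n_repeats), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "repeat_run", r)
    recs <- gsea_collection(ranked, collection, cfg)
    sig <- recs[recs$fdr_q < config$alpha_q & recs$direction != "none", ]
    n_act <- sum(sig$direction == "activated")
    n_sup <- sum(sig$direction == "suppressed")
    tibble(repeat_id = r, n_significant = nrow(sig),
           n_activated = n_act, n_suppressed = n_sup,
           fraction_activated = if (n_act + n_sup) n_act / (n_act + n_sup)
                                else NaN)
  })
}

#' Flag redundant enrichment records by leading-edge overlap
#'
#' Single-linkage clusters of same-direction records whose leading-edge
#' Jaccard similarity reaches the threshold. Heavily overlapping records
#' usually reflect synonymous or nested (sub-)pathways detected repeatedly
#' rather than independent signals.
#'
#' @param records An `enrichment_record` tibble.
#' @param jaccard_threshold Minimum leading-edge Jaccard (default 0.8).
#' @return `records` with a `cluster` column added, plus attribute
#'   `clusters`: a tibble with one row per cluster (`cluster`,
#'   `representative` = member with largest |NES|, `n_members`,
#'   `direction`).
#' @export
redundancy_flag <- function(records, jaccard_threshold = 0.8) {
  if (!nrow(records)) abort("no records")
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (records$direction[i] != records$direction[j]) next
      a <- records$leading_edge[[i]]; b <- records$leading_edge[[j]]
      u <- length(union(a, b))
      if (u > 0 && length(intersect(a, b)) / u >= jaccard_threshold) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  records$cluster <- as.integer(comp)
  clusters <- records |>
    group_by(.data$cluster) |>
    summarise(representative = .data$set_name[which.max(abs(.data$nes))],
              n_members = dplyr::n(),
              direction = .data$direction[1], .groups = "drop")
  attr(records, "clusters") <- clusters
  records
}

#' Plot enrichment records as a signed NES bar chart
#'
#' @param object An `enrichment_record` tibble.
#' @param ... Unused.
#' @return A ggplot of NES per set, colored by direction.
#' @method autoplot enrichment_record
#' @export
autoplot.enrichment_record <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$set_name, .data$nes),
                               y = .data$nes, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized enrichment score",
                  fill = NULL)
}
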