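#' Intersection target gene set across selection methods
#'
#' The common benchmark universe: genes selected by every method, sorted
#' lexicographically. Running all downstream stages on this shared set is
#' what makes cross-method bias comparisons fair.
#'
#' @param per_method Named list (>= 2) of character gene-id vectors, one
#'   per method.
#' @return Sorted character vector of commonly selected genes.
#' @export
target_gene_set <- function(per_method) {
  if (length(per_method) < 2) abort("need at least two methods")
  out <- sort(purrr::reduce(lapply(per_method, unique), intersect))
  if (!length(out)) {
    abort(paste0("empty intersection of selected genes; relax the ",
                 "per-method selection thresholds"))
  }
  out
}

#' Benchmark configuration
#'
#' One config drives the whole chain: simulate (or load) a two-class
#' matrix, run the selection methods, intersect their gene lists into the
#' target set, audit coexpression balance, run repeated preranked GSEA per
#' target, account core-enriched genes and compute composite scores.
#'
#' @param sim Named list of arguments for [simulate_expression()] (or
#'   `NULL` when `expr` is supplied to [run_benchmark()] directly).
#' @param gene_sets_args Named list of arguments for
#'   [simulate_gene_sets()] (ignored when a collection is supplied).
#' @param methods Character subset of `c("macfc_v2", "macfc_main",
#'   "autofs", "wrst")`.
#' @param cor_threshold Strong-correlation threshold (default 0.5).
#' @param gsea A [gsea_config()]. Desk-scale defaults here use 200
#'   permutations and 5 repeats; see the methods vignette.
#' @param de_alpha,de_lfc_min Significance gates for the rank-sum method's
#'   selected set. The benchmark default gates on adjusted significance
#'   only (`de_lfc_min = 0`): the simulated continuous scale makes fold
#'   changes shift-dependent, so a count-style |logFC| cut is not
#'   meaningful there.
#' @param max_features mvAUC selection cap.
#' @param autofs An [autofs_config()] (its seed is overridden by the
#'   benchmark seed).
#' @param gsea_max_targets Cap on targets taken into the GSEA stage (the
#'   first `n` of the sorted target set), keeping repeated enrichment
#'   tractable.
#' @param seed Root seed; every stochastic stage derives from it.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(sim = list(), gene_sets_args = list(),
                             methods = c("macfc_v2", "wrst"),
                             cor_threshold = 0.5,
                             gsea = gsea_config(n_permutations = 200,
                                                n_repeats = 5),
                             de_alpha = 0.05, de_lfc_min = 0,
                             max_features = 50,
                             autofs = autofs_config(cv_folds = 3,
                                                    n_search_iterations = 5,
                                                    rfe_max_genes = 25),
                             gsea_max_targets = 10, seed = 1) {
  known <- c("macfc_v2", "macfc_main", "autofs", "wrst")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  }
  if (length(methods) < 2) abort("need at least two methods to intersect")
  structure(list(sim = sim, gene_sets_args = gene_sets_args,
                 methods = methods, cor_threshold = cor_threshold,
                 gsea = gsea, de_alpha = de_alpha, de_lfc_min = de_lfc_min,
                 max_features = max_features, autofs = autofs,
                 gsea_max_targets = as.integer(gsea_max_targets),
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

run_method <- function(method, expr, config) {
  switch(method,
    macfc_v2 = macfc_v2(expr, max_features = config$max_features)$gene_id,
    macfc_main = macfc_main(expr, max_features = config$max_features)$gene_id,
    autofs = {
      cfg <- config$autofs
      cfg$seed <- derive_seed(config$seed, "autofs")
      autofs(expr, cfg)$selected$gene_id
    },
    wrst = {
      de <- wrst_de(expr)
      de$gene_id[de$padj < config$de_alpha & abs(de$logfc) > config$de_lfc_min]
    }
  )
}

#' Run the full selection-to-score benchmark
#'
#' Executes the whole chain from one config, reproducibly: simulate (or
#' accept) a two-class matrix and gene sets, run each selection method,
#' intersect into the target gene set, profile coexpression balance of
#' every target, run repeated preranked GSEA for the leading targets,
#' account core-enriched genes per direction, and score gene-pathway
#' direction concordance. Reruns with the same config are identical; the
#' manifest records the seed and every tunable in effect.
#'
#' @param config A [benchmark_config()].
#' @param expr Optional [expression_set()] overriding the simulation.
#' @param collection Optional `gene_sets` collection overriding the
#'   simulated one (a simulated collection needs the simulated truth).
#' @param out_dir Optional directory; when given, per-stage TSVs, the
#'   composite-score JSON and the manifest JSON are written there.
#' @return A `benchmark_result` list: `expr`, `truth` (NULL for external
#'   data), `collection`, `selected` (named list), `targets`, `balance`
#'   (a [balance_report()]), `gsea_records` (tibble over targets),
#'   `fractions` (per target x repeat), `core` (per-direction accounting),
#'   `scores` (composite), `manifest`.
#' @export
run_benchmark <- function(config, expr = NULL, collection = NULL,
                          out_dir = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  truth <- NULL
  if (is.null(expr)) {
    sim_args <- utils::modifyList(
      list(baseline = 15, seed = derive_seed(config$seed, "simulate")),
      config$sim)
    sim <- do.call(simulate_expression, sim_args)
    expr <- sim$expr
    truth <- sim$truth
  }
  if (is.null(collection)) {
    if (is.null(truth)) {
      abort("a gene set collection is required with external expression data")
    }
    gs_args <- utils::modifyList(
      list(truth = truth, seed = derive_seed(config$seed, "gene_sets")),
      config$gene_sets_args)
    collection <- do.call(simulate_gene_sets, gs_args)
  }

  selected <- stats::setNames(
    lapply(config$methods, run_method, expr = expr, config = config),
    config$methods)
  targets <- target_gene_set(selected)

  balance <- balance_report(expr, targets, threshold = config$cor_threshold)

  gsea_targets <- utils::head(targets, config$gsea_max_targets)
  gsea_cfg <- config$gsea
  fractions <- purrr::map_dfr(gsea_targets, function(t) {
    cfg <- gsea_cfg
    cfg$seed <- derive_seed(config$seed, "gsea",
                            match(t, gsea_targets))
    repeat_fraction(expr, t, collection, cfg) |>
      mutate(target = t, .before = 1)
  })

  gsea_records <- purrr::map_dfr(gsea_targets, function(t) {
    cfg <- gsea_cfg
    cfg$seed <- derive_seed(config$seed, "permutation",
                            match(t, gsea_targets))
    ranked <- rank_by_target(expr, t)
    gsea_collection(ranked, collection, cfg) |>
      mutate(target = t, .before = 1)
  })

  sig_records <- gsea_records[gsea_records$fdr_q < gsea_cfg$alpha_q &
                                gsea_records$direction != "none", ]
  core <- quantify_core(sig_records, method = "benchmark")

  per_gene <- fractions |>
    left_join(balance$summary |>
                select("target", "pos_fraction"), by = "target")
  scores <- composite_score(per_gene,
                            attr(collection, "collection_label") %||%
                              "custom")

  manifest <- list(
    package = "coexbalance",
    version = as.character(utils::packageVersion("coexbalance")),
    seed = config$seed,
    methods = config$methods,
    cor_threshold = config$cor_threshold,
    de_alpha = config$de_alpha, de_lfc_min = config$de_lfc_min,
    max_features = config$max_features,
    gsea = unclass(config$gsea),
    autofs = list(cv_folds = config$autofs$cv_folds,
                  n_search_iterations = config$autofs$n_search_iterations,
                  rfe_max_genes = config$autofs$rfe_max_genes),
    gsea_max_targets = config$gsea_max_targets,
    sim = config$sim, gene_sets_args = config$gene_sets_args,
    n_targets = length(targets)
  )

  result <- structure(list(
    expr = expr, truth = truth, collection = collection,
    selected = selected, targets = targets, balance = balance,
    gsea_records = gsea_records, fractions = fractions,
    core = core, scores = scores, manifest = manifest
  ), class = "benchmark_result")

  if (!is.null(out_dir)) write_benchmark(result, out_dir)
  result
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  cat("  methods: ", paste(names(x$selected), collapse = ", "), "\n", sep = "")
  cat("  targets (intersection): ", length(x$targets), "\n", sep = "")
  cat("  balance index: ", signif(as.numeric(x$balance$balance_index), 4),
      "\n", sep = "")
  cat("  composite score: ", signif(x$scores$score, 4), "\n", sep = "")
  invisible(x)
}

# Serialize every tabular stage as TSV plus JSON for scores and manifest.
write_benchmark <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tab, name) {
    readr::write_tsv(tab, file.path(out_dir, name), progress = FALSE)
  }
  w(purrr::imap_dfr(result$selected, function(g, m) {
    tibble(method = m, gene_id = g)
  }), "selected_genes.tsv")
  w(tibble(target = result$targets), "target_gene_set.tsv")
  w(result$balance$summary, "balance_summary.tsv")
  w(result$gsea_records |>
      mutate(leading_edge = vapply(.data$leading_edge, paste,
                                   character(1), collapse = ",")),
    "gsea_records.tsv")
  w(result$fractions, "repeat_fractions.tsv")
  w(tidy(result$core) |>
      select(-"dedup_genes", -"super_core"), "core_stats.tsv")
  jsonlite::write_json(result$scores, file.path(out_dir, "scores.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
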