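#' Spearman rank correlation of two sample vectors
#'
#' Pearson correlation of average-ranked values. Returns `NaN` (with no
#' error) when either vector is constant, so degenerate genes propagate as
#' missing rather than spurious values.
#'
#' @param x,y Equal-length (>= 3) finite numeric vectors.
#' @return Correlation in \[-1, 1\], or `NaN`.
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("length mismatch")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
  stats::cor(rank(x), rank(y))
}

#' Coexpression direction profile of one target gene
#'
#' Computes the Spearman correlation of a target gene against every other
#' gene in the supplied universe, classifies strong correlates at
#' `rho > threshold` (positively correlated genes, PCG) and
#' `rho < -threshold` (negatively correlated genes, NCG) -- strict
#' inequalities, genes exactly at the threshold are excluded -- and
#' summarizes directional balance.
#'
#' @param x An [expression_set()].
#' @param target Target gene id (excluded from its own profile).
#' @param threshold Strong-correlation threshold (default 0.5).
#' @param universe Optional character vector restricting the correlation
#'   universe (e.g. a selected-gene subset); default: all other genes.
#' @return A list of class `cor_profile`: `target`, `rho` (tibble
#'   `gene_id`, `rho`), `pcg`, `ncg` (gene id vectors), `pos_fraction`
#'   (`|pcg| / (|pcg| + |ncg|)`, `NaN` when both empty), `median_abs_pos`,
#'   `median_abs_neg`, `median_ratio` (`NaN` when undefined), `threshold`,
#'   `degenerate` (TRUE for a constant target, with all-NaN correlations).
#' @export
profile_target <- function(x, target, threshold = 0.5, universe = NULL) {
  if (!target %in% gene_ids(x)) abort(paste0("target not in matrix: ", target))
  universe <- universe %||% gene_ids(x)
  universe <- setdiff(unique(universe), target)
  tv <- x$values[target, ]
  degenerate <- stats::sd(tv) == 0
  if (degenerate) {
    warn(paste0("constant target gene '", target, "': all-NaN profile"))
    rho <- rep(NaN, length(universe))
  } else {
    tr <- rank(tv)
    others <- x$values[universe, , drop = FALSE]
    rho <- apply(others, 1, function(v) {
      if (stats::sd(v) == 0) NaN else stats::cor(tr, rank(v))
    })
  }
  rho_tab <- tibble(gene_id = universe, rho = unname(rho))
  pcg <- rho_tab$gene_id[!is.nan(rho_tab$rho) & rho_tab$rho > threshold]
  ncg <- rho_tab$gene_id[!is.nan(rho_tab$rho) & rho_tab$rho < -threshold]
  n_strong <- length(pcg) + length(ncg)
  pos_rho <- rho_tab$rho[match(pcg, rho_tab$gene_id)]
  neg_rho <- rho_tab$rho[match(ncg, rho_tab$gene_id)]
  med_pos <- if (length(pos_rho)) stats::median(abs(pos_rho)) else NaN
  med_neg <- if (length(neg_rho)) stats::median(abs(neg_rho)) else NaN
  structure(list(
    target = target,
    rho = rho_tab,
    pcg = pcg, ncg = ncg,
    pos_fraction = if (n_strong) length(pcg) / n_strong else NaN,
    median_abs_pos = med_pos,
    median_abs_neg = med_neg,
    median_ratio = if (is.nan(med_pos) || is.nan(med_neg) || med_neg == 0)
      NaN else med_pos / med_neg,
    threshold = threshold,
    degenerate = degenerate
  ), class = "cor_profile")
}

#' @export
print.cor_profile <- function(x, ...) {
  cat("<cor_profile> target '", x$target, "' (|rho| > ", x$threshold,
      ")\n  PCG: ", length(x$pcg), "  NCG: ", length(x$ncg),
      "  pos_fraction: ", signif(x$pos_fraction, 4),
      "  median_ratio: ", signif(x$median_ratio, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy cor_profile
#' @export
tidy.cor_profile <- function(x, ...) {
  x$rho |>
    mutate(target = x$target,
           class = dplyr::case_when(
             is.nan(.data$rho) ~ "undefined",
             .data$rho > x$threshold ~ "pcg",
             .data$rho < -x$threshold ~ "ncg",
             TRUE ~ "weak"
           )) |>
    dplyr::relocate("target")
}

#' @method glance cor_profile
#' @export
glance.cor_profile <- function(x, ...) {
  tibble(target = x$target, n_pcg = length(x$pcg), n_ncg = length(x$ncg),
         pos_fraction = x$pos_fraction, median_abs_pos = x$median_abs_pos,
         median_abs_neg = x$median_abs_neg, median_ratio = x$median_ratio,
         degenerate = x$degenerate)
}

#' Balance index of a set of correlation profiles
#'
#' The balance index is the mean, over target genes with at least one
#' strong correlate, of the fraction of positive correlates among all
#' strong correlates. 0.5 is perfectly balanced. Profiles with no strong
#' correlates are excluded from the mean and counted in the attributes.
#'
#' @param profiles List of [profile_target()] results.
#' @return A single number in \[0, 1\] (NaN, with a warning, if no profile
#'   has a defined fraction), with attributes `n_used` and `n_undefined`.
#' @export
balance_index <- function(profiles) {
  if (!length(profiles)) abort("need at least one profile")
  fr <- vapply_dbl(profiles, function(p) p$pos_fraction)
  defined <- !is.nan(fr)
  if (!any(defined)) {
    warn("no profile has strong correlates; balance index undefined")
    out <- NaN
  } else {
    out <- mean(fr[defined])
  }
  structure(out, n_used = sum(defined), n_undefined = sum(!defined))
}

#' Balance report across target genes
#'
#' Convenience wrapper profiling every target and assembling the per-target
#' summaries plus the overall balance index.
#'
#' @inheritParams profile_target
#' @param targets Character vector of target gene ids.
#' @return A list of class `balance_report`: `profiles` (named list),
#'   `summary` (tibble of per-target glances), `balance_index`.
#' @export
balance_report <- function(x, targets, threshold = 0.5, universe = NULL) {
  profiles <- stats::setNames(
    lapply(targets, function(t) {
      profile_target(x, t, threshold = threshold, universe = universe)
    }), targets)
  structure(list(
    profiles = profiles,
    summary = purrr::map_dfr(profiles, glance),
    balance_index = balance_index(profiles),
    threshold = threshold
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", length(x$profiles), " targets, balance index ",
      signif(as.numeric(x$balance_index), 4), "\n", sep = "")
  invisible(x)
}

#' Plot per-target positive-correlate fractions
#'
#' @param report A [balance_report()].
#' @return A ggplot bar chart of per-target `pos_fraction` with the 0.5
#'   balance line.
#' @export
plot_balance <- function(report) {
  ggplot2::ggplot(report$summary,
                  ggplot2::aes(x = stats::reorder(.data$target,
                                                  .data$pos_fraction),
                               y = .data$pos_fraction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of positive strong correlates")
}

#' Rank targets by inter-method discrepancy in strong-correlate counts
#'
#' For each target gene, scores the focal method's count of (typically
#' negatively) correlated genes against the best count achieved by any
#' other method, and orders targets by descending score. Used to pick the
#' most extreme targets for in-depth auditing (the top 3 by default
#' elsewhere).
#'
#' @param counts Tibble or data frame: one row per target, one column per
#'   method (plus a `target` column), cells = strong-correlate counts.
#' @param focal Name of the focal method column.
#' @param top_k Optionally return only the first `top_k` targets (with a
#'   warning if fewer are available).
#' @return Tibble `target`, `focal_count`, `best_other`, `score`, ordered
#'   by descending score (stable for ties).
#' @export
discrepancy_rank <- function(counts, focal, top_k = NULL) {
  counts <- as_tibble(counts)
  if (!"target" %in% names(counts)) abort("`counts` needs a `target` column")
  methods <- setdiff(names(counts), "target")
  if (!focal %in% methods) abort(paste0("focal method missing: ", focal))
  others <- setdiff(methods, focal)
  if (!length(others)) abort("need at least one non-focal method")
  out <- tibble(
    target = counts$target,
    focal_count = counts[[focal]],
    best_other = do.call(pmax, counts[others]),
  ) |>
    mutate(score = .data$focal_count - .data$best_other) |>
    arrange(desc(.data$score))
  if (!is.null(top_k)) {
    if (top_k > nrow(out)) {
      warn(paste0("requested top ", top_k, " of ", nrow(out), " targets"))
    }
    out <- utils::head(out, top_k)
  }
  out
}
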