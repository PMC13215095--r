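#' AutoFS configuration
#'
#' Tunables for the ensemble feature selector: the univariate branch keeps
#' the top `k_univariate` genes by ANOVA F; the recursive branch eliminates
#' the least important gene (ensemble-averaged importance over a
#' maximal-margin linear classifier, a decision tree and gradient-boosted
#' trees) until one gene remains and keeps the subset size with the best
#' stratified cross-validated accuracy; a randomized search then tunes the
#' learners and a stacked model (logistic-regression meta-learner over
#' out-of-fold base probabilities) produces the final fit.
#'
#' @param k_univariate Genes kept by the univariate branch; default
#'   `min(100, n_genes / 10)`, resolved at run time.
#' @param cv_folds Stratified folds (>= 2, default 5).
#' @param n_search_iterations Randomized-search draws (default 25).
#' @param rfe_max_genes Cap on genes entering recursive elimination; wider
#'   inputs are prefiltered to this many by ANOVA F first (default 50).
#' @param seed Integer root seed; all stages derive from it.
#' @param search_space Named list of per-learner sampling functions; `NULL`
#'   uses the built-in space (SVM cost 2^U(-3,3); tree complexity and
#'   depth; boosting learning rate, depth and rounds).
#' @return A list of class `autofs_config`.
#' @export
autofs_config <- function(k_univariate = NULL, cv_folds = 5,
                          n_search_iterations = 25, rfe_max_genes = 50,
                          seed = 1, search_space = NULL) {
  stopifnot(cv_folds >= 2, n_search_iterations >= 1, rfe_max_genes >= 2)
  structure(list(k_univariate = k_univariate,
                 cv_folds = as.integer(cv_folds),
                 n_search_iterations = as.integer(n_search_iterations),
                 rfe_max_genes = as.integer(rfe_max_genes),
                 seed = as.integer(seed),
                 search_space = search_space %||% default_search_space()),
            class = "autofs_config")
}

default_search_space <- function() {
  list(
    svm = function() list(cost = 2^stats::runif(1, -3, 3)),
    tree = function() list(cp = stats::runif(1, 0.001, 0.05),
                           maxdepth = sample(2:8, 1)),
    gbt = function() list(eta = stats::runif(1, 0.05, 0.5),
                          max_depth = sample(2:6, 1),
                          nrounds = sample(seq(20, 60, 10), 1))
  )
}

default_params <- function() {
  list(svm = list(cost = 1),
       tree = list(cp = 0.01, maxdepth = 5),
       gbt = list(eta = 0.3, max_depth = 3, nrounds = 30))
}

#' Rank genes by between-class ANOVA F statistic
#'
#' One-way F between the two classes (equivalent to a squared two-sample
#' t on the pooled variance). A gene constant across all samples has an
#' undefined ratio and is assigned score 0, ranking last.
#'
#' @param x An [expression_set()].
#' @param k How many top genes to return (`1 <= k <= n_genes`).
#' @return Tibble `gene_id`, `f_stat`, ordered by decreasing F (ties
#'   lexicographic by gene id), truncated to `k` rows.
#' @export
univariate_rank <- function(x, k) {
  genes <- gene_ids(x)
  if (k < 1 || k > length(genes)) abort("k out of range")
  ca <- x$values[, case_cols(x), drop = FALSE]
  co <- x$values[, control_cols(x), drop = FALSE]
  n1 <- ncol(ca); n2 <- ncol(co); n <- n1 + n2
  m1 <- rowMeans(ca); m2 <- rowMeans(co)
  m <- (n1 * m1 + n2 * m2) / n
  between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  within <- rowSums((ca - m1)^2) + rowSums((co - m2)^2)
  f <- ifelse(within > 0, between / (within / (n - 2)), 0)
  tibble(gene_id = genes, f_stat = unname(f)) |>
    arrange(desc(.data$f_stat), .data$gene_id) |>
    utils::head(k)
}

# --- base learners -----------------------------------------------------

# Each learner fits on samples x genes matrix X and 0/1 case labels y,
# and exposes case probabilities and a nonnegative per-gene importance.
fit_base <- function(learner, X, y, params) {
  switch(learner,
    svm = {
      m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                      cost = params$cost, scale = FALSE)
      dv <- drop(attr(stats::predict(m, X, decision.values = TRUE),
                      "decision.values"))
      # decision-value sign is label-order dependent; orient toward case
      flip <- mean(dv[y == 1]) < mean(dv[y == 0])
      list(model = m, flip = flip, learner = "svm")
    },
    tree = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- factor(y, levels = c(0, 1))
      m <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = params$cp, maxdepth = params$maxdepth,
                          minsplit = 4, xval = 0))
      list(model = m, learner = "tree")
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      m <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth, nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
      list(model = m, learner = "gbt")
    },
    abort(paste0("unknown learner: ", learner))
  )
}

predict_base <- function(fit, X) {
  switch(fit$learner,
    svm = {
      dv <- drop(attr(stats::predict(fit$model, X, decision.values = TRUE),
                      "decision.values"))
      if (fit$flip) dv <- -dv
      stats::plogis(dv)
    },
    tree = {
      df <- data.frame(X, check.names = FALSE)
      stats::predict(fit$model, df, type = "prob")[, "1"]
    },
    gbt = stats::predict(fit$model,
                         xgboost::xgb.DMatrix(X, nthread = 1))
  )
}

importance_base <- function(fit, genes) {
  imp <- stats::setNames(rep(0, length(genes)), genes)
  raw <- switch(fit$learner,
    svm = {
      w <- drop(t(fit$model$coefs) %*% fit$model$SV)
      abs(w)
    },
    tree = fit$model$variable.importance,
    gbt = {
      it <- xgboost::xgb.importance(model = fit$model)
      if (is.null(it) || !nrow(it)) NULL else
        stats::setNames(it$Gain, it$Feature)
    }
  )
  if (!is.null(raw) && length(raw)) {
    common <- intersect(names(raw), genes)
    imp[common] <- abs(raw[common])
  }
  if (sum(imp) > 0) imp / sum(imp) else imp
}

ensemble_importance <- function(X, y, params) {
  genes <- colnames(X)
  imps <- lapply(names(params), function(l) {
    importance_base(fit_base(l, X, y, params[[l]]), genes)
  })
  Reduce(`+`, imps) / length(imps)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Mean CV accuracy of the probability-averaged ensemble on X restricted to
# the given fold assignment.
cv_accuracy_ensemble <- function(X, y, fold, params) {
  k <- max(fold)
  acc <- vapply_dbl(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    probs <- vapply(names(params), function(l) {
      fit <- fit_base(l, X[tr, , drop = FALSE], y[tr], params[[l]])
      predict_base(fit, X[te, , drop = FALSE])
    }, numeric(sum(te)))
    if (sum(te) == 1) probs <- matrix(probs, nrow = 1)
    pred <- rowMeans(probs) > 0.5
    mean(pred == (y[te] == 1))
  })
  mean(acc)
}

#' Cross-validated recursive feature elimination over the ensemble
#'
#' Starting from all genes (prefiltered to `rfe_max_genes` by ANOVA F when
#' wider), repeatedly drops the gene with the lowest ensemble-averaged
#' importance, scoring every visited subset size by stratified
#' cross-validated accuracy of the probability-averaged ensemble. Returns
#' the subset maximizing mean CV accuracy; ties resolve to the smaller
#' subset. Deterministic for a fixed config seed.
#'
#' @param x An [expression_set()].
#' @param config An [autofs_config()].
#' @return Character vector of retained gene ids, with attribute `path`: a
#'   tibble of `n_genes`, `cv_accuracy` per visited size.
#' @export
recursive_eliminate <- function(x, config = autofs_config()) {
  y <- as.integer(x$classes == x$case)
  if (min(table(y)) < config$cv_folds) {
    abort("fewer samples per class than cv folds")
  }
  genes <- gene_ids(x)
  if (length(genes) > config$rfe_max_genes) {
    genes <- univariate_rank(x, config$rfe_max_genes)$gene_id
  }
  set.seed(derive_seed(config$seed, "autofs"))
  fold <- stratified_folds(y, config$cv_folds)
  params <- default_params()
  current <- sort(genes)
  sizes <- integer(); accs <- numeric(); subsets <- list()
  while (length(current) >= 1) {
    X <- t(x$values[current, , drop = FALSE])
    sizes <- c(sizes, length(current))
    accs <- c(accs, cv_accuracy_ensemble(X, y, fold, params))
    subsets <- c(subsets, list(current))
    if (length(current) == 1) break
    imp <- ensemble_importance(X, y, params)
    worst <- min(imp)
    # drop the least important gene; among ties drop the lexicographically
    # last so that retained ids are stable across platforms
    ties <- names(imp)[imp <= worst + 1e-15]
    drop_gene <- ties[rev(lex_order(ties))[1]]
    current <- setdiff(current, drop_gene)
  }
  best_acc <- max(accs)
  eligible <- which(accs >= best_acc - 1e-12)
  best <- eligible[which.min(sizes[eligible])]
  out <- subsets[[best]]
  attr(out, "path") <- tibble(n_genes = sizes, cv_accuracy = accs)
  out
}

#' Ensemble feature selection with randomized search and stacking
#'
#' Full AutoFS pipeline: the union of the univariate branch
#' ([univariate_rank()]) and the recursive branch
#' ([recursive_eliminate()]) forms the selected set; a randomized
#' hyperparameter search (scored by stratified CV accuracy of the
#' ensemble) tunes the three base learners on the selected genes; the
#' final model stacks out-of-fold base-learner class probabilities under a
#' logistic-regression meta-learner. Gene importances are the normalized
#' ensemble importances of the tuned learners, restricted to the selected
#' genes and renormalized to sum 1.
#'
#' @param x An [expression_set()].
#' @param config An [autofs_config()].
#' @return An `autofs_fit` list: `selected` (tibble `gene_id`,
#'   `importance`, `provenance` in `{univariate, recursive, both}`),
#'   `cv_accuracy` (stacked model, out-of-fold), `base_cv_accuracy`
#'   (named), `best_params`, `search_trace` (tibble of draws), `config`.
#' @export
autofs <- function(x, config = autofs_config()) {
  y <- as.integer(x$classes == x$case)
  n_genes <- length(gene_ids(x))
  k_uni <- config$k_univariate %||% min(100L, max(1L, n_genes %/% 10L))
  uni <- univariate_rank(x, k_uni)$gene_id
  rec <- recursive_eliminate(x, config)
  selected <- sort(union(uni, rec))
  provenance <- dplyr::case_when(
    selected %in% uni & selected %in% rec ~ "both",
    selected %in% uni ~ "univariate",
    TRUE ~ "recursive"
  )
  X <- t(x$values[selected, , drop = FALSE])

  set.seed(derive_seed(config$seed, "search"))
  fold <- stratified_folds(y, config$cv_folds)
  draws <- purrr::map(seq_len(config$n_search_iterations), function(i) {
    params <- lapply(config$search_space, function(f) f())
    list(iteration = i, params = params,
         accuracy = cv_accuracy_ensemble(X, y, fold, params))
  })
  search_trace <- purrr::map_dfr(draws, function(d) {
    tibble(iteration = d$iteration, cv_accuracy = d$accuracy)
  })
  best <- draws[[which.max(vapply_dbl(draws, `[[`, "accuracy"))]]
  params <- best$params

  # out-of-fold base probabilities -> logistic meta-learner
  set.seed(derive_seed(config$seed, "autofs", 1L))
  oof <- matrix(NA_real_, nrow(X), length(params),
                dimnames = list(NULL, names(params)))
  base_acc <- stats::setNames(numeric(length(params)), names(params))
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f; te <- fold == f
    for (l in names(params)) {
      fit <- fit_base(l, X[tr, , drop = FALSE], y[tr], params[[l]])
      oof[te, l] <- predict_base(fit, X[te, , drop = FALSE])
    }
  }
  for (l in names(params)) {
    base_acc[l] <- mean((oof[, l] > 0.5) == (y == 1))
  }
  meta_df <- data.frame(oof)
  meta_df$.y <- y
  meta <- stats::glm(.y ~ ., data = meta_df, family = stats::binomial())
  stack_prob <- stats::predict(meta, type = "response")
  cv_accuracy <- mean((stack_prob > 0.5) == (y == 1))

  imp <- ensemble_importance(X, y, params)
  if (sum(imp) == 0) imp[] <- 1 / length(imp)
  imp <- imp / sum(imp)

  structure(list(
    selected = tibble(gene_id = selected,
                      importance = unname(imp[selected]),
                      provenance = provenance) |>
      arrange(desc(.data$importance), .data$gene_id),
    cv_accuracy = cv_accuracy,
    base_cv_accuracy = base_acc,
    best_params = params,
    search_trace = search_trace,
    config = config
  ), class = "autofs_fit")
}

#' @export
print.autofs_fit <- function(x, ...) {
  cat("<autofs_fit> ", nrow(x$selected), " genes selected, stacked CV accuracy ",
      round(x$cv_accuracy, 3), "\n", sep = "")
  print(utils::head(x$selected))
  invisible(x)
}

#' @method tidy autofs_fit
#' @export
tidy.autofs_fit <- function(x, ...) x$selected

#' @method glance autofs_fit
#' @export
glance.autofs_fit <- function(x, ...) {
  tibble(n_selected = nrow(x$selected),
         cv_accuracy = x$cv_accuracy,
         best_base_accuracy = max(x$base_cv_accuracy),
         n_univariate = sum(x$selected$provenance != "recursive"),
         n_recursive = sum(x$selected$provenance != "univariate"))
}

#' Plot AutoFS gene importances
#'
#' @param object An `autofs_fit`.
#' @param top How many genes to show (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of importances colored by provenance.
#' @method autoplot autofs_fit
#' @export
autoplot.autofs_fit <- function(object, top = 20, ...) {
  d <- utils::head(object$selected, top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$importance),
    y = .data$importance, fill = .data$provenance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized ensemble importance",
                  fill = NULL)
}
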