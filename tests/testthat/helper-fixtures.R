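# Fixture builders and independent oracles shared across the suite.

# Build an expr_set from a plain matrix; default classes split columns in
# half (first half case).
make_expr <- function(values, classes = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(classes)) {
    n <- ncol(values)
    classes <- stats::setNames(
      rep(c("case", "control"), c(ceiling(n / 2), floor(n / 2))),
      colnames(values))
  }
  expression_set(values, classes, case_label = "case")
}

rand_expr <- function(n_genes, n_case, n_control, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_case + n_control)),
              n_genes, n_case + n_control)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  cls <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                         colnames(m))
  make_expr(m, cls)
}

# --- independent mvAUC oracle -----------------------------------------
# Naive pair-enumeration evaluation of a feature set, written directly
# from the definition with explicit loops: per (case, control) pair the
# credit is the best over oriented member features, where a feature's
# orientation is fixed by its own raw AUC (>= 0.5 -> up-in-case).

oracle_feature_orientation <- function(ca, co) {
  wins <- 0; ties <- 0
  for (a in ca) for (b in co) {
    if (a > b) wins <- wins + 1 else if (a == b) ties <- ties + 1
  }
  raw <- (wins + 0.5 * ties) / (length(ca) * length(co))
  list(raw = raw, up = raw >= 0.5)
}

oracle_mvauc <- function(x, genes) {
  ca_idx <- which(x$classes == x$case)
  co_idx <- which(x$classes == x$control)
  orient <- lapply(genes, function(g) {
    oracle_feature_orientation(x$values[g, ca_idx], x$values[g, co_idx])
  })
  total <- 0; n_pairs <- 0
  for (i in ca_idx) for (j in co_idx) {
    best <- 0
    for (k in seq_along(genes)) {
      a <- x$values[genes[k], i]; b <- x$values[genes[k], j]
      credit <- if (a == b) 0.5 else if ((a > b) == orient[[k]]$up) 1 else 0
      best <- max(best, credit)
    }
    total <- total + best
    n_pairs <- n_pairs + 1
  }
  total / n_pairs
}

# --- exact rank-sum enumeration oracle --------------------------------
# Two-sided p over all label assignments, defined as twice the smaller
# one-sided tail (point mass included), capped at 1. Valid for tie-free
# samples.
oracle_wilcox_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  stats_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  pl <- mean(stats_all <= obs)
  pu <- mean(stats_all >= obs)
  min(1, 2 * min(pl, pu))
}

# --- classical (unweighted) KS running-sum oracle ---------------------
# Step-by-step walk over the ranked list with equal hit increments.
oracle_ks_es <- function(universe, members) {
  k <- sum(universe %in% members)
  N <- length(universe)
  running <- 0; best <- 0
  for (g in universe) {
    running <- running + if (g %in% members) 1 / k else -1 / (N - k)
    if (abs(running) > abs(best)) best <- running
  }
  best
}
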