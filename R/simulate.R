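#' Simulate a two-class expression matrix with known coexpression structure
#'
#' Generates an expression matrix under a latent single-factor model so that
#' every downstream stage (selection, correlation balance, enrichment) has
#' exact ground truth. Each anchor gene carries the class signal:
#' `anchor = delta * I(case) + N(0, 1)` per sample. Positive-block genes are
#' `beta * anchor + N(0, noise_sd)`, negative-block genes
#' `-beta * anchor + N(0, noise_sd)` (blocks are assigned to anchors
#' round-robin when there are several), and null genes are pure
#' `N(0, noise_sd)` noise. The coupling `beta` monotonically controls the
#' attained |Spearman rho| with the anchor, and the per-gene sign structure
#' is guaranteed by construction.
#'
#' @param n_case,n_control Samples per class (each >= 4).
#' @param n_anchor Number of anchor (target) genes, >= 1.
#' @param pos_block_size,neg_block_size,null_block_size Gene counts for the
#'   positively coupled, negatively coupled and background blocks (>= 0,
#'   not all zero together with anchors).
#' @param beta Coupling strength (> 0) of block genes to their anchor.
#' @param delta Anchor mean shift between case and control samples.
#' @param noise_sd Standard deviation (> 0) of block/null gene noise.
#' @param baseline Constant added to every value (default 0). All rank
#'   based statistics (AUC, Spearman, rank-sum tests) are invariant to the
#'   shift; a positive baseline keeps class means positive so that the
#'   pseudocount log fold change of [wrst_de()] is defined.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return A list with `expr` (an [expression_set()]) and `truth`, a tibble
#'   with columns `gene_id`, `block` (`anchor`, `pos`, `neg`, `null`),
#'   `designed_sign` (+1, -1, 0) and `anchor_id` (coupled anchor, `NA` for
#'   null genes).
#' @examples
#' sim <- simulate_expression(seed = 1)
#' sim$expr
#' dplyr::count(sim$truth, block)
#' @export
simulate_expression <- function(n_case = 50, n_control = 50, n_anchor = 1,
                                pos_block_size = 50, neg_block_size = 50,
                                null_block_size = 100, beta = 5,
                                delta = 2, noise_sd = 1, baseline = 0,
                                seed = 1) {
  stopifnot(n_case >= 4, n_control >= 4, n_anchor >= 1,
            pos_block_size >= 0, neg_block_size >= 0, null_block_size >= 0,
            beta > 0, noise_sd > 0)
  if (pos_block_size + neg_block_size + null_block_size == 0) {
    abort("degenerate config: all non-anchor blocks empty")
  }
  set.seed(as.integer(seed))
  n <- n_case + n_control
  cls <- c(rep("case", n_case), rep("control", n_control))
  samples <- sprintf("S%03d", seq_len(n))

  pad <- function(prefix, k) if (k) sprintf("%s%03d", prefix, seq_len(k)) else character()
  anchor_ids <- pad("ANCHOR", n_anchor)
  pos_ids <- pad("POS", pos_block_size)
  neg_ids <- pad("NEG", neg_block_size)
  null_ids <- pad("NULL", null_block_size)

  anchors <- vapply(seq_len(n_anchor), function(i) {
    delta * (cls == "case") + stats::rnorm(n)
  }, numeric(n))           # n x n_anchor
  anchors <- t(anchors)    # n_anchor x n

  assign_anchor <- function(k) {
    if (!k) return(integer())
    rep_len(seq_len(n_anchor), k)
  }
  pos_a <- assign_anchor(pos_block_size)
  neg_a <- assign_anchor(neg_block_size)

  block_rows <- function(k, anchor_idx, sign) {
    if (!k) return(matrix(numeric(), 0, n))
    t(vapply(seq_len(k), function(i) {
      sign * beta * anchors[anchor_idx[i], ] + stats::rnorm(n, sd = noise_sd)
    }, numeric(n)))
  }
  pos_m <- block_rows(pos_block_size, pos_a, +1)
  neg_m <- block_rows(neg_block_size, neg_a, -1)
  null_m <- if (null_block_size) {
    matrix(stats::rnorm(null_block_size * n, sd = noise_sd),
           null_block_size, n)
  } else matrix(numeric(), 0, n)

  values <- rbind(anchors, pos_m, neg_m, null_m) + baseline
  rownames(values) <- c(anchor_ids, pos_ids, neg_ids, null_ids)
  colnames(values) <- samples

  truth <- tibble(
    gene_id = rownames(values),
    block = c(rep("anchor", n_anchor), rep("pos", pos_block_size),
              rep("neg", neg_block_size), rep("null", null_block_size)),
    designed_sign = c(rep(1L, n_anchor), rep(1L, pos_block_size),
                      rep(-1L, neg_block_size), rep(0L, null_block_size)),
    anchor_id = c(anchor_ids,
                  anchor_ids[pos_a], anchor_ids[neg_a],
                  rep(NA_character_, null_block_size))
  )

  expr <- expression_set(values, stats::setNames(cls, samples),
                         case_label = "case", scale_tag = "simulated")
  list(expr = expr, truth = truth)
}

#' Simulate gene sets with known activation direction
#'
#' Builds a collection whose ground truth matches a [simulate_expression()]
#' dataset: half the sets are "designed-activated" (members drawn
#' predominantly from the positively coupled block), half
#' "designed-suppressed" (from the negative block); the remainder of each
#' set is filled from the null block. Set names encode the design
#' (`ACT_...` / `SUP_...`) so tests can assert recovered direction.
#'
#' @param truth Ground-truth tibble from [simulate_expression()].
#' @param n_sets Total number of sets (split evenly between directions).
#' @param set_size Members per set.
#' @param purity Fraction (0, 1] of each set drawn from its designed block.
#' @param seed Integer seed.
#' @return A `gene_sets` collection with an extra attribute
#'   `designed_direction` (named vector: `activated` / `suppressed`).
#' @export
simulate_gene_sets <- function(truth, n_sets = 10, set_size = 10,
                               purity = 1, seed = 1) {
  stopifnot(purity > 0, purity <= 1, n_sets >= 0, set_size >= 1)
  if (n_sets == 0) {
    return(gene_set_collection(character(), list(),
                               collection_label = "simulated"))
  }
  set.seed(as.integer(seed))
  pos_pool <- truth$gene_id[truth$block == "pos"]
  neg_pool <- truth$gene_id[truth$block == "neg"]
  null_pool <- truth$gene_id[truth$block == "null"]
  n_designed <- round(purity * set_size)
  n_filler <- set_size - n_designed
  if (n_designed > min(length(pos_pool), length(neg_pool))) {
    abort("requested designed members exceed available block pool")
  }
  if (n_filler > length(null_pool)) {
    abort("requested filler members exceed available null pool")
  }
  n_act <- ceiling(n_sets / 2)
  n_sup <- n_sets - n_act
  build <- function(pool, k) {
    lapply(seq_len(k), function(i) {
      c(sample(pool, n_designed), sample(null_pool, n_filler))
    })
  }
  act_members <- build(pos_pool, n_act)
  sup_members <- build(neg_pool, n_sup)
  nm <- c(if (n_act) sprintf("ACT_SET%02d", seq_len(n_act)),
          if (n_sup) sprintf("SUP_SET%02d", seq_len(n_sup)))
  dirs <- stats::setNames(
    c(rep("activated", n_act), rep("suppressed", n_sup)), nm)
  out <- gene_set_collection(
    nm,
    c(act_members, sup_members),
    descriptions = paste0("designed-", dirs, " synthetic set"),
    collection_label = "simulated"
  )
  attr(out, "designed_direction") <- dirs
  out
}
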