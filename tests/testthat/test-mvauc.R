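# 2-case / 2-control fixture in which two features perfectly order
# disjoint halves of the between-class pairs and tie elsewhere.
complementary_fixture <- function() {
  m <- rbind(
    gA = c(2, 1, 1, 1),
    gB = c(1, 2, 1, 1)
  )
  colnames(m) <- paste0("s", 1:4)
  make_expr(m)
}

test_that("oriented AUC handles separation, symmetry, ties and constants", {
  m <- rbind(up = c(3, 4, 1, 2),
             down = c(1, 2, 3, 4),
             tied = c(1, 2, 2, 3),
             flat = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  es <- make_expr(m)

  up <- feature_auc(es, "up")
  expect_equal(up$auc, 1)
  expect_equal(up$orientation, "up-in-case")

  down <- feature_auc(es, "down")
  expect_equal(down$auc, 1)
  expect_equal(down$orientation, "down-in-case")

  # case (1,2) vs control (2,3): raw = (0 + 0.5 * 1) / 4 = 0.125
  tied <- feature_auc(es, "tied")
  expect_equal(tied$raw_auc, 0.125)
  expect_equal(tied$auc, 0.875)
  expect_equal(tied$orientation, "down-in-case")

  flat <- feature_auc(es, "flat")
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$orientation, "up-in-case")

  expect_error(feature_auc(es, "absent"), "not in matrix")
})

test_that("mvAUC reduces to AUC on singletons and unions complementary coverage", {
  es <- complementary_fixture()
  a <- feature_auc(es, "gA")$auc
  b <- feature_auc(es, "gB")$auc
  expect_equal(mvauc(es, "gA"), a)
  expect_equal(mvauc(es, "gB"), b)
  expect_lt(a, 1)
  expect_lt(b, 1)
  expect_equal(mvauc(es, c("gA", "gB")), 1)
  expect_equal(mvauc(es, c("gA", "gA")), mvauc(es, "gA"))
  expect_error(mvauc(es, character()), "empty")
})

test_that("greedy selection suppresses redundancy and completes complementary pairs", {
  dup <- make_expr(matrix(rep(c(3, 4, 1, 2), 5), 5, 4, byrow = TRUE))
  tr <- macfc_main(dup)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$cumulative_mvauc, 1)

  es <- complementary_fixture()
  tr2 <- macfc_main(es)
  expect_setequal(tr2$gene_id, c("gA", "gB"))
  expect_equal(tr2$cumulative_mvauc[2], 1)
  expect_true(all(diff(tr2$cumulative_mvauc) >= 0))
  expect_equal(nrow(tr2), length(tr2$weight))
})

test_that("greedy two-step prefix matches exhaustive subset search on a small fixture", {
  es <- rand_expr(6, 3, 3, seed = 5)
  tr <- macfc_main(es, max_features = 2)
  genes <- gene_ids(es)
  best1 <- max(vapply(genes, function(g) oracle_mvauc(es, g), numeric(1)))
  expect_equal(tr$cumulative_mvauc[1], best1)
  if (nrow(tr) >= 2) {
    pairs <- utils::combn(genes, 2)
    best2 <- max(apply(pairs, 2, function(p) oracle_mvauc(es, p)))
    # greedy's 2-prefix must reach the exhaustive optimum here
    expect_equal(tr$cumulative_mvauc[2], best2)
  }
})

test_that("seeded variant retains high-AUC genes and reduces to greedy when none pass", {
  # 10 case / 10 control values engineered to oriented AUCs 0.97/0.96/0.80
  ctrl <- 1:10
  g97 <- c(7.5, 12:20)     # 3 of 100 pairs wrong
  g96 <- c(6.5, 12:20)     # 4 wrong
  g80 <- c(0.5, 0.6, 13:20)  # 2 x 10 wrong
  m <- rbind(g97 = c(g97, ctrl), g96 = c(g96, ctrl), g80 = c(g80, ctrl))
  colnames(m) <- paste0("s", 1:20)
  es <- make_expr(m)
  expect_equal(feature_auc(es, "g97")$auc, 0.97)
  expect_equal(feature_auc(es, "g96")$auc, 0.96)
  expect_equal(feature_auc(es, "g80")$auc, 0.80)

  tr <- macfc_v2(es, auc_threshold = 0.95)
  expect_equal(attr(tr, "seed_set"), c("g97", "g96"))
  expect_equal(tr$gene_id[1:2], c("g97", "g96"))

  # saturated seed: one perfect gene covers all pairs, no complementary picks
  perfect <- make_expr(rbind(hero = c(11:20, 1:10),
                             noise = c(1, 3, 2, 4, 1, 3, 2, 4, 1, 3,
                                       2, 4, 1, 3, 2, 4, 1, 3, 2, 4)))
  trp <- macfc_v2(perfect, auc_threshold = 0.95)
  expect_equal(trp$gene_id, "hero")
  expect_equal(trp$cumulative_mvauc, 1)

  # nothing above threshold: identical to the unseeded algorithm
  es2 <- rand_expr(8, 4, 4, seed = 9)
  t_main <- macfc_main(es2)
  t_v2 <- macfc_v2(es2, auc_threshold = 0.999)
  expect_equal(tidy(t_v2), tidy(t_main))
})

test_that("mvAUC obeys monotonicity, dominance and label-swap symmetry", {
  for (seed in 1:10) {
    es <- rand_expr(6, 3, 3, seed = seed)
    genes <- gene_ids(es)
    s <- sample(genes, 3)
    g <- sample(setdiff(genes, s), 1)
    base <- mvauc(es, s)
    expect_gte(mvauc(es, c(s, g)), base)
    expect_gte(base, max(vapply(s, function(gg) feature_auc(es, gg)$auc,
                                numeric(1))))
    swapped <- swap_classes(es)
    expect_equal(mvauc(swapped, s), base)
    fa <- feature_auc(es, g)
    fs <- feature_auc(swapped, g)
    expect_equal(fs$auc, fa$auc)
    if (fa$auc > 0.5) expect_false(fs$orientation == fa$orientation)
  }
})
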