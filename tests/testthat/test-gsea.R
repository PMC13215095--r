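ranked_fixture <- function(ids, scores) {
  out <- tibble::tibble(gene_id = ids, score = scores)
  class(out) <- c("ranked_list", class(out))
  out
}

test_that("ranking by target puts coupled blocks at the extremes", {
  sim <- simulate_expression(n_case = 25, n_control = 25,
                             pos_block_size = 10, neg_block_size = 10,
                             null_block_size = 20,
                             beta = 10, noise_sd = 0.1, seed = 6)
  rk <- rank_by_target(sim$expr, "ANCHOR001")
  expect_false("ANCHOR001" %in% rk$gene_id)
  expect_true(all(diff(rk$score) <= 0))
  pos <- sim$truth$gene_id[sim$truth$block == "pos"]
  neg <- sim$truth$gene_id[sim$truth$block == "neg"]
  expect_setequal(utils::head(rk$gene_id, 10), pos)
  expect_setequal(utils::tail(rk$gene_id, 10), neg)
})

test_that("tied ranking scores fall back to lexicographic gene order", {
  m <- rbind(t = c(1, 2, 3, 4, 5, 6),
             zb = c(1, 2, 3, 4, 5, 6) * 2,
             za = c(2, 4, 6, 8, 10, 12),
             low = c(6, 5, 4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:6)
  rk <- rank_by_target(make_expr(m), "t")
  expect_equal(rk$gene_id, c("za", "zb", "low"))  # rho 1, 1, -1
})

test_that("enrichment score matches the hand-walked 4-gene examples", {
  rk <- ranked_fixture(paste0("g", 1:4), c(4, 3, 2, 1))
  top <- enrichment_score(rk, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, "g1")

  bottom <- enrichment_score(rk, "g4")
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, "g4")

  expect_error(enrichment_score(rk, c("x", "y")), "no overlap")
  expect_error(enrichment_score(rk, paste0("g", 1:4)), "entire")
})

test_that("unweighted ES equals the classical KS running-sum statistic", {
  rk <- ranked_fixture(paste0("g", 1:6), c(3, 2.5, 2, 1.5, 1, 0.5))
  members <- c("g2", "g3")
  es <- enrichment_score(rk, members, p = 0)$es
  expect_equal(es, 0.75)  # frozen from the 6-step hand walk
  expect_equal(es, oracle_ks_es(rk$gene_id, members))

  # independent random checks against the step-by-step oracle
  for (seed in 1:10) {
    set.seed(seed)
    ids <- paste0("g", 1:30)
    rkr <- ranked_fixture(ids, sort(rnorm(30), decreasing = TRUE))
    mem <- sample(ids, 6)
    expect_equal(enrichment_score(rkr, mem, p = 0)$es,
                 oracle_ks_es(ids, mem))
  }
})

test_that("ES stays in [-1, 1], reversal negates it at p = 0, leading edge non-empty", {
  for (seed in 1:15) {
    set.seed(seed)
    ids <- paste0("g", 1:40)
    scores <- sort(rnorm(40), decreasing = TRUE)
    rk <- ranked_fixture(ids, scores)
    mem <- sample(ids, sample(3:10, 1))
    r <- enrichment_score(rk, mem, p = 1)
    expect_gte(r$es, -1)
    expect_lte(r$es, 1)
    if (r$es != 0) expect_gt(length(r$leading_edge), 0)
    expect_true(all(r$leading_edge %in% intersect(mem, ids)))

    rev_rk <- ranked_fixture(rev(ids), rev(-scores))
    expect_equal(enrichment_score(rev_rk, mem, p = 0)$es,
                 -enrichment_score(rk, mem, p = 0)$es)
  }
})

test_that("weighted ES agrees with an external reference implementation", {
  skip_if_not_installed("fgsea")
  for (seed in 1:8) {
    set.seed(seed)
    ids <- paste0("g", 1:50)
    scores <- sort(rnorm(50), decreasing = TRUE)
    rk <- ranked_fixture(ids, scores)
    mem <- sample(ids, 8)
    ours <- enrichment_score(rk, mem, p = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(scores, ids),
                               selectedStats = which(ids %in% mem),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("designed sets reach significance with the right sign, reproducibly", {
  sim <- simulate_expression(n_case = 20, n_control = 20,
                             pos_block_size = 25, neg_block_size = 25,
                             null_block_size = 50, seed = 12)
  gs <- simulate_gene_sets(sim$truth, n_sets = 6, set_size = 10,
                           purity = 1, seed = 2)
  rk <- rank_by_target(sim$expr, "ANCHOR001")
  cfg <- gsea_config(n_permutations = 200, seed = 5)
  recs <- gsea_collection(rk, gs, cfg)
  dirs <- attr(gs, "designed_direction")
  for (i in seq_len(nrow(recs))) {
    expected <- dirs[[recs$set_name[i]]]
    expect_equal(recs$direction[i], expected)
    expect_lte(recs$pvalue[i], 0.05)
  }
  recs2 <- gsea_collection(rk, gs, cfg)
  expect_identical(recs$nes, recs2$nes)
  expect_identical(recs$leading_edge, recs2$leading_edge)

  one <- gsea_significance(rk, gs$members[[1]], cfg, set_name = "solo")
  expect_equal(one$direction, "activated")
})

test_that("repeat fractions are one-sided, balanced or NaN as designed", {
  sim <- simulate_expression(n_case = 20, n_control = 20,
                             pos_block_size = 25, neg_block_size = 25,
                             null_block_size = 50, seed = 12)
  cfg <- gsea_config(n_permutations = 100, n_repeats = 4, seed = 9)

  act_only <- simulate_gene_sets(sim$truth, n_sets = 4, set_size = 10,
                                 purity = 1, seed = 3)
  act_only <- act_only[startsWith(act_only$set_name, "ACT"), ]
  fr <- repeat_fraction(sim$expr, "ANCHOR001", act_only, cfg)
  expect_true(all(fr$fraction_activated == 1))

  balanced <- simulate_gene_sets(sim$truth, n_sets = 8, set_size = 10,
                                 purity = 1, seed = 4)
  frb <- repeat_fraction(sim$expr, "ANCHOR001", balanced, cfg)
  expect_equal(mean(frb$fraction_activated), 0.5, tolerance = 0.1)

  # null sets under a strict gate pass nothing: NaN, never 0
  null_ids <- sim$truth$gene_id[sim$truth$block == "null"]
  set.seed(1)
  null_sets <- gene_set_collection(
    paste0("NULLSET", 1:4),
    lapply(1:4, function(i) sample(null_ids, 10)),
    collection_label = "null")
  strict <- cfg
  strict$alpha_q <- 1e-4
  frn <- repeat_fraction(sim$expr, "ANCHOR001", null_sets, strict)
  expect_true(all(is.nan(frn$fraction_activated)))
})

test_that("redundancy clustering is single-linkage on same-direction leading edges", {
  mk_rec <- function(name, dir, nes, le) {
    tibble::tibble(set_name = name, es = sign(nes) * 0.5, nes = nes,
                   pvalue = 0.01, fdr_q = 0.01, direction = dir,
                   leading_edge = list(le), n_hits = length(le),
                   collection_label = "x")
  }
  recs <- dplyr::bind_rows(
    mk_rec("A", "activated", 2.0, letters[1:10]),
    mk_rec("B", "activated", 1.5, letters[1:10]),       # identical: J = 1
    mk_rec("C", "activated", 1.2, letters[15:20]),      # disjoint
    mk_rec("D", "suppressed", -2.1, letters[1:10])      # other direction
  )
  out <- redundancy_flag(recs, jaccard_threshold = 0.8)
  expect_equal(out$cluster[1], out$cluster[2])
  expect_false(out$cluster[3] == out$cluster[1])
  expect_false(out$cluster[4] == out$cluster[1])
  cl <- attr(out, "clusters")
  expect_equal(cl$representative[cl$n_members == 2], "A")  # largest |NES|

  # nested sub-pathway: leading edges overlapping at Jaccard >= 0.85
  nested <- dplyr::bind_rows(
    mk_rec("big", "activated", 1.8, letters[1:20]),
    mk_rec("sub", "activated", 1.1, letters[1:17])  # J = 17/20 = 0.85
  )
  out2 <- redundancy_flag(nested, jaccard_threshold = 0.85)
  expect_equal(out2$cluster[1], out2$cluster[2])
})
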