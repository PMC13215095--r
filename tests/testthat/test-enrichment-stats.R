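mk_rec <- function(name, dir, le) {
  tibble::tibble(set_name = name, es = if (dir == "activated") 0.5 else -0.5,
                 nes = if (dir == "activated") 1.5 else -1.5,
                 pvalue = 0.01, fdr_q = 0.01, direction = dir,
                 leading_edge = list(le), n_hits = length(le),
                 collection_label = "x")
}

test_that("core-gene accounting separates dedup, non-dedup and super-core", {
  recs <- dplyr::bind_rows(
    mk_rec("P1", "activated", c("a", "b")),
    mk_rec("P2", "activated", c("a", "c")),
    mk_rec("N1", "suppressed", "d")
  )
  cs <- quantify_core(recs, "demo")
  act <- cs$by_direction[cs$by_direction$direction == "activated", ]
  sup <- cs$by_direction[cs$by_direction$direction == "suppressed", ]
  expect_equal(act$n_dedup, 3)        # {a, b, c}
  expect_equal(act$n_nondedup, 4)     # a counted twice
  expect_equal(act$super_core[[1]]$gene_id, "a")
  expect_equal(act$super_core[[1]]$recurrence, 2L)
  expect_equal(sup$n_dedup, 1)
  expect_equal(cs$ratio_dedup, 3)
  expect_equal(cs$ratio_nondedup, 4)

  # no recurrence anywhere: both accountings agree
  flat <- dplyr::bind_rows(mk_rec("P1", "activated", c("a", "b")),
                           mk_rec("N1", "suppressed", c("c", "d")))
  cf <- quantify_core(flat, "demo")
  expect_equal(cf$ratio_dedup, cf$ratio_nondedup)
  expect_true(all(vapply(cf$by_direction$super_core, nrow, integer(1)) == 0))

  # no suppressed pathways: ratios NaN with a diagnostic, not an error
  expect_message(up_only <- quantify_core(mk_rec("P1", "activated", "a"),
                                          "demo"),
                 "undefined")
  expect_true(is.nan(up_only$ratio_dedup))
})

test_that("super-core recurrence confined to one side amplifies its ratio", {
  # random fixtures: activated edges may share genes, suppressed never do
  for (seed in 1:20) {
    set.seed(seed)
    shared_pool <- paste0("s", 1:6)
    n_act <- sample(2:5, 1)
    act <- lapply(seq_len(n_act), function(i) {
      unique(c(sample(shared_pool, sample(1:3, 1)),
               paste0("a", i, "_", 1:3)))
    })
    sup <- lapply(seq_len(sample(1:4, 1)), function(i) {
      paste0("z", i, "_", 1:4)  # disjoint by construction
    })
    recs <- dplyr::bind_rows(
      purrr::imap(act, function(le, i) mk_rec(paste0("A", i), "activated", le)),
      purrr::imap(sup, function(le, i) mk_rec(paste0("S", i), "suppressed", le))
    )
    cs <- quantify_core(recs, "m")
    expect_gte(cs$ratio_nondedup, cs$ratio_dedup)
    recur <- sum(vapply(cs$by_direction$super_core, nrow, integer(1)))
    if (recur == 0) expect_equal(cs$ratio_nondedup, cs$ratio_dedup)
  }
})

test_that("unique and shared core genes split as designed", {
  same <- list(m1 = c("a", "b"), m2 = c("a", "b"))
  u <- unique_vs_shared(same)
  expect_equal(u$shared, c("a", "b"))
  expect_true(all(u$per_method$n_unique == 0))

  disj <- list(m1 = c("a", "b"), m2 = c("c", "d"))
  u2 <- unique_vs_shared(disj)
  expect_length(u2$shared, 0)
  expect_equal(u2$per_method$unique_genes[[1]], c("a", "b"))

  # 3 methods with designed overlaps, proportions hand-counted
  three <- list(m1 = c("a", "b", "c", "x"),
                m2 = c("b", "c", "y"),
                m3 = c("c", "z", "x"))
  u3 <- unique_vs_shared(three)
  expect_equal(u3$shared, "c")
  expect_equal(u3$per_method$n_unique, c(1L, 1L, 1L))  # a / y / z
  expect_equal(u3$per_method$prop_unique, c(1 / 4, 1 / 3, 1 / 3))

  expect_error(unique_vs_shared(list(m1 = "a")), "at least two")
})

test_that("Kruskal-Wallis handles null, separated and permuted groups", {
  ident <- list(c(1, 2, 3), c(1, 2, 3))
  k0 <- kruskal_wallis(ident)
  expect_equal(k0$statistic, 0)
  expect_equal(k0$pvalue, 1)

  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  k <- kruskal_wallis(g)
  expect_equal(k$statistic, 7.2)
  expect_equal(k$df, 2)

  kp <- kruskal_wallis(g[c(3, 1, 2)])
  expect_equal(kp$statistic, k$statistic)
  expect_equal(kp$pvalue, k$pvalue)
})

test_that("pairwise rank-sum matrix is symmetric and matches enumeration", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 3, 4))
  m <- wilcoxon_pairwise(g, adjust = "none")
  expect_equal(diag(m), setNames(rep(1, 3), names(g)))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], 0.1)  # exact, fully separated 3v3

  ident <- wilcoxon_pairwise(list(x = c(5, 5, 5), y = c(5, 5, 5)))
  expect_equal(ident["x", "y"], 1)

  # exact-enumeration oracle agreement for tie-free groups of size <= 5
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    ours <- wilcoxon_pairwise(list(a = a, b = b), adjust = "none")["a", "b"]
    expect_equal(ours, oracle_wilcox_p(a, b))
  }
})

test_that("the composite score rewards balance and concordance, penalizes failure", {
  perfect <- tibble::tibble(target = "t1",
                            fraction_activated = rep(0.5, 4),
                            pos_fraction = 0.5)
  expect_equal(composite_score(perfect)$score, 1)

  failed <- tibble::tibble(target = "t1",
                           fraction_activated = rep(NaN, 4),
                           pos_fraction = 0.5)
  expect_equal(composite_score(failed)$score, 0)
  expect_equal(composite_score(failed)$n_failed, 4L)

  single <- tibble::tibble(target = "t1", fraction_activated = 0.75,
                           pos_fraction = 0.5)
  expect_equal(composite_score(single)$score, 0.75 * 0.5)

  # monotone nonincreasing in |f_pathway - 0.5| at fixed concordance
  drift <- vapply(c(0.5, 0.6, 0.7, 0.8), function(f) {
    composite_score(tibble::tibble(target = "t", fraction_activated = f,
                                   pos_fraction = f))$score
  }, numeric(1))
  expect_true(all(diff(drift) <= 0))

  expect_error(composite_score(tibble::tibble()), "missing column")
})
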