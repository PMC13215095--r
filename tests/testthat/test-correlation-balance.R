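test_that("Spearman correlation follows rank arithmetic and guards inputs", {
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)  # hand-ranked Pearson
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 1), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  expect_true(is.nan(spearman_rho(1:5, rep(2, 5))))
  expect_error(spearman_rho(1:4, 1:5), "length mismatch")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(1:3, c(1, NA, 3)), "non-finite")

  # invariance under strictly increasing transforms of either vector
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(20); y <- rnorm(20)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r)
    expect_equal(spearman_rho(x, y^3 + 5 * y), r)
  }
})

test_that("profiles classify designed blocks exactly under strong coupling", {
  sim <- simulate_expression(n_case = 25, n_control = 25,
                             pos_block_size = 20, neg_block_size = 20,
                             null_block_size = 20,
                             beta = 10, noise_sd = 0.1, seed = 4)
  prof <- profile_target(sim$expr, "ANCHOR001")
  expect_setequal(prof$pcg, sim$truth$gene_id[sim$truth$block == "pos"])
  expect_setequal(prof$ncg, sim$truth$gene_id[sim$truth$block == "neg"])
  expect_equal(prof$pos_fraction, 0.5)
  expect_false(prof$target %in% prof$rho$gene_id)  # self-excluded

  unreachable <- profile_target(sim$expr, "ANCHOR001", threshold = 1)
  expect_length(unreachable$pcg, 0)
  expect_length(unreachable$ncg, 0)
  expect_true(is.nan(unreachable$pos_fraction))

  flat <- sim$expr
  flat$values["NULL001", ] <- 7
  expect_warning(pf <- profile_target(flat, "NULL001"), "constant")
  expect_true(pf$degenerate)
  expect_true(all(is.nan(pf$rho$rho)))
})

test_that("a rho just above the threshold is classified as a positive correlate", {
  set.seed(99)
  repeat {
    x <- rnorm(30)
    y <- 0.75 * x + rnorm(30)
    r <- spearman_rho(x, y)
    if (r > 0.55 && r < 0.7) break
  }
  m <- rbind(t = x, other = y, pad1 = rnorm(30), pad2 = rnorm(30))
  colnames(m) <- paste0("s", 1:30)
  es <- make_expr(m)
  expect_true("other" %in% profile_target(es, "t")$pcg)
})

test_that("the balance index averages defined fractions and flips under negation", {
  sim <- simulate_expression(n_case = 20, n_control = 20,
                             pos_block_size = 15, neg_block_size = 5,
                             null_block_size = 10,
                             beta = 10, noise_sd = 0.1, seed = 8)
  prof <- profile_target(sim$expr, "ANCHOR001")
  expect_equal(prof$pos_fraction, 0.75)

  # negating the target exchanges its positive and negative correlates
  neg <- sim$expr
  neg$values["ANCHOR001", ] <- -neg$values["ANCHOR001", ]
  pneg <- profile_target(neg, "ANCHOR001")
  expect_equal(pneg$pos_fraction, 1 - prof$pos_fraction)
  expect_setequal(pneg$pcg, prof$ncg)

  fake <- function(f) structure(list(pos_fraction = f), class = "cor_profile")
  expect_equal(as.numeric(balance_index(list(fake(1), fake(0)))), 0.5)
  expect_equal(as.numeric(balance_index(list(fake(0.5), fake(NaN)))), 0.5)
  expect_equal(attr(balance_index(list(fake(0.5), fake(NaN))), "n_undefined"), 1)
  expect_warning(b <- balance_index(list(fake(NaN))), "undefined")
  expect_true(is.nan(as.numeric(b)))
})

test_that("strong-correlate counts under independence match the Spearman null tail", {
  # n = 10 samples: two-sided tail P(|rho| > 0.5) from the t approximation
  n <- 10
  tstat <- 0.5 * sqrt((n - 2) / (1 - 0.25))
  expected <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  fracs <- vapply(1:10, function(s) {
    sim <- simulate_expression(n_case = 5, n_control = 5,
                               pos_block_size = 0, neg_block_size = 0,
                               null_block_size = 300, delta = 0, seed = s)
    p <- profile_target(sim$expr, "ANCHOR001")
    (length(p$pcg) + length(p$ncg)) / nrow(p$rho)
  }, numeric(1))
  expect_equal(mean(fracs), expected, tolerance = 0.25)
})

test_that("discrepancy ranking orders targets by focal excess", {
  counts <- tibble::tibble(target = c("t1", "t2"),
                           focal = c(10, 2),
                           m2 = c(4, 5), m3 = c(2, 1))
  r <- discrepancy_rank(counts, "focal")
  expect_equal(r$score, c(6, -3))
  expect_equal(r$target, c("t1", "t2"))

  tied <- tibble::tibble(target = c("a", "b", "c"),
                         focal = c(3, 3, 3), other = c(3, 3, 3))
  rt <- discrepancy_rank(tied, "focal")
  expect_equal(rt$score, c(0, 0, 0))
  expect_equal(rt$target, c("a", "b", "c"))  # stable order

  expect_warning(topped <- discrepancy_rank(counts, "focal", top_k = 3),
                 "top 3")
  expect_equal(nrow(topped), 2)
  expect_error(discrepancy_rank(counts, "nope"), "focal method missing")
})
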