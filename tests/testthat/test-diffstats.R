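test_that("two-sample pooled t matches hand evaluation and t.test", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$diff, -3)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0214, tolerance = 1e-2)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)

  # identical samples: t = 0, p = 1
  r0 <- two_sample_t(c(2, 3, 4), c(2, 3, 4))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # s0 shrinks every nonzero statistic toward 0, never flips the sign
  for (s0 in c(0.1, 1, 5)) {
    rs <- two_sample_t(c(1, 2, 3), c(4, 5, 6), s0 = s0)
    expect_lt(abs(rs$t), abs(r$t))
    expect_equal(sign(rs$t), sign(r$t))
    # the reference p stays that of the unmodified statistic
    expect_equal(rs$p, r$p)
  }

  # zero pooled variance
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$t, 0)
  rz <- two_sample_t(c(2, 2), c(1, 1))
  expect_identical(rz$t, Inf)
  expect_equal(rz$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("exhaustive 3v3 estimates match an explicit enumeration oracle", {
  set.seed(13)
  n <- 60
  grid <- matrix(rnorm(n * 6), n, 6)
  grid[1:5, 1:3] <- grid[1:5, 1:3] + 3   # a few real shifts
  m <- tiny_matrix(grid, groups = rep(c("A", "B"), each = 3),
                   scale = "log2")
  res <- perm_fdr(m, q = 0.05, seed = 1)
  expect_identical(res$mode, "exhaustive")
  expect_equal(res$n_labelings, choose(6, 3))

  # oracle: brute-force every labeling with t.test, then the FDR formula
  # with plain loops and a tail-minimum monotonization
  labs <- combn(6, 3, simplify = FALSE)
  tstat <- function(ia) {
    apply(grid, 1, function(row) {
      unname(t.test(row[ia], row[-ia], var.equal = TRUE)$statistic)
    })
  }
  obs_abs <- abs(tstat(1:3))
  null_abs <- abs(vapply(labs, tstat, numeric(n)))
  fdr_raw <- vapply(seq_len(n), function(i) {
    thr <- obs_abs[i]
    min(1, mean(colSums(null_abs >= thr)) / sum(obs_abs >= thr))
  }, numeric(1))
  ord <- order(-obs_abs)
  fdr_oracle <- numeric(n)
  for (r in seq_len(n)) {
    fdr_oracle[ord[r]] <- min(fdr_raw[ord[r:n]])
  }
  expect_equal(res$table$fdr, fdr_oracle, tolerance = 1e-12)
  expect_identical(res$table$significant, fdr_oracle <= 0.05)

  # significant sites form a prefix of the |t| ranking
  sig_ranks <- which(res$table$significant[order(-abs(res$table$t))])
  if (length(sig_ranks) > 0) {
    expect_identical(sig_ranks, seq_along(sig_ranks))
  }
})

test_that("random permutation mode folds back to exhaustive when saturated", {
  set.seed(29)
  grid <- matrix(rnorm(40 * 6), 40, 6)
  m <- tiny_matrix(grid, groups = rep(c("A", "B"), each = 3),
                   scale = "log2")
  exh <- perm_fdr(m, seed = 1)
  # force random mode, but ask for >= all distinct labelings
  sat <- perm_fdr(m, n_perm = 100, exhaustive_below = 5, seed = 1)
  expect_identical(sat$mode, "exhaustive")
  expect_match(sat$log, "enumerating all", all = FALSE)
  expect_equal(sat$table$fdr, exh$table$fdr)

  # genuine random mode runs and is seed-reproducible
  rnd1 <- perm_fdr(m, n_perm = 15, exhaustive_below = 5, seed = 4)
  rnd2 <- perm_fdr(m, n_perm = 15, exhaustive_below = 5, seed = 4)
  expect_identical(rnd1$mode, "random")
  expect_equal(rnd1$table$fdr, rnd2$table$fdr)
})

test_that("relabeling the groups flips signs but not inference", {
  set.seed(31)
  grid <- matrix(rnorm(50 * 9), 50, 9)
  grid[1:4, 5:9] <- grid[1:4, 5:9] + 4
  groups <- rep(c("A", "B"), c(4, 5))
  m1 <- tiny_matrix(grid, groups = groups, scale = "log2")
  m2 <- tiny_matrix(grid, groups = c("B", "A")[match(groups, c("A", "B"))],
                    scale = "log2")
  r1 <- perm_fdr(m1, seed = 2)
  r2 <- perm_fdr(m2, seed = 2)
  # renaming the groups flips every difference's sign (groups are reported
  # alphabetically) and leaves |t|, p and the significant set unchanged
  expect_equal(r2$table$diff, -r1$table$diff)
  expect_equal(abs(r2$table$t), abs(r1$table$t))
  expect_equal(r2$table$p, r1$table$p)
  expect_identical(r2$table$significant, r1$table$significant)
  expect_setequal(r2$higher_in$B, r1$higher_in$A)
  expect_setequal(r2$higher_in$A, r1$higher_in$B)
})

test_that("null data yields (almost) no calls; a separated site is first", {
  set.seed(37)
  null_grid <- matrix(rnorm(500 * 9), 500, 9)
  m <- tiny_matrix(null_grid, groups = rep(c("A", "B"), c(4, 5)),
                   scale = "log2")
  r <- perm_fdr(m, seed = 3)
  expect_lte(sum(r$table$significant), 2)

  grid <- matrix(rnorm(1000 * 9), 1000, 9)
  grid[1, 1:4] <- grid[1, 1:4] + 10
  m2 <- tiny_matrix(grid, groups = rep(c("A", "B"), c(4, 5)),
                    scale = "log2")
  r2 <- perm_fdr(m2, seed = 3)
  expect_true(r2$table$significant[1])
  expect_equal(which.max(abs(r2$table$t)), 1L)
  expect_identical(r2$table$direction[1], "A")

  expect_error(perm_fdr(tiny_matrix(rbind(c(1, NA, 2, 3)),
                                    groups = rep(c("A", "B"), each = 2),
                                    scale = "log2"), seed = 1),
               "complete")
  expect_error(perm_fdr(tiny_matrix(rbind(c(1, 2, 3)),
                                    groups = c("A", "A", "B"),
                                    scale = "log2"), seed = 1),
               "at least 2")
})
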