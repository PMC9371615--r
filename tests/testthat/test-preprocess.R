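test_that("log2 transform maps values and preserves missingness", {
  m <- tiny_matrix(rbind(c(8, 1), c(NA, 4)))
  lm <- log2_transform(m)
  expect_equal(unname(lm$intensity[1, ]), c(3, 0))
  expect_true(is.na(lm$intensity[2, 1]))
  expect_identical(is.na(lm$intensity), is.na(m$intensity))
  expect_error(log2_transform(lm), "log2")
})

test_that("median normalization centers each column's present values", {
  grid <- rbind(c(1, 2), c(2, NA), c(3, 4))
  m <- tiny_matrix(grid, scale = "log2")
  norm <- median_normalize(m)
  expect_equal(unname(norm$intensity[, 1]), c(-1, 0, 1))
  expect_equal(unname(norm$intensity[, 2]), c(-1, NA, 1))
  # postcondition: per-column present-value median is 0
  meds <- apply(norm$intensity, 2, stats::median, na.rm = TRUE)
  expect_equal(unname(meds), c(0, 0))
  # idempotence
  expect_equal(median_normalize(norm)$intensity, norm$intensity)
  # missing pattern untouched
  expect_identical(is.na(norm$intensity), is.na(m$intensity))

  all_na <- tiny_matrix(rbind(c(1, NA), c(2, NA)), scale = "log2")
  expect_error(median_normalize(all_na), "s2")
})

test_that("detection counts are per group over included samples", {
  grid <- rbind(c(5, NA, 6, NA, NA, NA, NA, NA, NA),  # A: 2, B: 0
                rep(NA_real_, 9),                      # 0, 0
                rep(1, 9))                             # 4, 5
  m <- tiny_matrix(grid, groups = rep(c("A", "B"), c(4, 5)))
  det <- detection_matrix(m)
  expect_equal(unname(det$counts[1, ]), c(2L, 0L))
  expect_equal(unname(det$counts[2, ]), c(0L, 0L))
  expect_equal(unname(det$counts[3, ]), c(4L, 5L))
  expect_true(all(det$counts[, "A"] <= 4 & det$counts[, "B"] <= 5))
})

test_that("min-valid filter keeps a site iff one group reaches the minimum", {
  present <- function(a, b) {
    c(ifelse(seq_len(4) <= a, 1, NA), ifelse(seq_len(5) <= b, 1, NA))
  }
  grid <- rbind(present(3, 0), present(2, 2), present(0, 5), present(2, 3))
  m <- tiny_matrix(grid, groups = rep(c("A", "B"), c(4, 5)),
                   scale = "log2")
  f <- filter_min_valid(m, min_valid = 3)
  expect_identical(f$matrix$sites$protein, c("P1", "P3", "P4"))
  expect_identical(f$dropped$site, "P2_2_S_1")
  # partition: retained + dropped = input, no overlap
  expect_setequal(c(site_key(f$matrix), f$dropped$site), site_key(m))
  # filtering does not change which cells are present
  expect_identical(is.na(f$matrix$intensity),
                   is.na(m$intensity[c(1, 3, 4), , drop = FALSE]))
  expect_error(filter_min_valid(m, min_valid = 6), "configuration")
})

test_that("sample QC reports mean pairwise correlations and flags", {
  a <- c(1, 2, 3, 4, 5)
  m <- tiny_matrix(cbind(a, a, -a), groups = c("A", "A", "B"),
                   scale = "log2")
  qc <- sample_qc(m)
  expect_equal(qc$pairwise["s1", "s2"], 1)
  expect_equal(qc$pairwise["s1", "s3"], -1)
  expect_equal(qc$pairwise["s2", "s1"], qc$pairwise["s1", "s2"])
  expect_true(qc$table$flagged[qc$table$sample_id == "s3"])

  # hand-evaluated product-moment correlation
  m2 <- tiny_matrix(cbind(c(1, 2, 3), c(1, 2, 4), c(2, 2, 2.5)),
                    scale = "log2")
  qc2 <- sample_qc(m2)
  expect_equal(qc2$pairwise["s1", "s2"], 0.9820, tolerance = 1e-4)

  # pairs with <3 shared present values are recorded, not used
  grid <- cbind(c(1, 2, 3, 4), c(1.1, 2, 3, 4), c(NA, NA, 3, 4))
  qc3 <- sample_qc(tiny_matrix(grid, scale = "log2"))
  expect_equal(nrow(qc3$incomputable_pairs), 2L)
  expect_equal(qc3$table$n_pairs[1], 1L)

  expect_error(sample_qc(tiny_matrix(cbind(a, a), scale = "log2")),
               "3 included samples")
})

test_that("QC flags a corrupted sample; exclusion is explicit", {
  sim <- simulate_phospho_dataset(n_sites = 400, seed = 301)
  m <- log2_transform(sim$matrix)
  j <- which(m$samples$sample_id == "DMSO_1")
  obs <- which(!is.na(m$intensity[, j]))
  set.seed(99)
  m$intensity[obs, j] <- sample(m$intensity[obs, j])
  qc <- sample_qc(m)
  expect_true(qc$table$flagged[qc$table$sample_id == "DMSO_1"])
  expect_false(any(qc$table$flagged[qc$table$sample_id != "DMSO_1"]))
  m2 <- exclude_samples(m, "DMSO_1")
  expect_false("DMSO_1" %in% m2$samples$sample_id)
  expect_equal(ncol(m2$intensity), 8L)
  expect_error(exclude_samples(m, "nope"), "nope")
})
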