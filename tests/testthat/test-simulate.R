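test_that("truth classes follow the requested fractions", {
  sim <- simulate_phospho_dataset(n_sites = 200, effect_fraction = 0,
                                  presence_absence_fraction = 0, seed = 1)
  expect_true(all(sim$truth$class == "null"))
  expect_true(all(sim$truth$effect == 0))

  sim2 <- simulate_phospho_dataset(n_sites = 200, effect_fraction = 0.1,
                                   presence_absence_fraction = 0.05,
                                   seed = 1)
  expect_equal(sum(sim2$truth$class == "shifted"), 20L)
  expect_equal(sum(sim2$truth$class == "presence_absence"), 10L)
  expect_true(all(sim2$truth$effect[sim2$truth$class == "null"] == 0))
  expect_true(all(abs(sim2$truth$effect[sim2$truth$class == "shifted"])
                  == 1))
  # dialect matches the reader's expectations
  expect_s3_class(sim2$matrix, "site_matrix")
  expect_equal(unname(sim2$matrix$samples$group[1]), "DMSO")
  expect_error(simulate_phospho_dataset(n_sites = 10, effect_fraction = 0.9,
                                        presence_absence_fraction = 0.3,
                                        seed = 1),
               "configuration")
})

test_that("identical parameters and seed give byte-identical tables", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  s1 <- simulate_phospho_dataset(n_sites = 150, seed = 77, n_terms = 10)
  s2 <- simulate_phospho_dataset(n_sites = 150, seed = 77, n_terms = 10)
  write_site_table(s1$matrix, f1)
  write_site_table(s2$matrix, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- simulate_phospho_dataset(n_sites = 150, seed = 78, n_terms = 10)
  expect_false(identical(s1$matrix$intensity, s3$matrix$intensity))
})

test_that("a vanishing detection scale becomes a hard threshold", {
  sim <- simulate_phospho_dataset(n_sites = 300, detection_scale = 1e-9,
                                  detection_midpoint = 23,
                                  presence_absence_fraction = 0, seed = 5)
  detected <- !is.na(sim$matrix$intensity)
  expect_identical(detected, sim$latent > 23)
})

test_that("detection rate rises with simulated abundance", {
  sim <- simulate_phospho_dataset(n_sites = 2000, seed = 9,
                                  presence_absence_fraction = 0)
  x <- as.vector(sim$latent)
  detected <- as.vector(!is.na(sim$matrix$intensity))
  bins <- cut(x, breaks = quantile(x, probs = seq(0, 1, 0.1)),
              include.lowest = TRUE)
  rate <- tapply(detected, bins, mean)
  expect_true(all(diff(rate) >= -0.02))  # monotone up to binning noise
  expect_lt(rate[[1]], 0.5)
  expect_gt(rate[[10]], 0.99)
})

test_that("recovery metrics equal explicit set arithmetic", {
  sim <- simulate_phospho_dataset(n_sites = 60, effect_fraction = 0.2,
                                  presence_absence_fraction = 0.1,
                                  seed = 21)
  truth <- sim$truth
  set.seed(22)
  called <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.2, 0.8))
  fake_diff <- structure(
    list(table = data.frame(site = truth$site, significant = called)),
    class = "perm_fdr")
  ev <- evaluate_calls(fake_diff, NULL, truth)
  shifted <- truth$site[truth$class == "shifted"]
  nulls <- truth$site[truth$class == "null"]
  called_sites <- truth$site[called]
  expect_equal(ev$power,
               length(intersect(called_sites, shifted)) / length(shifted))
  expect_equal(ev$fdp,
               length(intersect(called_sites, nulls)) /
                 length(called_sites))
  expect_equal(ev$n_called, length(called_sites))

  # zero calls: power 0, FDP 0 by convention
  none <- fake_diff
  none$table$significant <- FALSE
  ev0 <- evaluate_calls(none, NULL, truth)
  expect_equal(ev0$power, 0)
  expect_equal(ev0$fdp, 0)

  # perfect calls: power 1, FDP 0
  perfect <- fake_diff
  perfect$table$significant <- truth$class == "shifted"
  ev1 <- evaluate_calls(perfect, NULL, truth)
  expect_equal(ev1$power, 1)
  expect_equal(ev1$fdp, 0)

  # key mismatch is an error
  bad <- fake_diff
  bad$table$site[1] <- "NOPE_1_S_1"
  expect_error(evaluate_calls(bad, NULL, truth), "align")
})

test_that("presence/absence sites are recovered by the detection rule", {
  sim <- simulate_phospho_dataset(n_sites = 800, effect_fraction = 0,
                                  presence_absence_fraction = 0.1,
                                  seed = 33)
  cl <- classify_sites(detection_matrix(sim$matrix))
  ev <- evaluate_calls(NULL, cl, sim$truth)
  expect_gt(ev$pa_sensitivity, 0.5)
  expect_gt(ev$pa_specificity, 0.95)
})
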