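test_that("peak ratio follows the C/(C+T) formula", {
  expect_equal(peak_ratio(50, 50), 50)
  expect_equal(peak_ratio(0, 120), 0)
  expect_equal(peak_ratio(84, 16), 84)
  expect_true(is.na(peak_ratio(0, 0)))
  expect_error(peak_ratio(-1, 5))
})

test_that("peak ratio is strictly increasing in the primary height", {
  h <- seq(0, 200, by = 10)
  r <- peak_ratio(h, 50)
  expect_true(all(diff(r) > 0))
})

test_that("conversion efficiency is one minus the mean control ratio", {
  expect_equal(estimate_conversion_efficiency(c(0, 0, 0)), 1)
  expect_equal(estimate_conversion_efficiency(c(5, 5, 5)), 0.95)
  expect_equal(estimate_conversion_efficiency(c(0, 5, 10)), 0.95)
  expect_true(is.na(estimate_conversion_efficiency(c(1, 2))))
  expect_true(is.na(estimate_conversion_efficiency(c(1, NA, NA))))
})

test_that("conversion correction subtracts the residual and rescales", {
  expect_equal(correct_conversion(37, 1), 37)
  expect_equal(correct_conversion(5, 0.95), 0)
  expect_equal(correct_conversion(50, 0.90), 100 * (0.5 - 0.1) / 0.9)
  expect_equal(correct_conversion(2, 0.95), 0)   # below residual floors at 0
  expect_equal(correct_conversion(100, 0.95), 100)
  expect_error(correct_conversion(50, 0), "efficiency")
})

test_that("correction never increases values and stays in [0, 100]", {
  m <- seq(0, 100, by = 2.5)
  for (eff in c(0.9, 0.95, 1)) {
    out <- correct_conversion(m, eff)
    expect_true(all(out <= m + 1e-12))
    expect_true(all(out >= 0 & out <= 100))
  }
})

test_that("noise-free traces invert exactly, with and without residual", {
  q <- fixture_quantified(c(30, 0, 100, 62.5), sigma = 0, efficiency = 1)
  calls <- q$profile$calls
  expect_equal(calls$m_raw[match(q$cpg_ids, calls$site_id)],
               unname(q$truth[q$cpg_ids]))

  q2 <- fixture_quantified(c(30, 0, 100, 62.5), sigma = 0, efficiency = 0.95)
  expect_equal(q2$profile$conversion_efficiency, 0.95)
  calls2 <- q2$profile$calls
  expect_equal(calls2$m_corrected[match(q2$cpg_ids, calls2$site_id)],
               unname(q2$truth[q2$cpg_ids]))
})

test_that("reverse-direction traces quantify identically after flipping", {
  q <- fixture_quantified(c(30, 0, 100, 62.5), sigma = 0, efficiency = 0.95,
                          strand = "reverse")
  calls <- q$profile$calls
  expect_equal(calls$m_corrected[match(q$cpg_ids, calls$site_id)],
               unname(q$truth[q$cpg_ids]))
})

test_that("estimated efficiency recovers the simulated value within a point", {
  errs <- purrr::map_dbl(1:10, function(seed) {
    q <- fixture_quantified(c(40, 20, 80, 60), sigma = 0.02,
                            efficiency = 0.95, seed = seed)
    q$profile$conversion_efficiency - 0.95
  })
  expect_true(all(abs(errs) < 0.01))
})

test_that("noisy quantification stays within two points on average", {
  err <- purrr::map(1:20, function(seed) {
    truth <- withr::with_seed(seed + 100, stats::runif(4, 0, 100))
    q <- fixture_quantified(truth, sigma = 0.02, efficiency = 0.95, seed = seed)
    calls <- q$profile$calls
    abs(calls$m_corrected[match(q$cpg_ids, calls$site_id)] - unname(q$truth[q$cpg_ids]))
  })
  expect_lt(mean(unlist(err)), 2)
})

test_that("silent calls are flagged as missing, not zero", {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  truth <- setNames(rep(0, nrow(panel)), panel$site_id)
  chrom <- withr::with_seed(1, simulate_trace(truth, reg, panel, "s",
                                              sigma = 0, efficiency = 1))
  # kill the C and T channels at the first CpG call
  idx <- panel$offset[panel$label == "CpG-1"] + 1L
  chrom$calls$H_C[idx] <- 0
  chrom$calls$H_T[idx] <- 0
  prof <- quantify_sample(chrom, panel, converted_reference(reg, panel),
                          min_overlap = 10L)
  row <- prof$calls[prof$calls$label == "CpG-1", ]
  expect_true(is.na(row$m_raw))
  expect_equal(row$qc_flags, "no-signal")
})

test_that("uninformative-site filter drops exactly the near-zero block", {
  mat <- fixture_matrix(n_per_group = 20)
  low_sites <- names(mat)[3:5]
  for (sc in low_sites) mat[[sc]] <- stats::runif(nrow(mat), 0, 3)
  res <- filter_uninformative_sites(mat, threshold_pct = 5, min_fraction = 0.95)
  expect_setequal(res$dropped$site_id, low_sites)
  expect_false(any(low_sites %in% names(res$matrix)))

  keep_all <- filter_uninformative_sites(fixture_matrix(n_per_group = 10))
  expect_equal(nrow(keep_all$dropped), 0L)
})

test_that("a site low in only one group is kept", {
  mat <- fixture_matrix(n_per_group = 20)
  sc <- names(mat)[3]
  mat[[sc]][mat$group == "A"] <- 1
  res <- filter_uninformative_sites(mat)
  expect_false(sc %in% res$dropped$site_id)
})

test_that("CpH discovery thresholds on the maximum group median", {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  cph <- panel$site_id[panel$kind == "CpH"]
  mat <- fixture_matrix(n_per_group = 15)
  for (sc in cph) mat[[sc]] <- 2                     # background residual
  mat[[cph[1]]][mat$group == "B"] <- 20              # elevated in one group
  disc <- discover_noncpg(mat, panel)
  expect_true(disc$discovered[disc$site_id == cph[1]])
  expect_false(any(disc$discovered[disc$site_id != cph[1]]))
})

test_that("cohort quantification excludes corrupt traces and keeps going", {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  truth <- setNames(rep(20, nrow(panel)), panel$site_id)
  truth[panel$kind == "CpH"] <- 0
  chroms <- purrr::map(1:4, function(i) {
    withr::with_seed(i, simulate_trace(truth, reg, panel, paste0("s", i),
                                       sigma = 0.02, efficiency = 0.97))
  })
  # corrupt one trace's basecalls so it cannot align (ref has no plain C)
  chroms[[3]]$calls$base <- rep("C", nrow(chroms[[3]]$calls))
  res <- quantify_cohort(chroms, reg, panel, min_identity = 0.9)
  expect_equal(sum(res$qc$status == "excluded"), 1L)
  expect_equal(res$qc$sample_id[res$qc$status == "excluded"], "s3")
  expect_equal(nrow(res$matrix), 3L)
  expect_true(all(c("s1", "s2", "s4") %in% res$matrix$sample_id))
})
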