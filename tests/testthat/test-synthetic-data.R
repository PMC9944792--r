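test_that("bounded marginal fits reproduce printed quantile triplets", {
  sym <- fit_bounded_distribution(50, 25, 75)
  expect_equal(sym$a, sym$b, tolerance = 0.05)
  expect_equal(unname(sym$achieved), c(25, 50, 75), tolerance = 0.1)

  top <- fit_bounded_distribution(100, 87, 100)
  expect_gte(top$p100, 0.5)
  expect_equal(unname(top$achieved[["q1"]]), 87, tolerance = 1)

  mid <- fit_bounded_distribution(50, 40, 55)
  expect_true(max(abs(mid$achieved - mid$target)) < 1)

  low <- fit_bounded_distribution(0, 0, 10)
  expect_gte(low$p0, 0.5)
  expect_equal(unname(low$achieved[["q3"]]), 10, tolerance = 1)

  expect_error(fit_bounded_distribution(50, 60, 70), "infeasible")
  expect_error(fit_bounded_distribution(105, 90, 110), "infeasible")
})

test_that("simulated draws match fitted quantiles closely", {
  targets <- list(c(50, 40, 55), c(10, 0, 17), c(100, 86, 100), c(26, 21, 33))
  for (tg in targets) {
    d <- fit_bounded_distribution(tg[1], tg[2], tg[3])
    x <- withr::with_seed(8, rsitedist(5000, d))
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    expect_true(all(abs(q - c(tg[2], tg[1], tg[3])) < 1.5),
                label = paste("marginal", paste(tg, collapse = "/")))
  }
})

test_that("Spearman-Pearson calibration uses the Gaussian-copula form", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1)
  expect_equal(spearman_to_pearson(0.5), 2 * sin(pi * 0.5 / 6))
  expect_equal(spearman_to_pearson(-1), -1)
  expect_error(spearman_to_pearson(1.2))
})

test_that("simulated cohorts have the requested sizes and structure", {
  panel <- site_panel(synthetic_reference()$regions)
  specs <- snca_site_specs(panel)
  co <- simulate_cohort(cohort_spec(), specs, snca_correlation_targets(),
                        seed = 5)
  expect_equal(nrow(co$matrix), 82 + 24 + 50)
  expect_equal(as.vector(table(co$design$group)[c("PD", "MSA", "control")]),
               c(82L, 24L, 50L))
  expect_true(all(co$design$sample_id == co$matrix$sample_id))
  site_cols <- setdiff(names(co$matrix), c("sample_id", "group"))
  vals <- unlist(co$matrix[site_cols])
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("cohort simulation is deterministic under a fixed seed", {
  panel <- site_panel(synthetic_reference()$regions)
  specs <- snca_site_specs(panel)
  a <- simulate_cohort(cohort_spec(c(PD = 10L, MSA = 10L, control = 10L)),
                       specs, snca_correlation_targets(), seed = 123)
  b <- simulate_cohort(cohort_spec(c(PD = 10L, MSA = 10L, control = 10L)),
                       specs, snca_correlation_targets(), seed = 123)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$design, b$design)
})

test_that("design invariants hold: onset + duration = age, controls blank", {
  panel <- site_panel(synthetic_reference()$regions)
  specs <- snca_site_specs(panel)
  co <- simulate_cohort(cohort_spec(), specs, seed = 9)
  d <- co$design
  pats <- d[d$group != "control", ]
  expect_equal(pats$age, pats$age_at_onset + pats$disease_duration)
  expect_true(all(pats$age_at_onset + pats$disease_duration <= pats$age + 1))
  ctrl <- d[d$group == "control", ]
  expect_true(all(is.na(ctrl$age_at_onset)))
  expect_true(all(is.na(ctrl$disease_duration)))
  expect_true(all(!is.na(ctrl$age)))
  expect_true(all(d$hoehn_yahr[d$group != "control"] %in% 1:4))
})

test_that("copula recovery at large n hits targets without leakage", {
  # single large synthetic group: one injected correlation, one null pair
  dist <- fit_bounded_distribution(30, 22, 38)
  spec <- cohort_spec(c(PD = 5000L, MSA = 1L, control = 1L))
  site_specs <- tidyr::crossing(
    tibble::tibble(site_id = c("intron1:CpG-40", "intron1:CpG-45")),
    tibble::tibble(group = c("PD", "MSA", "control"))
  )
  site_specs$dist <- list(dist)
  co <- simulate_cohort(
    spec, site_specs,
    correlations = tibble::tibble(site_id = "intron1:CpG-40",
                                  covariate = "age_at_onset",
                                  rho = 0.56, group = "PD"),
    seed = 77
  )
  pd <- co$matrix[co$matrix$group == "PD", ]
  des <- co$design[co$design$group == "PD", ]
  r_hit <- cor(pd$`intron1:CpG-40`, des$age_at_onset, method = "spearman")
  r_null <- cor(pd$`intron1:CpG-45`, des$age_at_onset, method = "spearman")
  expect_equal(r_hit, 0.56, tolerance = 0.05)
  expect_lt(abs(r_null), 0.05)
})

test_that("independent sites stay uncorrelated across replicates", {
  dist <- fit_bounded_distribution(30, 22, 38)
  spec <- cohort_spec(c(PD = 100L, MSA = 1L, control = 1L))
  site_specs <- tidyr::crossing(
    tibble::tibble(site_id = c("s:CpG-1", "s:CpG-2")),
    tibble::tibble(group = c("PD", "MSA", "control"))
  )
  site_specs$dist <- list(dist)
  rs <- purrr::map_dbl(1:50, function(s) {
    co <- simulate_cohort(spec, site_specs, seed = s)
    pd <- co$matrix[co$matrix$group == "PD", ]
    cor(pd$`s:CpG-1`, pd$`s:CpG-2`, method = "spearman")
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("trace simulation is the generative inverse of the peak ratio", {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  truth <- setNames(rep(0, nrow(panel)), panel$site_id)
  cpgs <- panel[panel$kind == "CpG", ]
  truth[cpgs$site_id] <- c(100, 0, 50, 25)
  ch <- withr::with_seed(1, simulate_trace(truth, reg, panel, "s", sigma = 0,
                                           efficiency = 1))
  at <- function(lab) ch$calls[cpgs$offset[cpgs$label == lab] + 1, ]
  expect_equal(at("CpG-1")$H_T, 0)
  expect_equal(at("CpG-2")$H_C, 0)
  expect_equal(peak_ratio(at("CpG-3")$H_C, at("CpG-3")$H_T), 50)
  # CpH controls carry only the residual signal
  ch2 <- withr::with_seed(1, simulate_trace(truth, reg, panel, "s", sigma = 0,
                                            efficiency = 0.9))
  cph1 <- panel[panel$kind == "CpH", ][1, ]
  r <- ch2$calls[cph1$offset + 1, ]
  expect_equal(peak_ratio(r$H_C, r$H_T), 10, tolerance = 1e-9)
})

test_that("the study scenario reproduces the documented site geometry", {
  ref <- synthetic_reference()
  panel <- site_panel(ref$regions)
  counts <- table(panel$region, panel$kind)
  expect_equal(counts["promoter", "CpG"], 9)
  expect_equal(counts["intron1", "CpG"], 48)
  expect_equal(counts["intron2", "CpG"], 2)
  # the adjacent CCC run: 4I/4J/4K at consecutive offsets, contexts CC,CC,CA
  ccc <- panel[panel$site_id %in% paste0("promoter:CpG-4", c("I", "J", "K")), ]
  expect_equal(diff(ccc$offset), c(1L, 1L))
  expect_equal(ccc$context, c("CC", "CC", "CA"))
  # 7A sits three bases downstream of CpG-7 (descending genome coordinates)
  p7 <- panel[panel$site_id == "promoter:CpG-7", ]
  p7a <- panel[panel$site_id == "promoter:CpG-7A", ]
  expect_equal(p7a$offset - p7$offset, 3L)
  expect_equal(p7$genomic_pos - p7a$genomic_pos, 3L)
  # 28 elevated promoter CpH candidates in the marginal table
  specs <- snca_site_specs(panel)
  elevated <- specs[specs$median > 5 & grepl("^promoter:", specs$site_id) &
                      specs$site_id %in% panel$site_id[panel$kind == "CpH"], ]
  expect_equal(dplyr::n_distinct(elevated$site_id), 28L)
})

test_that("scenario writing is deterministic and complete", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sizes <- c(PD = 3L, MSA = 3L, control = 3L)
  write_scenario(snca_scenario(seed = 4, group_sizes = sizes), dir1)
  write_scenario(snca_scenario(seed = 4, group_sizes = sizes), dir2)
  files <- c("reference.fa", "regions.bed", "panel.csv", "design.csv",
             "truth_matrix.csv", "truth.json")
  for (f in files) {
    expect_identical(readr::read_file(file.path(dir1, f)),
                     readr::read_file(file.path(dir2, f)),
                     label = f)
  }
  traces1 <- sort(list.files(file.path(dir1, "traces")))
  expect_length(traces1, 9 * 3)
  expect_identical(
    readr::read_file(file.path(dir1, "traces", traces1[1])),
    readr::read_file(file.path(dir2, "traces", traces1[1]))
  )
  expect_error(write_scenario(snca_scenario(seed = 4, group_sizes = sizes),
                              dir1),
               "not empty")
})
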