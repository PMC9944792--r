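# full-enumeration two-sided Mann-Whitney oracle (no ties)
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  combos <- utils::combn(length(pooled), nx)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  })
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("median and quartiles use type-7 interpolation", {
  s <- median_iqr(c(1, 2, 3, 4))
  expect_equal(c(s$q1, s$median, s$q3), c(1.75, 2.5, 3.25))
  s1 <- median_iqr(5)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(5, 5, 5))
  s2 <- median_iqr(rep(7.3, 9))
  expect_equal(c(s2$q1, s2$median, s2$q3), rep(7.3, 3))
  expect_true(is.na(median_iqr(c(NA_real_, NA_real_))$median))
})

test_that("Mann-Whitney matches hand-enumerated exact cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2/20 arrangements as extreme
  expect_equal(res$method, "exact")

  same <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(same$p_value, 1)
})

test_that("Mann-Whitney exact p equals the full-permutation oracle", {
  withr::with_seed(7, {
    for (i in 1:15) {
      nx <- sample(2:6, 1)
      ny <- sample(2:6, 1)
      v <- sample(1000, nx + ny)  # distinct -> no ties
      x <- v[seq_len(nx)]
      y <- v[-seq_len(nx)]
      res <- mann_whitney_u(x, y)
      expect_equal(res$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney is symmetric under group swap", {
  withr::with_seed(3, {
    x <- runif(8)
    y <- runif(5)
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_equal(a$statistic, 8 * 5 - b$statistic)
    expect_equal(a$p_value, b$p_value)
  })
})

test_that("Kruskal-Wallis matches the rank-sum formula and edge cases", {
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  withr::with_seed(11, {
    groups <- list(runif(6), runif(5), runif(7))
    res <- kruskal_wallis(groups)
    # independent rank-sum arithmetic (no ties)
    values <- unlist(groups)
    r <- rank(values)
    n <- length(values)
    idx <- rep(seq_along(groups), lengths(groups))
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
    expect_equal(res$statistic, h, tolerance = 1e-10)
    expect_equal(res$p_value, stats::pchisq(h, 2, lower.tail = FALSE))
  })
})

test_that("two-group Kruskal-Wallis approximates the Mann-Whitney p", {
  withr::with_seed(5, {
    x <- rnorm(40)
    y <- rnorm(40, 0.5)
    kw <- kruskal_wallis(list(x, y))
    mw <- mann_whitney_u(x, y)   # n_x * n_y > 400 -> normal approximation
    expect_equal(kw$p_value, mw$p_value, tolerance = 0.05)
  })
})

test_that("Spearman correlation classifies strength bands", {
  inc <- spearman_rho(1:10, (1:10)^2)
  expect_equal(inc$rho, 1)
  expect_equal(inc$strength, "very strong")
  dec <- spearman_rho(1:10, -(1:10))
  expect_equal(dec$rho, -1)

  # rho engineered near 0.52: moderate and retained
  withr::with_seed(19, {
    repeat {
      x <- rnorm(60)
      y <- 0.55 * x + rnorm(60, 0, 0.85)
      r <- cor(x, y, method = "spearman")
      if (r > 0.5 && r < 0.6) break
    }
    res <- spearman_rho(x, y)
    expect_equal(res$strength, "moderate")
    expect_true(res$retained)
  })
  expect_true(is.na(spearman_rho(rep(1, 6), 1:6)$rho))
  expect_true(is.na(spearman_rho(1:4, 1:4)$rho))  # below minimum n
})

test_that("Spearman is invariant under monotone transforms", {
  withr::with_seed(2, {
    x <- runif(30)
    y <- runif(30)
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(3 * x), y)$rho, base$rho)
    expect_equal(spearman_rho(x, rank(y))$rho, base$rho)
  })
})

test_that("Bonferroni thresholds and their truncated display forms", {
  expect_equal(bonferroni_alpha(2), 0.025)
  expect_equal(bonferroni_alpha(7), 0.05 / 7)
  expect_equal(bonferroni_alpha(28), 0.05 / 28)
  expect_equal(format_alpha_truncated(bonferroni_alpha(7)), "0.007")
  expect_equal(format_alpha_truncated(bonferroni_alpha(28)), "0.0017")
  expect_equal(format_alpha_truncated(bonferroni_alpha(2)), "0.025")
  expect_error(bonferroni_alpha(0))
})

test_that("group comparisons honour families and the strict threshold", {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  shifted <- panel$site_id[panel$kind == "CpG"][1]
  mat <- fixture_matrix(n_per_group = 25, shift_sites = shifted, shift = 30)
  res <- run_group_comparisons(mat, panel)
  tbl <- tidy(res)
  expect_equal(sort(unique(tbl$family_size[tbl$kind == "CpG"])), 4L)
  expect_equal(sort(unique(tbl$family_size[tbl$kind == "CpH"])), 3L)
  expect_true(tbl$significant[tbl$site_id == shifted])
  expect_false(any(tbl$significant[tbl$site_id != shifted]))
  expect_true(all(tbl$significant == (tbl$p_value < tbl$alpha_adjusted)))

  g <- glance(res)
  expect_equal(g$n_tests, nrow(tbl))
  expect_equal(g$n_significant, 1L)
})

test_that("a p-value above the family threshold is not significant", {
  # emulate the agonist-subgroup case: p = 0.0028 in a 28-test family
  expect_false(0.0028 < bonferroni_alpha(28))
  expect_true(0.000221 < bonferroni_alpha(28))
  # boundary: p exactly at the threshold is not significant
  expect_false(bonferroni_alpha(28) < bonferroni_alpha(28))
})

test_that("unknown group labels are rejected by name", {
  mat <- fixture_matrix(n_per_group = 5)
  panel <- site_panel(fixture_small_region())
  expect_error(run_group_comparisons(mat, panel, comparisons = list(c("A", "Z"))),
               "unknown group label.*Z")
})

test_that("correlation screen retains injected signal and skips small groups", {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  n <- 60
  withr::with_seed(31, {
    onset <- runif(n, 40, 70)
    mat <- tibble::tibble(
      sample_id = sprintf("p%02d", 1:n), group = "PD",
      age_at_onset = onset
    )
    for (sid in panel$site_id) mat[[sid]] <- runif(n, 10, 60)
    target <- panel$site_id[1]
    mat[[target]] <- 30 + 0.9 * (onset - 55) + rnorm(n, 0, 4)
  })
  res <- run_correlation_screen(mat, panel, covariates = "age_at_onset")
  tbl <- tidy(res)
  hit <- tbl[tbl$site_id == target, ]
  expect_true(hit$retained)
  expect_gt(hit$rho, 0.5)
  expect_false(any(tbl$retained[tbl$site_id != target]))

  small <- mat[1:4, ]
  expect_warning(run_correlation_screen(small, panel,
                                        covariates = "age_at_onset"),
                 "fewer than 5")
})
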