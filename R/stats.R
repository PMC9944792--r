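#' Median and interquartile range
#'
#' Group summaries follow the `median [Q1; Q3]` convention; quartiles use
#' linear interpolation between closest ranks (quantile type 7, the R
#' default). Other types can be selected since the original analysis
#' software's quantile rule is not documented.
#'
#' @param values Numeric vector (NAs dropped).
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return One-row tibble `n`, `median`, `q1`, `q3` (all NA when no
#'   non-missing values).
#' @examples
#' median_iqr(c(1, 2, 3, 4))  # 2.5 [1.75; 3.25]
#' @export
median_iqr <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(tibble(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = type))
  tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
}

#' Mann-Whitney U test (two-sided)
#'
#' Two-group comparison of methylation percentages. The p-value is exact
#' (full null enumeration of rank assignments) when there are no ties and
#' `n_x * n_y <= 400`; otherwise the tie-corrected normal approximation
#' without continuity correction is used. The U statistic counts (x, y)
#' pairs with x > y (plus half the ties), so swapping the groups maps U to
#' `n_x * n_y - U` with the same p-value.
#'
#' @param x,y Numeric vectors with at least 2 non-missing values each.
#' @return One-row tibble `n_x`, `n_y`, `statistic` (U), `p_value`,
#'   `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble(n_x = length(x), n_y = length(y), statistic = NA_real_,
                  p_value = NA_real_, method = NA_character_))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE, alternative = "two.sided")
  )
  tibble(
    n_x = length(x), n_y = length(y),
    statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
    method = if (exact) "exact" else "normal"
  )
}

#' Kruskal-Wallis rank test
#'
#' k-group comparison with tie correction; p from the chi-square reference
#' with k - 1 degrees of freedom. All-identical values give H = 0, p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups with >= 2 values).
#' @return One-row tibble `n_groups`, `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- purrr::map(groups, ~ .x[!is.na(.x)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2 || sum(lengths(groups) >= 2) < 2) {
    abort("kruskal_wallis needs at least 2 groups with at least 2 values")
  }
  values <- unlist(groups)
  if (length(unique(values)) == 1) {
    return(tibble(n_groups = length(groups), statistic = 0,
                  df = length(groups) - 1L, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(values, g)
  tibble(
    n_groups = length(groups), statistic = unname(kt$statistic),
    df = unname(kt$parameter), p_value = kt$p.value
  )
}

#' Spearman rank correlation with strength classification
#'
#' Rank correlation on average ranks, p-value from the t approximation.
#' The absolute correlation is classed with the conventional bands used in
#' the clinical screen: `< 0.3` negligible, `[0.3, 0.5)` weak (screened out:
#' `retained = FALSE`), `[0.5, 0.7)` moderate, `[0.7, 0.9)` strong,
#' `>= 0.9` very strong. Only moderate-or-stronger correlations are
#' retained.
#'
#' @param x,y Paired numeric vectors (>= 5 complete pairs).
#' @return One-row tibble `n`, `rho`, `p_value`, `strength`, `retained`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  empty <- tibble(n = length(x), rho = NA_real_, p_value = NA_real_,
                  strength = NA_character_, retained = NA)
  if (length(x) < 5) return(empty)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(empty)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  tibble(
    n = length(x), rho = rho, p_value = ct$p.value,
    strength = correlation_strength(rho), retained = abs(rho) >= 0.5
  )
}

correlation_strength <- function(rho) {
  a <- abs(rho)
  dplyr::case_when(
    a < 0.3 ~ "negligible",
    a < 0.5 ~ "weak",
    a < 0.7 ~ "moderate",
    a < 0.9 ~ "strong",
    TRUE ~ "very strong"
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' Per-family adjusted alpha, `alpha / family_size`, used at full precision
#' for all significance decisions.
#'
#' @param family_size Number of simultaneous tests (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return Adjusted threshold.
#' @examples
#' bonferroni_alpha(2)   # 0.025
#' bonferroni_alpha(28)  # 0.001785714...
#' @export
bonferroni_alpha <- function(family_size, alpha = 0.05) {
  if (length(family_size) != 1 || is.na(family_size) || family_size < 1) {
    abort("family_size must be a single integer >= 1")
  }
  alpha / family_size
}

#' Display form of an adjusted alpha
#'
#' Report rendering truncates (never rounds) the adjusted threshold: to 3
#' decimals when it is at least 0.005, to 4 decimals below that, matching
#' the printed style "0.025", "0.007", "0.0017". Decisions always use the
#' full-precision value from [bonferroni_alpha()].
#'
#' @param alpha_adjusted Adjusted threshold(s).
#' @return Character vector.
#' @export
format_alpha_truncated <- function(alpha_adjusted) {
  purrr::map_chr(alpha_adjusted, function(a) {
    digits <- if (a >= 0.005) 3L else 4L
    sprintf(paste0("%.", digits, "f"), floor(a * 10^digits) / 10^digits)
  })
}

#' Per-site group summaries
#'
#' @param matrix Methylation matrix with design columns.
#' @param panel Site panel (restricts and annotates columns).
#' @return Tibble `site_id`, `region`, `kind`, `label`, `group`, `n`,
#'   `median`, `q1`, `q3`.
#' @export
group_summaries <- function(matrix, panel) {
  cols <- intersect(panel$site_id, names(matrix))
  purrr::map_dfr(cols, function(sc) {
    matrix |>
      group_by(group = as.character(.data$group)) |>
      dplyr::group_modify(~ median_iqr(.x[[sc]])) |>
      ungroup() |>
      mutate(
        site_id = sc,
        region = panel$region[match(sc, panel$site_id)],
        kind = panel$kind[match(sc, panel$site_id)],
        label = panel$label[match(sc, panel$site_id)]
      )
  }) |>
    select("site_id", "region", "kind", "label", "group", "n",
           "median", "q1", "q3")
}

#' Run pairwise group comparisons with region-wise Bonferroni families
#'
#' One Mann-Whitney U test per site and group pair. Sites are partitioned
#' into families by region and site kind (e.g. promoter CpG, promoter CpH,
#' intron-1 CpG, intron-2 CpG); each comparison forms its own family, and a
#' result is significant when its p-value is strictly below the family's
#' full-precision adjusted alpha.
#'
#' @param matrix Methylation matrix including a `group` column.
#' @param panel Site panel (defines families via region + kind).
#' @param comparisons List of 2-vectors of group labels; default all
#'   pairwise combinations in first-appearance order.
#' @param alpha Family-wise level (default 0.05).
#' @return A `meth_comparisons` tibble: `site_id`, `region`, `kind`,
#'   `label`, `comparison`, `n_1`, `n_2`, `statistic`, `p_value`, `method`,
#'   `family`, `family_size`, `alpha_adjusted`, `significant`.
#' @export
run_group_comparisons <- function(matrix, panel, comparisons = NULL,
                                  alpha = 0.05) {
  if (!"group" %in% names(matrix)) abort("matrix must carry a 'group' column")
  groups_present <- unique(as.character(matrix$group))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(groups_present, 2, simplify = FALSE)
  }
  unknown <- setdiff(unlist(comparisons), groups_present)
  if (length(unknown) > 0) {
    abort(paste0("unknown group label(s): ", paste(unknown, collapse = ", ")))
  }
  cols <- intersect(panel$site_id, names(matrix))
  fam_tbl <- panel |>
    filter(.data$site_id %in% cols) |>
    mutate(family = paste0(.data$region, " ", .data$kind)) |>
    group_by(.data$family) |>
    mutate(family_size = dplyr::n()) |>
    ungroup()
  if (nrow(fam_tbl) == 0) {
    warn("no panel sites present in the matrix; nothing to compare")
    return(new_meth_comparisons(tibble()))
  }
  out <- purrr::map_dfr(comparisons, function(cmp) {
    purrr::map_dfr(seq_len(nrow(fam_tbl)), function(i) {
      row <- fam_tbl[i, ]
      x <- matrix[[row$site_id]][matrix$group == cmp[1]]
      y <- matrix[[row$site_id]][matrix$group == cmp[2]]
      mw <- mann_whitney_u(x, y)
      tibble(
        site_id = row$site_id, region = row$region, kind = row$kind,
        label = row$label, comparison = paste(cmp[1], "vs", cmp[2]),
        n_1 = mw$n_x, n_2 = mw$n_y, statistic = mw$statistic,
        p_value = mw$p_value, method = mw$method,
        family = row$family, family_size = row$family_size,
        alpha_adjusted = bonferroni_alpha(row$family_size, alpha)
      )
    })
  }) |>
    mutate(significant = !is.na(.data$p_value) &
             .data$p_value < .data$alpha_adjusted)
  new_meth_comparisons(out)
}

new_meth_comparisons <- function(x) {
  structure(x, class = c("meth_comparisons", class(x)))
}

#' Correlation screen between methylation and clinical covariates
#'
#' Per-group Spearman screen of every site against each clinical covariate
#' (age, age at onset, disease duration, UPDRS-III, Hoehn-Yahr stage).
#' Covariates defined only for patients (onset, duration) are screened in
#' the patient groups only; groups with fewer than 5 complete pairs are
#' skipped with a warning. Weak correlations (|rho| < 0.5) are reported but
#' not retained.
#'
#' @param matrix Methylation matrix with design columns.
#' @param panel Site panel.
#' @param covariates Character vector of design column names to screen.
#' @param groups Character vector of group labels to screen (default all).
#' @return A `meth_correlations` tibble: `group`, `covariate`, `site_id`,
#'   `region`, `kind`, `label`, `n`, `rho`, `p_value`, `strength`,
#'   `retained`.
#' @export
run_correlation_screen <- function(matrix, panel,
                                   covariates = c("age", "age_at_onset",
                                                  "disease_duration",
                                                  "updrs3", "hoehn_yahr"),
                                   groups = NULL) {
  if (!"group" %in% names(matrix)) abort("matrix must carry a 'group' column")
  covariates <- intersect(covariates, names(matrix))
  groups <- groups %||% unique(as.character(matrix$group))
  cols <- intersect(panel$site_id, names(matrix))
  out <- purrr::map_dfr(groups, function(g) {
    sub <- filter(matrix, as.character(.data$group) == g)
    purrr::map_dfr(covariates, function(cv) {
      cov_vals <- as.numeric(sub[[cv]])
      if (sum(!is.na(cov_vals)) < 5) {
        warn(paste0("group ", g, ": covariate ", cv,
                    " has fewer than 5 values; skipped"))
        return(tibble())
      }
      purrr::map_dfr(cols, function(sc) {
        sp <- spearman_rho(sub[[sc]], cov_vals)
        tibble(
          group = g, covariate = cv, site_id = sc,
          region = panel$region[match(sc, panel$site_id)],
          kind = panel$kind[match(sc, panel$site_id)],
          label = panel$label[match(sc, panel$site_id)],
          n = sp$n, rho = sp$rho, p_value = sp$p_value,
          strength = sp$strength, retained = sp$retained
        )
      })
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(
      group = character(), covariate = character(), site_id = character(),
      region = character(), kind = character(), label = character(),
      n = integer(), rho = numeric(), p_value = numeric(),
      strength = character(), retained = logical()
    )
  }
  structure(out, class = c("meth_correlations", class(out)))
}
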