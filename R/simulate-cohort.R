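#' Piecewise-linear quantile marginal for a clinical covariate
#'
#' Builds a monotone quantile function anchored at the printed median and
#' quartiles, with linearly extrapolated tails (1.5 x the adjacent
#' inter-quantile gap down to the 1st / up to the 99th percentile) clamped
#' to `[lower, upper]`. Being a monotone transform of the latent uniform,
#' it preserves Spearman correlations exactly while reproducing the
#' printed median and IQR.
#'
#' @param median,q1,q3 Printed summary values.
#' @param lower,upper Hard range limits.
#' @return Function mapping probabilities `u` to covariate values.
#' @export
quantile_marginal <- function(median, q1, q3, lower = -Inf, upper = Inf) {
  lo_tail <- max(q1 - 1.5 * (median - q1), lower)
  hi_tail <- min(q3 + 1.5 * (q3 - median), upper)
  p <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  q <- c(min(lo_tail, q1), q1, median, q3, max(hi_tail, q3))
  function(u) {
    u <- pmin(pmax(u, 0.01), 0.99)
    stats::approx(p, q, xout = u, ties = "ordered")$y
  }
}

#' Cohort specification for the three-group synucleinopathy study design
#'
#' Default study conditions: 82 Parkinson's disease (PD) patients, 24
#' multiple system atrophy (MSA) patients and 50 controls, with clinical
#' covariate summaries (age, age at onset, disease duration, UPDRS-III,
#' Hoehn-Yahr stage distribution, sex counts and antiparkinsonian treatment
#' prevalences) matching the published cohort description. Patient age is
#' onset + duration by construction.
#'
#' @param group_sizes Named integer vector with entries `PD`, `MSA`,
#'   `control`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(PD = 82L, MSA = 24L, control = 50L)) {
  stopifnot(all(c("PD", "MSA", "control") %in% names(group_sizes)),
            all(group_sizes > 0))
  structure(
    list(
      group_sizes = group_sizes,
      covariates = list(
        PD = list(
          age_at_onset = quantile_marginal(55, 48, 62, lower = 25, upper = 85),
          disease_duration = quantile_marginal(4, 3, 8, lower = 0.5, upper = 40),
          updrs3 = quantile_marginal(45, 22, 56, lower = 0, upper = 108),
          hoehn_yahr = c(`1` = 14, `2` = 26, `3` = 40, `4` = 2) / 82,
          sex = c(F = 41, M = 41) / 82,
          treatment = c(levodopa = 0.537, agonist = 0.488, amantadine = 0.378)
        ),
        MSA = list(
          age_at_onset = quantile_marginal(55, 52, 64, lower = 25, upper = 85),
          disease_duration = quantile_marginal(3.5, 2, 5.25, lower = 0.5, upper = 40),
          updrs3 = quantile_marginal(45, 22, 56, lower = 0, upper = 108),
          hoehn_yahr = c(`1` = 14, `2` = 26, `3` = 40, `4` = 2) / 82,
          sex = c(F = 17, M = 7) / 24,
          treatment = c(levodopa = 0.537, agonist = 0.488, amantadine = 0.378)
        ),
        control = list(
          age = quantile_marginal(58.5, 53, 62.75, lower = 30, upper = 90),
          sex = c(F = 31, M = 19) / 50
        )
      )
    ),
    class = "cohort_spec"
  )
}

#' Simulate a methylation cohort through a Gaussian copula
#'
#' Draws, per study group, a latent multivariate normal whose correlation
#' matrix encodes the requested site-covariate Spearman targets (calibrated
#' with [spearman_to_pearson()]), maps each site margin through its fitted
#' boundary-inflated beta quantile function and each covariate through its
#' monotone quantile marginal. Sites sharing a correlated covariate receive
#' a mutual latent correlation (`site_block_rho`) — neighbouring sites are
#' co-methylated in practice, and without it the latent matrix with several
#' sites tied to one covariate is not positive definite. Any remaining
#' non-PD matrix is repaired with [Matrix::nearPD()].
#'
#' @param spec A [cohort_spec()].
#' @param site_specs Tibble with columns `site_id`, `group` and a
#'   list-column `dist` of `site_dist` objects (one row per site x group).
#' @param correlations Tibble with columns `site_id`, `covariate`, `rho`,
#'   `group`; Spearman targets to inject.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param site_block_rho Latent correlation among sites sharing a target
#'   covariate (default 0.5).
#' @return List with `matrix` (tibble `sample_id`, `group` + site columns)
#'   and `design` (study design tibble).
#' @export
simulate_cohort <- function(spec, site_specs, correlations = NULL, seed = 1,
                            site_block_rho = 0.5) {
  set.seed(as.integer(seed))
  correlations <- correlations %||%
    tibble(site_id = character(), covariate = character(),
           rho = numeric(), group = character())
  stopifnot(all(abs(correlations$rho) < 1))
  groups <- names(spec$group_sizes)
  out <- purrr::map(groups, function(g) {
    n <- spec$group_sizes[[g]]
    gsites <- filter(site_specs, .data$group == g)
    cov_spec <- spec$covariates[[g]]
    latent_covs <- intersect(
      c("age", "age_at_onset", "disease_duration", "updrs3"), names(cov_spec)
    )
    vars <- c(gsites$site_id, latent_covs)
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    gcorr <- filter(correlations, .data$group == g)
    for (i in seq_len(nrow(gcorr))) {
      s <- gcorr$site_id[i]
      cv <- gcorr$covariate[i]
      if (!s %in% vars || !cv %in% vars) {
        abort(paste0("correlation target references unknown variable: ",
                     s, " / ", cv, " in group ", g))
      }
      R[s, cv] <- R[cv, s] <- spearman_to_pearson(gcorr$rho[i])
    }
    # co-methylation block among sites tied to the same covariate
    for (cv in unique(gcorr$covariate)) {
      ss <- gcorr$site_id[gcorr$covariate == cv]
      if (length(ss) > 1) {
        for (a in seq_along(ss)) for (b in seq_along(ss)) {
          if (a != b) R[ss[a], ss[b]] <- site_block_rho
        }
      }
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      npd <- Matrix::nearPD(R, corr = TRUE)
      if (!npd$converged) {
        worst <- which(abs(R - diag(nrow(R))) > 0, arr.ind = TRUE)
        abort(paste0(
          "latent correlation matrix irreparably non-positive-definite; ",
          "offending pairs: ",
          paste(unique(apply(worst, 1, function(ij)
            paste(vars[ij[1]], vars[ij[2]], sep = "~"))), collapse = ", ")
        ))
      }
      R <- as.matrix(npd$mat)
      dimnames(R) <- list(vars, vars)
    }
    z <- matrix(rnorm(n * length(vars)), nrow = n) %*% chol(R)
    colnames(z) <- vars
    u <- pnorm(z)

    site_vals <- purrr::map(seq_len(nrow(gsites)), function(i) {
      qsitedist(u[, gsites$site_id[i]], gsites$dist[[i]])
    })
    names(site_vals) <- gsites$site_id
    sample_id <- sprintf("%s_%03d", g, seq_len(n))
    mat <- bind_cols(tibble(sample_id = sample_id, group = g),
                     as_tibble(site_vals, .name_repair = "minimal"))

    design <- tibble(sample_id = sample_id, group = g)
    for (cv in latent_covs) design[[cv]] <- cov_spec[[cv]](u[, cv])
    if (all(c("age_at_onset", "disease_duration") %in% names(design))) {
      design$age <- design$age_at_onset + design$disease_duration
    }
    if (!"age_at_onset" %in% names(design)) design$age_at_onset <- NA_real_
    if (!"disease_duration" %in% names(design)) design$disease_duration <- NA_real_
    if (!"updrs3" %in% names(design)) design$updrs3 <- NA_real_
    design$hoehn_yahr <- if ("hoehn_yahr" %in% names(cov_spec)) {
      as.integer(sample(names(cov_spec$hoehn_yahr), n, replace = TRUE,
                        prob = cov_spec$hoehn_yahr))
    } else NA_integer_
    design$sex <- sample(names(cov_spec$sex), n, replace = TRUE,
                         prob = cov_spec$sex)
    if ("treatment" %in% names(cov_spec)) {
      for (tr in names(cov_spec$treatment)) {
        design[[tr]] <- runif(n) < cov_spec$treatment[[tr]]
      }
    } else {
      design$levodopa <- design$agonist <- design$amantadine <- NA
    }
    list(matrix = mat, design = design)
  })
  mats <- purrr::map(out, "matrix")
  common <- Reduce(intersect, purrr::map(mats, names))
  list(
    matrix = bind_rows(purrr::map(mats, ~ .x[common])),
    design = bind_rows(purrr::map(out, "design")) |>
      select("sample_id", "group", "sex", "age", "age_at_onset",
             "disease_duration", "hoehn_yahr", "updrs3",
             "levodopa", "agonist", "amantadine")
  )
}
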