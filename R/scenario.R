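#' Synthetic SNCA-like reference regions
#'
#' Builds a deterministic synthetic gene fragment (clearly labelled as
#' synthetic — no real genome sequence is shipped) whose site geometry
#' mirrors the analysed SNCA regulatory regions: a promoter with 9 CpG
#' sites and a cluster of 28 elevated non-CpG candidates — including the
#' adjacent C-C-C run giving sites 4I/4J/4K and site 7A three bases
#' downstream of CpG-7 — plus three unmethylated CpH conversion controls;
#' an intron 1 with 48 CpG sites (CpG 1-20 persistently demethylated) and
#' six CpH controls; and an intron 2 with 2 CpG sites and four CpH
#' controls. The gene lies on the minus strand of the fragment, as SNCA
#' does in the reference genome.
#'
#' @return List with `regions` (region tibble, analysed orientation),
#'   `genome` (named character, plus-strand fragment) and `bed` (tibble of
#'   BED fields).
#' @export
synthetic_reference <- function() {
  promoter <- build_region_seq(c(
    "f10",
    "CG", "f6",          # CpG-1
    "CG", "f4",          # CpG-2
    "CA", "f4", "CT", "f4", "CA", "f4",   # controls 2A-2C (never methylated)
    "CG", "f3", "CA", "f5",               # CpG-3, 3A
    "CG", "f3",                           # CpG-4
    "CA", "f3", "CT", "f3", "CA", "f3", "CT", "f3",  # 4A-4D
    "CA", "f3", "CT", "f3", "CA", "f3", "CT", "f3",  # 4E-4H
    "CCCA", "f3",                         # 4I, 4J, 4K: the adjacent CCC run
    "CT", "f3",                           # 4L
    "CG", "f3", "CA", "f3", "CT", "f3", "CA", "f3",  # CpG-5, 5A-5C
    "CG", "f3", "CA", "f3", "CT", "f3",              # CpG-6, 6A-6B
    "CG", "f1", "CA", "f3",               # CpG-7, 7A three bases downstream
    "CT", "f3", "CA", "f3", "CT", "f3",   # 7B-7D
    "CG", "f3", "CA", "f3", "CT", "f3", "CA", "f3",  # CpG-8, 8A-8C
    "CG", "f3", "CA", "f3", "CT", "f3", "CA", "f3",  # CpG-9, 9A-9C
    "f10"
  ))
  intron1_tokens <- c("f8")
  for (i in 1:48) {
    intron1_tokens <- c(intron1_tokens, "CG", "f4")
    if (i %% 8 == 0) {
      intron1_tokens <- c(intron1_tokens,
                          if ((i %/% 8) %% 2 == 1) "CT" else "CA", "f3")
    }
  }
  intron1 <- build_region_seq(c(intron1_tokens, "f8"))
  intron2 <- build_region_seq(c(
    "f6", "CG", "f4",
    "CA", "f4", "CT", "f4", "CA", "f4", "CT", "f4",
    "CG", "f6"
  ))

  gap <- strrep("TTAGT", 10)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))
  )
  # gene on minus strand: promoter at the high-coordinate end
  genome <- paste0(gap, rc(intron2), gap, rc(intron1), gap, rc(promoter), gap)
  g <- nchar(gap)
  i2_start <- g
  i2_end <- i2_start + nchar(intron2)
  i1_start <- i2_end + g
  i1_end <- i1_start + nchar(intron1)
  pr_start <- i1_end + g
  pr_end <- pr_start + nchar(promoter)
  chrom <- "chr4_synthetic_fragment"
  regions <- bind_rows(
    region_row("promoter", chrom, pr_start, pr_end, "-", promoter),
    region_row("intron1", chrom, i1_start, i1_end, "-", intron1),
    region_row("intron2", chrom, i2_start, i2_end, "-", intron2)
  )
  bed <- tibble(
    chrom = chrom, start = c(pr_start, i1_start, i2_start),
    end = c(pr_end, i1_end, i2_end),
    name = c("promoter", "intron1", "intron2"), score = 0L, strand = "-"
  )
  list(regions = regions, genome = setNames(genome, chrom), bed = bed)
}

# Deterministic sequence assembly from tokens: "fN" = N filler bases from a
# fixed C-free pattern (each segment restarts at T so a preceding CC token
# never gains a CpG context), otherwise the literal token.
build_region_seq <- function(tokens) {
  filler <- function(n) {
    paste(rep_len(strsplit("TAGTT", "")[[1]], n), collapse = "")
  }
  paste(purrr::map_chr(tokens, function(tk) {
    if (grepl("^f[0-9]+$", tk)) filler(as.integer(sub("^f", "", tk))) else tk
  }), collapse = "")
}

#' Per-site methylation marginal specifications for the study scenario
#'
#' One boundary-inflated beta marginal per analysed site and study group.
#' Sites with published group summaries use the printed median \[Q1; Q3\]
#' values; the remaining sites carry deterministic, documented defaults
#' (equal across groups, so they contribute no spurious group effects).
#' The persistently demethylated blocks (promoter CpG 1-2, intron-1 CpG
#' 1-20) use a near-zero marginal. Conversion-control CpH candidates carry
#' no marginal: their simulated methylation is exactly zero.
#'
#' @param panel Site panel from [site_panel()] over [synthetic_reference()]
#'   regions.
#' @return Tibble `site_id`, `group`, `median`, `q1`, `q3` and list-column
#'   `dist` of fitted `site_dist` objects.
#' @export
snca_site_specs <- function(panel) {
  targets <- scenario_marginals()
  missing_sites <- setdiff(targets$site_id, panel$site_id)
  if (length(missing_sites) > 0) {
    abort(paste0("marginal table references absent site(s): ",
                 paste(missing_sites, collapse = ", ")))
  }
  targets |>
    mutate(dist = purrr::pmap(
      list(.data$median, .data$q1, .data$q3),
      function(median, q1, q3) {
        if (median == 0 && q1 == 0 && q3 <= 2) near_zero_dist()
        else fit_bounded_distribution(median, q1, q3)
      }
    ))
}

# Marginal for persistently demethylated sites: 70% exact zeros plus a
# beta(1, 150) body (mean 0.67%, P(> 5%) < 0.1%), i.e. methylation is
# essentially always below the 5% information threshold, which is what
# "demethylated in patients and controls" means operationally here.
near_zero_dist <- function() {
  dist <- structure(
    list(p0 = 0.7, p100 = 0, a = 1, b = 150,
         target = c(q1 = 0, median = 0, q3 = 2), achieved = NULL),
    class = "site_dist"
  )
  dist$achieved <- setNames(qsitedist(c(0.25, 0.5, 0.75), dist),
                            c("q1", "median", "q3"))
  dist
}

# The full marginal table: published group summaries where printed,
# deterministic defaults elsewhere (see the methods vignette).
scenario_marginals <- function() {
  row <- function(site_id, group, med, q1, q3) {
    tibble(site_id = site_id, group = group, median = med, q1 = q1, q3 = q3)
  }
  same <- function(site_id, med, q1, q3) {
    bind_rows(row(site_id, "PD", med, q1, q3),
              row(site_id, "MSA", med, q1, q3),
              row(site_id, "control", med, q1, q3))
  }
  out <- list()

  # --- promoter CpG 1-9 (CpG 1-2 demethylated; CpG-7 published) ---
  out <- c(out, list(
    same("promoter:CpG-1", 0, 0, 2), same("promoter:CpG-2", 0, 0, 2),
    row("promoter:CpG-7", "MSA", 36, 31, 41.5),
    row("promoter:CpG-7", "control", 26, 21, 33),
    row("promoter:CpG-7", "PD", 29, 23.5, 31)
  ))
  other_prom_cpg <- c(`3` = 24, `4` = 26, `5` = 30, `6` = 27, `8` = 25, `9` = 31)
  for (i in names(other_prom_cpg)) {
    m <- other_prom_cpg[[i]]
    out <- c(out, list(same(paste0("promoter:CpG-", i), m, m - 6, m + 7)))
  }

  # --- promoter CpH: published MSA/control rows; PD printed for 4I/7A ---
  cph_pub <- tibble::tribble(
    ~label, ~msa, ~c_grp, ~pd,
    "3A", c(13, 9.5, 14),    c(6, 3.25, 8),       c(9, 6, 12),
    "4B", c(13, 11, 17.5),   c(7, 4.25, 10),      c(10, 7, 13),
    "4C", c(23, 19.5, 28),   c(12, 7, 19),        c(17, 12, 23),
    "4I", c(26, 23, 31),     c(13, 9.5, 21.25),   c(20, 11.5, 24.5),
    "4J", c(28, 21.5, 30.5), c(14, 10.75, 21.5),  c(20, 15, 26),
    "4K", c(27, 25, 32),     c(19, 12.75, 26),    c(23, 17, 29),
    "4L", c(10, 8, 13),      c(6, 3.25, 9),       c(8, 5, 11),
    "7A", c(39, 32, 43),     c(13, 9, 19),        c(18, 12, 32)
  )
  for (i in seq_len(nrow(cph_pub))) {
    sid <- paste0("promoter:CpG-", cph_pub$label[i])
    out <- c(out, list(
      row(sid, "MSA", cph_pub$msa[[i]][1], cph_pub$msa[[i]][2], cph_pub$msa[[i]][3]),
      row(sid, "control", cph_pub$c_grp[[i]][1], cph_pub$c_grp[[i]][2], cph_pub$c_grp[[i]][3]),
      row(sid, "PD", cph_pub$pd[[i]][1], cph_pub$pd[[i]][2], cph_pub$pd[[i]][3])
    ))
  }
  other_cph <- c("4A", "4D", "4E", "4F", "4G", "4H", "5A", "5B", "5C",
                 "6A", "6B", "7B", "7C", "7D", "8A", "8B", "8C",
                 "9A", "9B", "9C")
  for (j in seq_along(other_cph)) {
    m <- 8 + (j %% 6) * 3
    out <- c(out, list(same(paste0("promoter:CpG-", other_cph[j]),
                            m, max(m - 4, 1), m + 5)))
  }

  # --- intron 1: CpG 1-20 demethylated; 31/32/33/45/47 (partly) published ---
  for (i in 1:20) {
    out <- c(out, list(same(paste0("intron1:CpG-", i), 0, 0, 2)))
  }
  out <- c(out, list(
    row("intron1:CpG-31", "PD", 0, 0, 10),
    row("intron1:CpG-31", "control", 10, 0, 17),
    row("intron1:CpG-31", "MSA", 5, 0, 14),
    row("intron1:CpG-32", "PD", 0, 0, 12.25),
    row("intron1:CpG-32", "control", 14, 0, 19),
    row("intron1:CpG-32", "MSA", 7, 0, 15),
    row("intron1:CpG-33", "PD", 0, 0, 9.5),
    row("intron1:CpG-33", "control", 10, 0, 15),
    row("intron1:CpG-33", "MSA", 5, 0, 12),
    row("intron1:CpG-45", "PD", 40, 35, 48),
    row("intron1:CpG-45", "control", 50, 40, 55),
    row("intron1:CpG-45", "MSA", 41, 32, 44.25),
    row("intron1:CpG-47", "PD", 42, 37, 45),
    row("intron1:CpG-47", "MSA", 37.5, 31.75, 39.25),
    row("intron1:CpG-47", "control", 43, 38, 48),
    same("intron1:CpG-22", 25, 18, 33),
    same("intron1:CpG-26", 28, 20, 35),
    same("intron1:CpG-39", 22, 15, 30),
    same("intron1:CpG-40", 30, 22, 38),
    row("intron1:CpG-38", "PD", 15, 6, 26),
    row("intron1:CpG-38", "control", 18, 10, 28),
    row("intron1:CpG-38", "MSA", 16, 8, 26)
  ))
  rest_i1 <- setdiff(21:48, c(22, 26, 31, 32, 33, 38, 39, 40, 45, 47))
  for (i in rest_i1) {
    m <- 18 + (i %% 7) * 4
    out <- c(out, list(same(paste0("intron1:CpG-", i), m, max(m - 8, 0), m + 9)))
  }

  # --- intron 2 ---
  out <- c(out, list(
    row("intron2:CpG-1", "MSA", 84, 77.75, 100),
    row("intron2:CpG-1", "control", 77, 74, 79),
    row("intron2:CpG-1", "PD", 80, 76, 90),
    row("intron2:CpG-2", "PD", 100, 87, 100),
    row("intron2:CpG-2", "MSA", 100, 86, 100),
    row("intron2:CpG-2", "control", 83, 81.5, 100)
  ))
  bind_rows(out)
}

#' Correlation targets of the study scenario
#'
#' The published clinical-epigenetic correlations injected by the
#' generator: age at onset vs intron-1 CpG-22/26/39/40 in PD (rho 0.52,
#' 0.52, 0.52, 0.56) and disease duration vs the promoter CCC-run sites
#' 4I/4J/4K in MSA (rho -0.66, -0.63, -0.67).
#'
#' @return Tibble `site_id`, `covariate`, `rho`, `group`.
#' @export
snca_correlation_targets <- function() {
  tibble::tribble(
    ~site_id, ~covariate, ~rho, ~group,
    "intron1:CpG-22", "age_at_onset", 0.52, "PD",
    "intron1:CpG-26", "age_at_onset", 0.52, "PD",
    "intron1:CpG-39", "age_at_onset", 0.52, "PD",
    "intron1:CpG-40", "age_at_onset", 0.56, "PD",
    "promoter:CpG-4I", "disease_duration", -0.66, "MSA",
    "promoter:CpG-4J", "disease_duration", -0.63, "MSA",
    "promoter:CpG-4K", "disease_duration", -0.67, "MSA"
  )
}

#' Generate the full synthetic study scenario
#'
#' End-to-end study generator: synthetic reference regions and site panel,
#' fitted per-site marginals, copula-simulated three-group cohort with the
#' published correlation structure, and (optionally, via
#' [write_scenario()]) per-sample trace tables. Deterministic under a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param group_sizes Named sizes for `PD`, `MSA`, `control` (defaults to
#'   the published 82/24/50).
#' @param trace Trace noise parameters: list with `total_signal`, `sigma`,
#'   `efficiency`, `crosstalk`.
#' @return List with `regions`, `panel`, `site_specs`, `correlations`,
#'   `cohort` (`$matrix` ground-truth percentages + `$design`), `trace`
#'   parameters and `seed`.
#' @export
snca_scenario <- function(seed = 1,
                          group_sizes = c(PD = 82L, MSA = 24L, control = 50L),
                          trace = list(total_signal = 1000, sigma = 0.02,
                                       efficiency = 0.98, crosstalk = 0.01)) {
  ref <- synthetic_reference()
  panel <- site_panel(ref$regions)
  site_specs <- snca_site_specs(panel)
  cohort <- simulate_cohort(
    cohort_spec(group_sizes), site_specs,
    correlations = snca_correlation_targets(), seed = seed
  )
  list(
    regions = ref$regions, genome = ref$genome, bed = ref$bed,
    panel = panel, site_specs = site_specs,
    correlations = snca_correlation_targets(),
    cohort = cohort, trace = trace, seed = as.integer(seed)
  )
}

#' Write a scenario to disk as plain-text study inputs
#'
#' Emits `reference.fa`, `regions.bed`, `panel.csv`, `design.csv`,
#' `truth.json` (ground-truth methylation and correlation targets) and one
#' trace table per sample x region under `traces/`. Intron-2 amplicons are
#' written as reverse-direction reads to exercise the channel-flip path.
#'
#' @param scenario A [snca_scenario()] result.
#' @param dir Output directory (created; must be empty unless
#'   `force = TRUE`).
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("output directory ", dir,
                 " exists and is not empty (use force = TRUE)"))
  }
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  writeLines(
    c(paste0(">", names(scenario$genome)),
      substring(scenario$genome,
                seq(1, nchar(scenario$genome), 70),
                pmin(seq(1, nchar(scenario$genome), 70) + 69,
                     nchar(scenario$genome)))),
    file.path(dir, "reference.fa")
  )
  readr::write_tsv(scenario$bed, file.path(dir, "regions.bed"),
                   col_names = FALSE)
  write_site_panel(scenario$panel, file.path(dir, "panel.csv"))
  readr::write_csv(scenario$cohort$design, file.path(dir, "design.csv"))
  readr::write_csv(scenario$cohort$matrix, file.path(dir, "truth_matrix.csv"))
  jsonlite::write_json(
    list(
      seed = scenario$seed, trace = scenario$trace,
      correlation_targets = scenario$correlations,
      marginals = select(scenario$site_specs, "site_id", "group",
                         "median", "q1", "q3")
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  # trace noise continues the scenario RNG stream: re-seed then burn the
  # cohort draw so repeated writes of one scenario object are identical
  set.seed(scenario$seed + 1L)
  mat <- scenario$cohort$matrix
  for (i in seq_len(nrow(mat))) {
    values <- unlist(mat[i, setdiff(names(mat), c("sample_id", "group"))])
    for (r in seq_len(nrow(scenario$regions))) {
      reg <- scenario$regions[r, ]
      rp <- filter(scenario$panel, .data$region == reg$region)
      chrom <- simulate_trace(
        values, reg, rp, sample_id = mat$sample_id[i],
        total_signal = scenario$trace$total_signal,
        sigma = scenario$trace$sigma,
        efficiency = scenario$trace$efficiency,
        crosstalk = scenario$trace$crosstalk,
        strand = if (reg$region == "intron2") "reverse" else "forward"
      )
      write_trace_table(
        chrom,
        file.path(dir, "traces",
                  paste0(mat$sample_id[i], "_", reg$region, ".tsv"))
      )
    }
  }
  invisible(dir)
}
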