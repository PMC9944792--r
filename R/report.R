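#' Format a `median [Q1; Q3]` summary
#'
#' Values are stored at full precision and displayed with at most two
#' decimals, trailing zeros stripped (the table style "41 \[32; 44.25\]").
#'
#' @param median,q1,q3 Summary values.
#' @return Character vector.
#' @export
format_median_iqr <- function(median, q1, q3) {
  fmt <- function(x) {
    ifelse(is.na(x), "NA", sub("\\.?0+$", "", sprintf("%.2f", x)))
  }
  ifelse(is.na(median), "NA",
         paste0(fmt(median), " [", fmt(q1), "; ", fmt(q3), "]"))
}

#' Render a plain-text cohort report
#'
#' Publication-style report: per region and site kind, a `median [Q1; Q3]` table
#' across groups, the Bonferroni family sizes with their truncated display
#' thresholds, significant pairwise differences and retained correlations.
#'
#' @param summaries [group_summaries()] output.
#' @param comparisons [run_group_comparisons()] output.
#' @param correlations [run_correlation_screen()] output (optional).
#' @param dropped Optional tibble of filtered-out sites.
#' @return Character vector of report lines.
#' @export
render_stats_report <- function(summaries, comparisons, correlations = NULL,
                                dropped = NULL) {
  lines <- c("Methylation cohort report", strrep("=", 25), "")
  groups <- unique(summaries$group)
  fams <- comparisons |>
    as_tibble() |>
    distinct(.data$family, .data$family_size, .data$alpha_adjusted)
  for (i in seq_len(nrow(fams))) {
    fam <- fams[i, ]
    fam_sites <- comparisons |>
      as_tibble() |>
      filter(.data$family == fam$family) |>
      distinct(.data$site_id, .data$label, .data$region)
    lines <- c(lines,
               paste0("## ", fam$family, " (", fam$family_size,
                      " sites, adjusted alpha ",
                      format_alpha_truncated(fam$alpha_adjusted), ")"),
               "")
    hdr <- paste(c(sprintf("%-10s", "site"),
                   sprintf("%-22s", groups)), collapse = "")
    lines <- c(lines, hdr, strrep("-", nchar(hdr)))
    for (j in seq_len(nrow(fam_sites))) {
      s <- summaries |> filter(.data$site_id == fam_sites$site_id[j])
      cells <- purrr::map_chr(groups, function(g) {
        r <- s |> filter(.data$group == g)
        if (nrow(r) == 0) "NA" else format_median_iqr(r$median, r$q1, r$q3)
      })
      lines <- c(lines, paste(c(sprintf("%-10s", fam_sites$label[j]),
                                sprintf("%-22s", cells)), collapse = ""))
    }
    sig <- comparisons |>
      as_tibble() |>
      filter(.data$family == fam$family, .data$significant)
    lines <- c(lines, "",
               if (nrow(sig) > 0) {
                 c("significant after Bonferroni:",
                   sprintf("  %s %s: U = %g, p = %.6g",
                           sig$label, sig$comparison, sig$statistic,
                           sig$p_value))
               } else {
                 "no significant differences after Bonferroni"
               },
               "")
  }
  if (!is.null(correlations)) {
    kept <- correlations |> as_tibble() |> filter(.data$retained)
    lines <- c(lines, "## Retained correlations (|rho| >= 0.5)", "")
    lines <- c(lines,
               if (nrow(kept) > 0) {
                 sprintf("  %s (%s) ~ %s: rho = %.2f (%s), p = %.3g",
                         kept$label, kept$group, kept$covariate, kept$rho,
                         kept$strength, kept$p_value)
               } else "  none", "")
  }
  if (!is.null(dropped) && nrow(dropped) > 0) {
    lines <- c(lines, paste0("Uninformative sites dropped before testing (",
                             nrow(dropped), "): "),
               paste0("  ", paste(dropped$site_id, collapse = ", ")), "")
  }
  lines
}

#' Simulate subcommand: write a synthetic study to disk
#'
#' @param out Output directory.
#' @param seed Integer seed.
#' @param group_sizes Named `PD`/`MSA`/`control` sizes.
#' @param force Overwrite a non-empty directory.
#' @param trace Trace parameter list (see [snca_scenario()]).
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(out, seed = 1,
                         group_sizes = c(PD = 82L, MSA = 24L, control = 50L),
                         force = FALSE, trace = NULL) {
  scenario <- if (is.null(trace)) snca_scenario(seed, group_sizes)
  else snca_scenario(seed, group_sizes, trace)
  write_scenario(scenario, out, force = force)
  manifest <- list(
    command = "simulate", seed = scenario$seed,
    group_sizes = as.list(group_sizes), trace = scenario$trace,
    package_version = as.character(utils::packageVersion("sangermeth")),
    files = sort(setdiff(list.files(out, recursive = TRUE), "manifest.json")),
    input_hashes = file_hashes(out, c("design.csv", "panel.csv",
                                      "reference.fa", "regions.bed"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(paste0("simulated study written to ", out, " (",
                nrow(scenario$cohort$design), " samples)"))
  invisible(out)
}

#' Quantify subcommand: traces to methylation matrix
#'
#' Reads the reference, region BED, design table and every trace table
#' under `<dir>/traces`, runs the two-pass cohort quantification and writes
#' `matrix.csv` plus `qc.json` (per-trace QC with exclusion reasons and the
#' CpH discovery table). Corrupt or unalignable traces exclude the affected
#' sample/region but do not abort the run.
#'
#' @param dir Study directory (layout as written by [cmd_simulate()]).
#' @param out Output directory (default `dir`).
#' @param correction Apply conversion correction (default TRUE).
#' @param efficiency_floor,detection_threshold_pct See [quantify_cohort()].
#' @return List as from [quantify_cohort()], invisibly.
#' @export
cmd_quantify <- function(dir, out = dir, correction = TRUE,
                         efficiency_floor = 0.90,
                         detection_threshold_pct = 5) {
  fasta <- file.path(dir, "reference.fa")
  bed <- file.path(dir, "regions.bed")
  if (!file.exists(fasta) || !file.exists(bed)) {
    abort("study directory must contain reference.fa and regions.bed")
  }
  regions <- read_regions(fasta, bed)
  panel <- site_panel(regions)
  design_path <- file.path(dir, "design.csv")
  design <- if (file.exists(design_path)) {
    readr::read_csv(design_path, show_col_types = FALSE)
  } else NULL
  trace_files <- list.files(file.path(dir, "traces"), full.names = TRUE)
  if (length(trace_files) == 0) abort(paste0("no trace tables under ", dir, "/traces"))
  chroms <- purrr::map(trace_files, function(f) {
    tryCatch(read_trace_table(f), error = function(e) {
      warn(paste0("skipping unreadable trace ", basename(f), ": ",
                  conditionMessage(e)))
      NULL
    })
  })
  chroms <- purrr::compact(chroms)
  res <- quantify_cohort(
    chroms, regions, panel, design = design, correction = correction,
    efficiency_floor = efficiency_floor,
    detection_threshold_pct = detection_threshold_pct
  )
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$matrix, file.path(out, "matrix.csv"))
  write_site_panel(panel, file.path(out, "panel.csv"))
  jsonlite::write_json(
    list(qc = res$qc, discovered = res$discovered,
         n_traces_read = length(chroms),
         n_traces_skipped = length(trace_files) - length(chroms)),
    file.path(out, "qc.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(res)
}

#' Stats subcommand: matrix to tests, correlations and report
#'
#' Applies the uninformative-site filter, computes group summaries,
#' pairwise Mann-Whitney comparisons with region-wise Bonferroni families
#' and the per-group Spearman screen, and writes `results_comparisons.csv`,
#' `results_correlations.csv`, `results.json` and a plain-text
#' `report.txt`.
#'
#' @param dir Directory containing `matrix.csv` and `panel.csv`.
#' @param out Output directory (default `dir`).
#' @param alpha Family-wise significance level.
#' @param threshold_pct,min_fraction Uninformative-site filter settings.
#' @return List with `summaries`, `comparisons`, `correlations`,
#'   `dropped` and `report` lines, invisibly.
#' @export
cmd_stats <- function(dir, out = dir, alpha = 0.05, threshold_pct = 5,
                      min_fraction = 0.95) {
  matrix_path <- file.path(dir, "matrix.csv")
  panel_path <- file.path(dir, "panel.csv")
  if (!file.exists(matrix_path) || !file.exists(panel_path)) {
    abort("stats stage needs matrix.csv and panel.csv (run cmd_quantify first)")
  }
  mat <- readr::read_csv(matrix_path, show_col_types = FALSE)
  panel_csv <- readr::read_csv(panel_path, show_col_types = FALSE)
  panel <- panel_csv |> rename(genomic_pos = "genomic_pos_1based")
  if (!"group" %in% names(mat)) abort("matrix.csv carries no 'group' column")
  filt <- filter_uninformative_sites(mat, threshold_pct = threshold_pct,
                                     min_fraction = min_fraction)
  summaries <- group_summaries(filt$matrix, panel)
  comparisons <- run_group_comparisons(filt$matrix, panel, alpha = alpha)
  correlations <- run_correlation_screen(filt$matrix, panel)
  report <- render_stats_report(summaries, comparisons, correlations,
                                filt$dropped)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(comparisons),
                   file.path(out, "results_comparisons.csv"))
  readr::write_csv(as_tibble(correlations),
                   file.path(out, "results_correlations.csv"))
  jsonlite::write_json(
    list(summaries = summaries, comparisons = as_tibble(comparisons),
         correlations = as_tibble(correlations), dropped = filt$dropped),
    file.path(out, "results.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_lines(report, file.path(out, "report.txt"))
  invisible(list(summaries = summaries, comparisons = comparisons,
                 correlations = correlations, dropped = filt$dropped,
                 report = report))
}

file_hashes <- function(dir, files) {
  present <- files[file.exists(file.path(dir, files))]
  setNames(
    purrr::map_chr(present, function(f) {
      # small content fingerprint without extra dependencies
      x <- readr::read_file(file.path(dir, f))
      sprintf("%d:%d", nchar(x), sum(utf8ToInt(x) * seq_len(nchar(x))) %% 2^31)
    }),
    present
  )
}
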