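#' Peak-height methylation ratio
#'
#' Per-site methylation from a bisulfite Sanger trace is the primary-channel
#' peak height over the sum of the two informative channels at that call:
#' `100 * H_C / (H_C + H_T)` on a forward read (the C peak marks the
#' protected, methylated cytosine; the T peak the converted one), and
#' identically `100 * H_G / (H_G + H_A)` on a reverse read after channel
#' flipping. Values are kept at full precision; rounding happens only in
#' rendered reports.
#'
#' @param h_primary,h_alternative Non-negative peak heights (C and T on a
#'   forward read).
#' @return Percent in `[0, 100]`, or `NA` when both heights are zero
#'   (no signal).
#' @examples
#' peak_ratio(84, 16)  # 84
#' @export
peak_ratio <- function(h_primary, h_alternative) {
  stopifnot(all(h_primary >= 0, na.rm = TRUE), all(h_alternative >= 0, na.rm = TRUE))
  denom <- h_primary + h_alternative
  out <- ifelse(denom > 0, 100 * h_primary / denom, NA_real_)
  unname(out)
}

#' Estimate bisulfite conversion efficiency from control cytosines
#'
#' Non-CpG cytosines that are not genuinely methylated read pure T after
#' complete conversion; any residual C signal there measures incomplete
#' conversion. Efficiency is `1 - mean(ratio)/100` over the control sites,
#' clipped to `[0, 1]`. Controls must exclude CpH sites discovered to be
#' genuinely methylated (see [discover_noncpg()]), otherwise samples with
#' true non-CpG methylation would be wrongly penalised.
#'
#' @param control_ratios Raw percent ratios at control CpH sites.
#' @param min_controls Minimum number of non-missing controls (default 3).
#' @return Efficiency fraction in `[0, 1]`, or `NA` if fewer than
#'   `min_controls` controls are available.
#' @export
estimate_conversion_efficiency <- function(control_ratios, min_controls = 3L) {
  control_ratios <- control_ratios[!is.na(control_ratios)]
  if (length(control_ratios) < min_controls) return(NA_real_)
  min(max(1 - mean(control_ratios) / 100, 0), 1)
}

#' Correct a raw methylation ratio for incomplete conversion
#'
#' Residual-subtraction rescale: an unconverted fraction `1 - eff` of
#' unmethylated template reads as C, so the raw ratio overestimates
#' methylation by `(1 - eff) * (1 - m)`. Inverting,
#' `m = (m_raw/100 - (1 - eff)) / eff`, floored at 0 and capped at 100.
#'
#' @param m_raw Raw percent ratio(s).
#' @param efficiency Conversion efficiency in `(0, 1]`.
#' @return Corrected percent in `[0, 100]` (NA propagates).
#' @examples
#' correct_conversion(50, 0.90)  # 44.44...
#' @export
correct_conversion <- function(m_raw, efficiency) {
  if (is.na(efficiency) || efficiency <= 0 || efficiency > 1) {
    abort("conversion efficiency must be in (0, 1]")
  }
  pmin(100 * pmax((m_raw / 100 - (1 - efficiency)) / efficiency, 0), 100)
}

#' Quantify one chromatogram against a site panel
#'
#' Composition of the per-sample pipeline: align the basecalls to the
#' converted reference, read off the C/T (or, on flipped reverse reads,
#' G/A-derived) peak heights at every mapped panel site, form raw ratios,
#' estimate conversion efficiency from control CpH sites and apply the
#' conversion correction. Non-CpG sites are treated exactly like CpG sites.
#'
#' @param chrom A `chromatogram`.
#' @param panel Site panel rows for the chromatogram's region.
#' @param converted_ref Converted reference for the region, with `Y` at
#'   panel cytosines (see [converted_reference()]).
#' @param discovered Character vector of CpH `site_id`s known to be
#'   genuinely methylated; excluded from the conversion control set.
#' @param correction Apply conversion correction (default TRUE). When FALSE
#'   `m_corrected` equals `m_raw`.
#' @param efficiency_floor QC floor for conversion efficiency (default
#'   0.90): profiles below it are flagged `low-conversion` and should be
#'   excluded by the caller.
#' @param min_identity,min_overlap Alignment QC, see [align_basecalls()].
#' @return A `sample_profile`: list with `sample_id`, `region`,
#'   `conversion_efficiency`, `qc_flags` and a `calls` tibble (`site_id`,
#'   `label`, `kind`, `call_index`, `h_primary`, `h_alternative`, `m_raw`,
#'   `m_corrected`, `qc_flags`).
#' @export
quantify_sample <- function(chrom, panel, converted_ref,
                            discovered = character(),
                            correction = TRUE, efficiency_floor = 0.90,
                            min_identity = 0.9, min_overlap = 20L) {
  map <- align_basecalls(chrom, converted_ref,
                         min_identity = min_identity, min_overlap = min_overlap)
  mapped <- map_sites_to_calls(map, panel)
  calls_tbl <- map$chrom$calls
  h_c <- calls_tbl$H_C[mapped$call_index + 1L]
  h_t <- calls_tbl$H_T[mapped$call_index + 1L]
  m_raw <- peak_ratio(ifelse(is.na(mapped$call_index), NA_real_, h_c),
                      ifelse(is.na(mapped$call_index), NA_real_, h_t))
  flags <- purrr::map2_chr(mapped$call_index, m_raw, function(ci, m) {
    if (is.na(ci)) "unmapped" else if (is.na(m)) "no-signal" else ""
  })
  calls <- tibble(
    site_id = mapped$site_id, label = mapped$label, kind = mapped$kind,
    call_index = mapped$call_index,
    h_primary = ifelse(is.na(mapped$call_index), NA_real_, h_c),
    h_alternative = ifelse(is.na(mapped$call_index), NA_real_, h_t),
    m_raw = m_raw, qc_flags = flags
  )
  profile_from_calls(
    calls, sample_id = chrom$sample_id, region = chrom$region,
    discovered = discovered, correction = correction,
    efficiency_floor = efficiency_floor,
    alignment = list(offset = map$offset, identity = map$identity,
                     mismatches = map$mismatches)
  )
}

# Shared tail of quantify_sample, reused when re-correcting after discovery.
profile_from_calls <- function(calls, sample_id, region, discovered,
                               correction, efficiency_floor, alignment = NULL) {
  control <- calls$kind == "CpH" & !(calls$site_id %in% discovered)
  eff <- estimate_conversion_efficiency(calls$m_raw[control])
  qc_flags <- character()
  if (is.na(eff)) {
    qc_flags <- c(qc_flags, "no-efficiency-estimate")
  } else if (eff < efficiency_floor) {
    qc_flags <- c(qc_flags, "low-conversion")
  }
  calls$m_corrected <- if (correction && !is.na(eff) && eff >= efficiency_floor) {
    correct_conversion(calls$m_raw, eff)
  } else {
    calls$m_raw
  }
  structure(
    list(
      sample_id = sample_id, region = region,
      conversion_efficiency = eff, qc_flags = qc_flags,
      n_controls = sum(control & !is.na(calls$m_raw)),
      alignment = alignment, calls = calls
    ),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile>", x$sample_id, "/", x$region, "|",
      nrow(x$calls), "sites | conversion",
      if (is.na(x$conversion_efficiency)) "NA"
      else sprintf("%.3f", x$conversion_efficiency),
      if (length(x$qc_flags)) paste("|", paste(x$qc_flags, collapse = ",")) else "",
      "\n")
  invisible(x)
}

#' Converted alignment reference for a region
#'
#' Bisulfite-converts the region sequence with every panel cytosine (CpG and
#' CpH candidate alike) rendered as the ambiguity code `Y`, since its
#' methylation state — hence its C/T identity in the read — is unknown.
#'
#' @param region One-row region tibble.
#' @param panel Site panel rows for the region.
#' @return Converted reference string.
#' @export
converted_reference <- function(region, panel) {
  bisulfite_convert(region$sequence, ambiguity_offsets = panel$offset)
}

#' Quantify a cohort of chromatograms into a methylation matrix
#'
#' Two-pass cohort quantification: (1) align and ratio every trace with all
#' CpH candidates as conversion controls; (2) discover genuinely methylated
#' CpH sites from the raw cohort matrix, then re-estimate each profile's
#' conversion efficiency on the reduced control set and apply the
#' correction. Traces failing alignment or the conversion-efficiency floor
#' are excluded and reported.
#'
#' @param chroms List of `chromatogram` objects (one per sample x region).
#' @param regions Region tibble.
#' @param panel Full site panel.
#' @param design Optional study design tibble (`sample_id`, `group`, ...)
#'   joined onto the matrix; group labels also drive CpH discovery.
#' @param correction,efficiency_floor,detection_threshold_pct,min_identity
#'   See [quantify_sample()] and [discover_noncpg()].
#' @return List with `matrix` (tibble, one row per passing sample; columns
#'   `sample_id`, design columns, then one column per panel `site_id`),
#'   `qc` (per-trace QC tibble) and `discovered` (CpH discovery tibble).
#' @export
quantify_cohort <- function(chroms, regions, panel, design = NULL,
                            correction = TRUE, efficiency_floor = 0.90,
                            detection_threshold_pct = 5,
                            min_identity = 0.9) {
  refs <- setNames(
    purrr::map_chr(seq_len(nrow(regions)), function(i) {
      reg <- regions[i, ]
      converted_reference(reg, filter(panel, .data$region == reg$region))
    }),
    regions$region
  )
  pass1 <- purrr::map(chroms, function(ch) {
    if (!ch$region %in% names(refs)) {
      return(list(error = paste0("unknown region '", ch$region, "'"),
                  sample_id = ch$sample_id, region = ch$region))
    }
    tryCatch(
      quantify_sample(
        ch, filter(panel, .data$region == ch$region), refs[[ch$region]],
        correction = FALSE, efficiency_floor = efficiency_floor,
        min_identity = min_identity
      ),
      error = function(e) list(error = conditionMessage(e),
                               sample_id = ch$sample_id, region = ch$region)
    )
  })
  failed <- purrr::map_lgl(pass1, ~ !inherits(.x, "sample_profile"))
  profiles <- pass1[!failed]

  raw_long <- purrr::map_dfr(profiles, function(p) {
    mutate(select(p$calls, "site_id", "m_raw"), sample_id = p$sample_id)
  })
  raw_matrix <- tidyr::pivot_wider(raw_long, id_cols = "sample_id",
                                   names_from = "site_id", values_from = "m_raw")
  groups <- cohort_groups(raw_matrix$sample_id, design)
  discovered_tbl <- discover_noncpg(
    raw_matrix, panel, groups = groups,
    detection_threshold_pct = detection_threshold_pct
  )
  discovered <- discovered_tbl$site_id[discovered_tbl$discovered]

  profiles2 <- purrr::map(profiles, function(p) {
    profile_from_calls(
      select(p$calls, -dplyr::any_of("m_corrected")),
      sample_id = p$sample_id, region = p$region, discovered = discovered,
      correction = correction, efficiency_floor = efficiency_floor,
      alignment = p$alignment
    )
  })
  qc <- bind_rows(
    purrr::map_dfr(profiles2, function(p) {
      tibble(
        sample_id = p$sample_id, region = p$region, status = "pass",
        conversion_efficiency = p$conversion_efficiency,
        n_controls = p$n_controls,
        flags = paste(p$qc_flags, collapse = ";"),
        reason = NA_character_
      )
    }),
    purrr::map_dfr(pass1[failed], function(f) {
      tibble(
        sample_id = f$sample_id %||% NA_character_,
        region = f$region %||% NA_character_,
        status = "excluded", conversion_efficiency = NA_real_,
        n_controls = NA_integer_, flags = "", reason = f$error
      )
    })
  )
  excluded_lowconv <- purrr::map_lgl(profiles2, ~ "low-conversion" %in% .x$qc_flags)
  qc$status[qc$status == "pass"][excluded_lowconv] <- "excluded"
  qc$reason[qc$status == "excluded" & is.na(qc$reason)] <- "conversion efficiency below floor"
  kept <- profiles2[!excluded_lowconv]

  long <- purrr::map_dfr(kept, function(p) {
    mutate(select(p$calls, "site_id", "m_corrected"), sample_id = p$sample_id)
  })
  mat <- tidyr::pivot_wider(long, id_cols = "sample_id",
                            names_from = "site_id", values_from = "m_corrected")
  ordered_sites <- intersect(panel$site_id, names(mat))
  mat <- mat[c("sample_id", ordered_sites)]
  if (!is.null(design)) {
    passing <- mat$sample_id
    mat <- design |>
      filter(.data$sample_id %in% passing) |>
      left_join(mat, by = "sample_id")
  }
  list(matrix = mat, qc = qc, discovered = discovered_tbl)
}

cohort_groups <- function(sample_ids, design) {
  if (is.null(design) || !"group" %in% names(design)) {
    return(setNames(rep("all", length(sample_ids)), sample_ids))
  }
  setNames(
    design$group[match(sample_ids, design$sample_id)],
    sample_ids
  )
}

#' Drop uninformative (persistently demethylated) sites
#'
#' Mirrors the pre-screening step of the source assay: sites that are
#' essentially unmethylated in every study group carry no comparative
#' information and are removed before testing (the SNCA intron-1 CpG 1-20
#' block is the canonical example). A site is dropped when its value is
#' `<= threshold_pct` in at least `min_fraction` of the non-missing samples
#' of every group.
#'
#' @param matrix Methylation matrix tibble (`sample_id` + site columns,
#'   optionally design columns).
#' @param threshold_pct Percent threshold (default 5).
#' @param min_fraction Fraction of samples per group (default 0.95).
#' @param groups Optional named vector `sample_id -> group`; defaults to the
#'   matrix's `group` column or a single group.
#' @return List with `matrix` (reduced) and `dropped` (tibble of dropped
#'   `site_id`s with per-group low fractions).
#' @export
filter_uninformative_sites <- function(matrix, threshold_pct = 5,
                                       min_fraction = 0.95, groups = NULL) {
  site_cols <- site_columns(matrix)
  if (length(site_cols) == 0) abort("matrix has no site columns")
  if (is.null(groups)) {
    groups <- if ("group" %in% names(matrix)) {
      setNames(as.character(matrix$group), matrix$sample_id)
    } else {
      setNames(rep("all", nrow(matrix)), matrix$sample_id)
    }
  }
  g <- groups[matrix$sample_id]
  dropped <- purrr::map_dfr(site_cols, function(sc) {
    v <- matrix[[sc]]
    frac <- tapply(v, g, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_real_)
      mean(x <= threshold_pct)
    })
    tibble(
      site_id = sc,
      min_group_low_fraction = suppressWarnings(min(frac, na.rm = TRUE)),
      drop = all(frac >= min_fraction, na.rm = TRUE) && !all(is.na(frac))
    )
  }) |> filter(.data$drop)
  list(
    matrix = matrix[setdiff(names(matrix), dropped$site_id)],
    dropped = select(dropped, "site_id", "min_group_low_fraction")
  )
}

#' Discover methylated non-CpG (CpH) sites
#'
#' A CpH candidate is called "discovered" (genuinely methylated) when its
#' group median raw ratio exceeds `detection_threshold_pct` in at least one
#' study group; all other candidates are reported absent and serve as
#' conversion-efficiency controls.
#'
#' @param matrix Methylation matrix tibble (raw ratios).
#' @param panel Site panel (used to restrict to CpH candidates).
#' @param groups Named vector `sample_id -> group` (default: `group` column
#'   or one group).
#' @param detection_threshold_pct Median detection threshold (default 5).
#' @return Tibble `site_id`, `region`, `max_group_median`, `discovered`.
#' @export
discover_noncpg <- function(matrix, panel, groups = NULL,
                            detection_threshold_pct = 5) {
  cph <- filter(panel, .data$kind == "CpH")
  cols <- intersect(cph$site_id, names(matrix))
  if (is.null(groups)) {
    groups <- if ("group" %in% names(matrix)) {
      setNames(as.character(matrix$group), matrix$sample_id)
    } else {
      setNames(rep("all", nrow(matrix)), matrix$sample_id)
    }
  }
  g <- groups[matrix$sample_id]
  purrr::map_dfr(cols, function(sc) {
    med <- tapply(matrix[[sc]], g, function(x) median(x, na.rm = TRUE))
    mx <- suppressWarnings(max(med, na.rm = TRUE))
    tibble(
      site_id = sc,
      region = cph$region[match(sc, cph$site_id)],
      max_group_median = if (is.finite(mx)) mx else NA_real_,
      discovered = is.finite(mx) && mx > detection_threshold_pct
    )
  })
}

# Site columns of a methylation matrix: everything matching region:label.
site_columns <- function(matrix) {
  grep("^[^:]+:CpG-[0-9]+[A-Z]*$", names(matrix), value = TRUE)
}
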