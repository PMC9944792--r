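#' Read a Sanger trace table
#'
#' The trace table is the package's canonical plain-text chromatogram
#' exchange format: comment header lines `# key=value` carrying `sample_id`,
#' `region` and `strand` (forward reads the converted plus strand, reverse
#' its complement), then a TSV body with columns `call_index` (0-based,
#' contiguous), `base` (A/C/G/T/N/Y/R) and the four channel peak heights
#' `H_A`, `H_C`, `H_G`, `H_T` in relative fluorescence units.
#'
#' @param path Path to a trace table file.
#' @return A `chromatogram` object: list with `sample_id`, `region`,
#'   `strand` and a `calls` tibble.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) abort(paste0("trace table not found: ", path))
  lines <- readr::read_lines(path)
  hdr_idx <- which(startsWith(lines, "#"))
  hdr_idx <- hdr_idx[hdr_idx == seq_along(hdr_idx)]  # leading block only
  meta <- list()
  for (ln in lines[hdr_idx]) {
    kv <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) abort(paste0(path, ": no call rows"))
  calls <- tryCatch(
    readr::read_tsv(I(body), show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0(path, ": cannot parse call table: ", conditionMessage(e)))
  )
  needed <- c("call_index", "base", "H_A", "H_C", "H_G", "H_T")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  calls <- calls[needed]
  for (h in c("H_A", "H_C", "H_G", "H_T")) {
    bad <- which(!is.finite(calls[[h]]) | calls[[h]] < 0)
    if (length(bad) > 0) {
      abort(paste0(
        path, ": negative or non-numeric height in column ", h,
        " at line ", length(hdr_idx) + 1 + bad[1]
      ))
    }
  }
  if (!identical(as.integer(calls$call_index), seq_len(nrow(calls)) - 1L)) {
    first_bad <- which(as.integer(calls$call_index) != seq_len(nrow(calls)) - 1L)[1]
    abort(paste0(
      path, ": call_index not contiguous from 0 at line ",
      length(hdr_idx) + 1 + first_bad
    ))
  }
  chromatogram(
    sample_id = meta$sample_id %||% NA_character_,
    region = meta$region %||% NA_character_,
    strand = meta$strand %||% "forward",
    calls = calls
  )
}

#' Write a chromatogram as a trace table
#'
#' @param chrom A `chromatogram` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(chrom, path) {
  hdr <- c(
    paste0("# sample_id=", chrom$sample_id),
    paste0("# region=", chrom$region),
    paste0("# strand=", chrom$strand)
  )
  body <- c(
    paste(c("call_index", "base", "H_A", "H_C", "H_G", "H_T"), collapse = "\t"),
    apply(chrom$calls, 1, function(r) {
      paste(c(r[["call_index"]], r[["base"]],
              format_height(r[["H_A"]]), format_height(r[["H_C"]]),
              format_height(r[["H_G"]]), format_height(r[["H_T"]])),
            collapse = "\t")
    })
  )
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

format_height <- function(x) formatC(as.numeric(x), format = "fg", digits = 10)

#' Construct a chromatogram object
#'
#' @param sample_id,region,strand Header metadata; `strand` is `"forward"`
#'   (reads the converted plus strand) or `"reverse"` (reads its complement).
#' @param calls Tibble with `call_index`, `base`, `H_A`, `H_C`, `H_G`, `H_T`.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(sample_id, region, strand, calls) {
  calls <- as_tibble(calls)
  calls$call_index <- as.integer(calls$call_index)
  calls$base <- toupper(as.character(calls$base))
  stopifnot(all(calls$base %in% c("A", "C", "G", "T", "N", "Y", "R")))
  heights <- as.matrix(calls[, c("H_A", "H_C", "H_G", "H_T")])
  if (any(heights < 0)) abort("chromatogram heights must be non-negative")
  if (nrow(calls) > 0 && any(rowSums(heights) <= 0)) {
    abort("every call must have at least one positive channel height")
  }
  structure(
    list(sample_id = sample_id, region = region,
         strand = match.arg(strand, c("forward", "reverse")), calls = calls),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram> sample", x$sample_id, "| region", x$region,
      "|", x$strand, "|", nrow(x$calls), "calls\n")
  invisible(x)
}

#' Complement-flip a reverse-direction chromatogram
#'
#' A reverse Sanger read runs 3'->5' along the complement of the converted
#' strand, so its G/A channels play the roles that C/T play on a forward
#' read. Flipping reverses the call order, complements the basecalls
#' (including Y<->R) and swaps the A<->T and C<->G channels, yielding a
#' chromatogram directly comparable to the converted reference. The
#' operation is an involution.
#'
#' @param chrom A `chromatogram`.
#' @return The flipped `chromatogram` (strand toggled).
#' @export
flip_chromatogram <- function(chrom) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", Y = "R", R = "Y")
  calls <- chrom$calls[rev(seq_len(nrow(chrom$calls))), ]
  calls <- tibble(
    call_index = seq_len(nrow(calls)) - 1L,
    base = unname(comp[calls$base]),
    H_A = calls$H_T, H_C = calls$H_G, H_G = calls$H_C, H_T = calls$H_A
  )
  chromatogram(
    sample_id = chrom$sample_id, region = chrom$region,
    strand = if (chrom$strand == "forward") "reverse" else "forward",
    calls = calls
  )
}

#' Align chromatogram basecalls to a converted reference
#'
#' Ungapped alignment of the basecall string against the in-silico converted
#' reference (built by [bisulfite_convert()] with methylation-variable
#' cytosines rendered as `Y`). The offset maximising the number of matching
#' calls is chosen; `Y` matches C or T, `R` matches G or A, `N` matches
#' anything. Reverse-direction chromatograms are complement-flipped first.
#' Indels are outside the model: a trace whose best ungapped identity over
#' the overlap falls below `min_identity` is rejected as unalignable.
#'
#' @param chrom A `chromatogram`.
#' @param converted_ref Converted reference string (may contain Y).
#' @param min_identity Identity floor over the aligned overlap (default 0.9,
#'   permissive because the converted sequence is effectively three-letter).
#' @param min_overlap Minimum number of overlapping calls for a candidate
#'   offset (default 20, or the full length for shorter inputs).
#' @return A `site_trace_map` to feed [quantify_sample()]: list with
#'   `offset` (trace call index aligned to reference position 0, may be
#'   negative), `matches`, `mismatches`, `identity`, `overlap` and the
#'   flipped-if-needed chromatogram in `$chrom`.
#' @export
align_basecalls <- function(chrom, converted_ref, min_identity = 0.9,
                            min_overlap = 20L) {
  if (chrom$strand == "reverse") chrom <- flip_chromatogram(chrom)
  trace <- chrom$calls$base
  ref <- strsplit(toupper(converted_ref), "")[[1]]
  lt <- length(trace)
  lr <- length(ref)
  min_overlap <- min(min_overlap, lt, lr)
  offsets <- seq(-(lr - min_overlap), lt - min_overlap)
  best <- list(score = -1L)
  for (off in offsets) {
    # trace[off + k + 1] pairs with ref[k + 1]
    k_lo <- max(0L, -off)
    k_hi <- min(lr - 1L, lt - 1L - off)
    if (k_hi - k_lo + 1L < min_overlap) next
    r <- ref[(k_lo:k_hi) + 1L]
    t <- trace[(k_lo:k_hi) + off + 1L]
    score <- sum(base_matches(r, t))
    overlap <- k_hi - k_lo + 1L
    # ties in match count go to the higher-identity (tighter) window
    if (score > best$score ||
        (score == best$score && score / overlap > best$score / best$overlap)) {
      best <- list(score = score, offset = off, overlap = overlap)
    }
  }
  if (best$score < 0) abort("no alignment offset with sufficient overlap")
  identity <- best$score / best$overlap
  if (identity < min_identity) {
    abort(
      paste0(
        "trace ", chrom$sample_id, "/", chrom$region,
        " unalignable: best identity ", sprintf("%.3f", identity),
        " < ", min_identity, " over ", best$overlap, " calls"
      ),
      class = "sangermeth_alignment_error"
    )
  }
  structure(
    list(
      chrom = chrom, offset = best$offset, matches = best$score,
      mismatches = best$overlap - best$score, identity = identity,
      overlap = best$overlap
    ),
    class = "site_trace_map"
  )
}

#' @export
print.site_trace_map <- function(x, ...) {
  cat("<site_trace_map> offset", x$offset, "| identity",
      sprintf("%.3f", x$identity), "|", x$mismatches, "mismatches\n")
  invisible(x)
}

#' Map panel sites to trace call indices
#'
#' @param map A `site_trace_map` from [align_basecalls()].
#' @param panel Site panel rows for the aligned region.
#' @return The panel with a `call_index` column (NA where the site falls
#'   outside the aligned read).
#' @export
map_sites_to_calls <- function(map, panel) {
  n_calls <- nrow(map$chrom$calls)
  idx <- panel$offset + map$offset
  idx[idx < 0 | idx >= n_calls] <- NA_integer_
  mutate(panel, call_index = as.integer(idx))
}

# IUPAC-aware match between converted-reference and trace basecalls
base_matches <- function(ref, trace) {
  exact <- ref == trace
  y <- ref == "Y" & trace %in% c("C", "T", "Y")
  r <- ref == "R" & trace %in% c("G", "A", "R")
  ty <- trace == "Y" & ref %in% c("C", "T")
  tr <- trace == "R" & ref %in% c("G", "A")
  anyn <- ref == "N" | trace == "N"
  exact | y | r | ty | tr | anyn
}
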