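#' Reference regions for bisulfite Sanger methylation analysis
#'
#' A region table holds one row per analysed amplicon region (e.g. the SNCA
#' promoter, intron 1 and intron 2) with its genomic interval and the
#' analysed-orientation sequence. Coordinates are 0-based half-open
#' internally (BED convention); all rendered reports use 1-based positions.
#' Minus-strand regions are reverse-complemented on load so that `sequence`
#' is always the strand on which sites are enumerated.
#'
#' @param fasta Path to a reference FASTA file.
#' @param bed Path to a BED file naming the regions (columns chrom, start,
#'   end, name, score, strand).
#' @return A tibble with columns `region`, `chrom`, `start`, `end`, `strand`
#'   and `sequence` (uppercase A/C/G/T/N, analysed orientation).
#' @examples
#' \dontrun{
#' regions <- read_regions("reference.fa", "regions.bed")
#' }
#' @export
read_regions <- function(fasta, bed) {
  if (!file.exists(fasta)) abort(paste0("FASTA file not found: ", fasta))
  if (!file.exists(bed)) abort(paste0("BED file not found: ", bed))
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  gr <- rtracklayer::import(bed, format = "BED")
  if (length(gr) == 0) abort("BED file defines no regions")
  purrr::map_dfr(seq_along(gr), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    if (!chrom %in% names(ref)) {
      abort(paste0("BED chromosome '", chrom, "' absent from FASTA"))
    }
    start0 <- GenomicRanges::start(gr)[i] - 1L  # back to 0-based half-open
    end0 <- GenomicRanges::end(gr)[i]
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    seq <- Biostrings::subseq(ref[[chrom]], start = start0 + 1L, end = end0)
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    region_row(
      name = as.character(gr$name[i]), chrom = chrom,
      start = start0, end = end0, strand = strand,
      sequence = as.character(seq)
    )
  })
}

#' Construct a single-region table row
#'
#' Low-level constructor used by [read_regions()] and the synthetic scenario;
#' validates the region invariants (interval length matches the sequence,
#' alphabet is A/C/G/T/N).
#'
#' @param name Region label (free text; `promoter`, `intron1`, `intron2` in
#'   the shipped scenario).
#' @param chrom,start,end,strand Genomic interval, 0-based half-open.
#' @param sequence Analysed-orientation DNA sequence.
#' @return One-row tibble in the [read_regions()] layout.
#' @export
region_row <- function(name, chrom, start, end, strand = "+", sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    abort(paste0("region '", name, "': sequence contains characters outside A/C/G/T/N"))
  }
  if (end - start != nchar(sequence)) {
    abort(paste0(
      "region '", name, "': interval width ", end - start,
      " does not match sequence length ", nchar(sequence)
    ))
  }
  tibble(
    region = name, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand, sequence = sequence
  )
}

#' In-silico bisulfite conversion
#'
#' Applies the bisulfite conversion rule to a sequence: unmethylated
#' cytosines deaminate and are read as thymine after PCR, methylated
#' cytosines are protected and stay cytosine. All other bases are unchanged.
#' The conversion operates on the given strand only.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param methylated_offsets Integer vector of 0-based offsets of protected
#'   (methylated) cytosines. Every offset must index a `C`.
#' @param ambiguity_offsets Optional 0-based offsets of cytosines whose
#'   methylation state is unknown; these are rendered as the IUPAC ambiguity
#'   code `Y` (C or T), the form used when building an alignment reference.
#' @return Converted sequence of the same length.
#' @examples
#' bisulfite_convert("ACGT", integer())  # "ATGT"
#' bisulfite_convert("ACGT", 1L)         # "ACGT" (protected CpG)
#' @export
bisulfite_convert <- function(sequence, methylated_offsets = integer(),
                              ambiguity_offsets = integer()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  methylated_offsets <- as.integer(methylated_offsets)
  ambiguity_offsets <- as.integer(ambiguity_offsets)
  for (off in c(methylated_offsets, ambiguity_offsets)) {
    if (off < 0L || off >= length(chars) || chars[off + 1L] != "C") {
      abort(paste0(
        "offset ", off, " does not index a cytosine (base is '",
        if (off >= 0L && off < length(chars)) chars[off + 1L] else "out of range",
        "')"
      ))
    }
  }
  is_c <- chars == "C"
  protect <- logical(length(chars))
  protect[methylated_offsets + 1L] <- TRUE
  ambig <- logical(length(chars))
  ambig[ambiguity_offsets + 1L] <- TRUE
  chars[is_c & !protect & !ambig] <- "T"
  chars[is_c & ambig] <- "Y"
  paste(chars, collapse = "")
}

#' Enumerate CpG sites in a region
#'
#' Finds every CG dinucleotide on the analysed strand and assigns the
#' field-standard site labels: CpG sites are numbered 1..k in 5'->3' order
#' from the region start ("CpG-1", "CpG-2", ...). Sites whose dinucleotide
#' context contains `N` are excluded with a message.
#'
#' @param region One-row region tibble (see [read_regions()]).
#' @return A site tibble with columns `region`, `kind` ("CpG"), `context`
#'   ("CG"), `local_index`, `letter` (empty), `label`, `offset` (0-based
#'   within the region) and `genomic_pos` (1-based genome coordinate of the
#'   cytosine).
#' @export
enumerate_cpg <- function(region) {
  stopifnot(nrow(region) == 1)
  seq <- region$sequence
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  offs <- which(chars == "C" & c(chars[-1], "") == "G") - 1L
  n_off <- which((chars == "C" & c(chars[-1], "") == "N") |
                   (chars == "N" & c(chars[-1], "") == "G")) - 1L
  if (length(n_off) > 0) {
    inform(paste0(
      "region '", region$region, "': ", length(n_off),
      " CpG-context site(s) with N excluded (offsets ",
      paste(n_off, collapse = ", "), ")"
    ))
  }
  if (length(offs) == 0) return(empty_site_panel())
  gpos <- genomic_position(region, offs)
  tibble(
    region = region$region,
    kind = "CpG",
    context = "CG",
    local_index = seq_along(offs),
    letter = "",
    label = paste0("CpG-", seq_along(offs)),
    offset = offs,
    genomic_pos = gpos
  )
}

#' Enumerate candidate non-CpG (CpH) sites in a region
#'
#' Finds every cytosine followed by A, T or C (mCA/mCT/mCC contexts, the
#' non-CpG methylation contexts of neural tissue). Each candidate is
#' labelled by the local index of the nearest upstream CpG site plus a Latin
#' letter in positional order among the candidates sharing that CpG
#' ("CpG-4A", "CpG-4B", ...). Candidates upstream of the first CpG use
#' index 0. If more than 26 candidates share an upstream CpG, double letters
#' (AA, AB, ...) are used.
#'
#' @param region One-row region tibble.
#' @param cpg_sites Optional precomputed [enumerate_cpg()] result for the
#'   region (computed if missing).
#' @return A site tibble in the [enumerate_cpg()] layout with `kind` "CpH"
#'   and `context` one of CA/CT/CC.
#' @export
enumerate_cph <- function(region, cpg_sites = NULL) {
  stopifnot(nrow(region) == 1)
  if (is.null(cpg_sites)) cpg_sites <- enumerate_cpg(region)
  chars <- strsplit(region$sequence, "", fixed = TRUE)[[1]]
  nxt <- c(chars[-1], "")
  offs <- which(chars == "C" & nxt %in% c("A", "T", "C")) - 1L
  n_off <- which(chars == "C" & nxt == "N") - 1L
  if (length(n_off) > 0) {
    inform(paste0(
      "region '", region$region, "': ", length(n_off),
      " CpH-context site(s) with N excluded (offsets ",
      paste(n_off, collapse = ", "), ")"
    ))
  }
  if (length(offs) == 0) return(empty_site_panel())
  upstream <- purrr::map_int(offs, function(o) {
    hits <- which(cpg_sites$offset < o)
    if (length(hits) == 0) 0L else cpg_sites$local_index[max(hits)]
  })
  gpos <- genomic_position(region, offs)
  out <- tibble(
    region = region$region,
    kind = "CpH",
    context = paste0("C", nxt[offs + 1L]),
    local_index = upstream,
    offset = offs,
    genomic_pos = gpos
  ) |>
    group_by(.data$local_index) |>
    mutate(letter = index_letters(dplyr::n())) |>
    ungroup() |>
    mutate(label = paste0("CpG-", .data$local_index, .data$letter)) |>
    select("region", "kind", "context", "local_index", "letter", "label",
           "offset", "genomic_pos")
  if (any(nchar(out$letter) > 1)) {
    inform(paste0(
      "region '", region$region,
      "': more than 26 CpH candidates after one CpG; double letters used"
    ))
  }
  out
}

#' Build the full site panel for a set of regions
#'
#' Union of [enumerate_cpg()] and [enumerate_cph()] over every region, with a
#' globally unique `site_id` of the form `region:label`. Together the two
#' kinds cover every cytosine of the analysed strand (every C is followed by
#' G, by A/T/C, or ends the sequence).
#'
#' @param regions Region tibble from [read_regions()].
#' @return Site panel tibble ordered by region and offset.
#' @export
site_panel <- function(regions) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    cpg <- enumerate_cpg(reg)
    bind_rows(cpg, enumerate_cph(reg, cpg)) |> arrange(.data$offset)
  }) |>
    mutate(site_id = paste0(.data$region, ":", .data$label)) |>
    select("site_id", dplyr::everything())
}

#' Parse a rendered site label
#'
#' Inverse of the label rendering used by [enumerate_cpg()] /
#' [enumerate_cph()]: `"CpG-45"` gives index 45 with no letter (a CpG),
#' `"CpG-4B"` gives index 4, letter `"B"` (a CpH candidate).
#'
#' @param label Character vector of labels.
#' @return Tibble with columns `label`, `local_index`, `letter`, `kind`.
#' @export
parse_site_label <- function(label) {
  m <- regmatches(label, regexec("^CpG-([0-9]+)([A-Z]*)$", label))
  bad <- lengths(m) != 3
  if (any(bad)) {
    abort(paste0("unparseable site label(s): ", paste(label[bad], collapse = ", ")))
  }
  tibble(
    label = label,
    local_index = as.integer(purrr::map_chr(m, 2)),
    letter = purrr::map_chr(m, 3),
    kind = ifelse(purrr::map_chr(m, 3) == "", "CpG", "CpH")
  )
}

#' Validate a bisulfite PCR primer pair
#'
#' After full bisulfite conversion the template's plus strand has no
#' cytosines outside protected positions, so a well-designed forward primer
#' (annealing to the converted sense strand) contains no C, and a reverse
#' primer (annealing to its complement) contains no G. Primer pairs
#' violating this would only amplify unconverted or methylated template.
#'
#' @param forward,reverse Primer sequences (A/C/G/T).
#' @param region Optional region label carried through to the result.
#' @return One-row tibble with `region`, `forward`, `reverse`, `pass` and a
#'   list-column `reasons` naming each violating base and 1-based position.
#' @examples
#' validate_bisulfite_primers("TAGAAGGGGTTGAAGAAGAAAATTG",
#'                            "AAACTCAACAAATCCTCTTTCCA")$pass
#' @export
validate_bisulfite_primers <- function(forward, reverse, region = NA_character_) {
  check <- function(p, name) {
    if (!grepl("^[ACGT]+$", toupper(p))) {
      abort(paste0(name, " primer contains non-ACGT characters: ", p))
    }
  }
  check(forward, "forward")
  check(reverse, "reverse")
  fwd <- strsplit(toupper(forward), "")[[1]]
  rev <- strsplit(toupper(reverse), "")[[1]]
  reasons <- c(
    purrr::map_chr(which(fwd == "C"),
                   ~ paste0("forward position ", .x, " is C (unconverted template)")),
    purrr::map_chr(which(rev == "G"),
                   ~ paste0("reverse position ", .x, " is G (unconverted template)"))
  )
  tibble(
    region = region, forward = toupper(forward), reverse = toupper(reverse),
    pass = length(reasons) == 0, reasons = list(reasons)
  )
}

#' Published SNCA bisulfite primer panel
#'
#' The five primer pairs used for the SNCA promoter, intron 1 (three
#' overlapping amplicons) and intron 2 bisulfite amplicons, as printed in
#' the source study's primer table; provided as package data for the primer
#' design check.
#'
#' @return Tibble with columns `region`, `forward`, `reverse`.
#' @export
snca_primers <- function() {
  tibble::tribble(
    ~region, ~forward, ~reverse,
    "promoter", "TAGAAGGGGTTGAAGAAGAAAATTG", "AAACTCAACAAATCCTCTTTCCA",
    "intron1_1", "GTTTAAGGAAAGAGATTTGATTTGG", "TTACCACCTATTAACTTAACCTC",
    "intron1_2", "GAGGTTAAGTTAATAGGTGGTAA", "AAATATCCTTAACATAAATCCCAAAA",
    "intron1_3", "TTTTGGGATTTATGTTAAGGATATTT", "ATAACTAATAAATTCCTTTACACCAC",
    "intron2", "GTTTGTTAAAAAGGTGGATTGAGT", "CTTTATACACATCACAAAAACATATC"
  )
}

#' Export a site panel to CSV
#'
#' @param panel Site panel from [site_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_panel <- function(panel, path) {
  panel |>
    mutate(genomic_pos_1based = .data$genomic_pos) |>
    select("site_id", "region", "label", "kind", "context", "genomic_pos_1based") |>
    readr::write_csv(path)
  invisible(path)
}

# 1-based genome coordinate of the cytosine at analysed-strand offset `off`.
# Plus strand: start is 0-based, so position = start + off + 1; minus strand:
# offset 0 sits at the interval's high end, position = end - off.
genomic_position <- function(region, off) {
  if (region$strand == "-") region$end - off else region$start + off + 1L
}

empty_site_panel <- function() {
  tibble(
    region = character(), kind = character(), context = character(),
    local_index = integer(), letter = character(), label = character(),
    offset = integer(), genomic_pos = integer()
  )
}

# A..Z then AA, AB, ... for the rare dense candidate runs
index_letters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- n - 26
  doubles <- paste0(
    LETTERS[rep(seq_len(ceiling(extra / 26)), each = 26)[seq_len(extra)]],
    LETTERS[((seq_len(extra) - 1) %% 26) + 1]
  )
  c(LETTERS, doubles)
}
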