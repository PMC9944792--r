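# Shared fixtures, all built in code.

# single plus-strand region wrapper around a raw sequence
fixture_region <- function(sequence, name = "reg", start = 100L) {
  region_row(name, "chrFix", start, start + nchar(sequence), "+", sequence)
}

# deterministic random DNA without Ns
fixture_random_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# a small region with a handful of CpG sites and CpH controls:
# offsets: CpG at 2, 10, 18, 26; CpH controls in between
fixture_small_region <- function() {
  fixture_region(paste0(
    "TT", "CG", "TTT", "CAT",     # CpG-1 at 2; CpH 1A at 7
    "CG", "TTT", "CTT",           # CpG-2 at 10; 2A at 15
    "CG", "TTT", "CAT",           # CpG-3 at 18; 3A at 23
    "CG", "TTTT"                  # CpG-4 at 26
  ), name = "mini")
}

# simulate + quantify helper for round-trip style tests
fixture_quantified <- function(truth_cpg, sigma = 0, efficiency = 1,
                               seed = 1, correction = TRUE, strand = "forward") {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  truth <- setNames(rep(0, nrow(panel)), panel$site_id)
  cpg_ids <- panel$site_id[panel$kind == "CpG"]
  truth[cpg_ids] <- truth_cpg
  chrom <- withr::with_seed(seed, simulate_trace(
    truth, reg, panel, "fix1", sigma = sigma, efficiency = efficiency,
    strand = strand
  ))
  prof <- quantify_sample(chrom, panel, converted_reference(reg, panel),
                          correction = correction, min_overlap = 10L)
  list(region = reg, panel = panel, truth = truth, profile = prof,
       cpg_ids = cpg_ids)
}

# cohort matrix with a known group shift at selected sites
fixture_matrix <- function(n_per_group = 20, shift_sites = character(),
                           shift = 25, seed = 42) {
  reg <- fixture_small_region()
  panel <- site_panel(reg)
  withr::with_seed(seed, {
    groups <- rep(c("A", "B"), each = n_per_group)
    mat <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_along(groups)),
      group = groups
    )
    for (sid in panel$site_id) {
      base <- stats::runif(length(groups), 20, 60)
      if (sid %in% shift_sites) base[groups == "B"] <- base[groups == "B"] + shift
      mat[[sid]] <- pmin(pmax(base, 0), 100)
    }
    mat
  })
}
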