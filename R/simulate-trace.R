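#' Simulate a bisulfite Sanger chromatogram for one sample and region
#'
#' Generative inverse of the peak-ratio quantification. At every panel
#' cytosine with methylation fraction `m` (percent/100) the C channel
#' receives `S * (m + (1 - eff) * (1 - m))` — protected signal plus the
#' unconverted residual — and the T channel `S * eff * (1 - m)`, each
#' perturbed by an independent multiplicative noise factor
#' `1 + eps, eps ~ N(0, sigma)` truncated at -0.9. Non-candidate calls get
#' their single converted-base channel at full signal; every silent channel
#' carries a small cross-talk baseline. Panel CpH sites without an assigned
#' value act as pure conversion controls (`m = 0`). Basecalls are the
#' maximal channel. Reverse-direction traces are generated forward and then
#' complement-flipped.
#'
#' @param values Named numeric vector `site_id -> percent` for the region's
#'   sites; missing panel sites default to 0.
#' @param region One-row region tibble.
#' @param panel Site panel rows for the region.
#' @param sample_id Sample identifier written into the header.
#' @param total_signal Mean full-channel signal S (default 1000 RFU).
#' @param sigma Multiplicative channel noise SD (default 0.02).
#' @param efficiency Bisulfite conversion efficiency (default 0.98).
#' @param crosstalk Baseline fraction of S on silent channels (default
#'   0.01).
#' @param strand `"forward"` or `"reverse"` sequencing direction.
#' @return A `chromatogram`.
#' @export
simulate_trace <- function(values, region, panel, sample_id,
                           total_signal = 1000, sigma = 0.02,
                           efficiency = 0.98, crosstalk = 0.01,
                           strand = "forward") {
  stopifnot(nrow(region) == 1)
  chars <- strsplit(region$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  m_frac <- rep(NA_real_, n)
  at <- panel$offset + 1L
  m_site <- values[panel$site_id]
  m_site[is.na(m_site)] <- 0
  stopifnot(all(m_site >= 0 & m_site <= 100))
  m_frac[at] <- m_site / 100

  noise <- function(k) pmax(1 + rnorm(k, 0, sigma), 0.1)
  H <- matrix(total_signal * crosstalk * noise(4L * n), nrow = n,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  is_site <- !is.na(m_frac)
  k <- sum(is_site)
  H[is_site, "C"] <- total_signal *
    (m_frac[is_site] + (1 - efficiency) * (1 - m_frac[is_site])) * noise(k)
  H[is_site, "T"] <- total_signal * efficiency * (1 - m_frac[is_site]) * noise(k)
  plain <- !is_site
  conv_base <- chars
  conv_base[plain & chars == "C"] <- "T"  # non-candidate C (none if panel complete)
  for (b in c("A", "C", "G", "T")) {
    sel <- plain & conv_base == b
    H[sel, b] <- total_signal * noise(sum(sel))
  }
  base <- c("A", "C", "G", "T")[max.col(H, ties.method = "first")]
  chrom <- chromatogram(
    sample_id = sample_id, region = region$region, strand = "forward",
    calls = tibble(
      call_index = seq_len(n) - 1L, base = base,
      H_A = H[, "A"], H_C = H[, "C"], H_G = H[, "G"], H_T = H[, "T"]
    )
  )
  if (strand == "reverse") chrom <- flip_chromatogram(chrom) else chrom
}
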