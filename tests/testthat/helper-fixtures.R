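# Shared fixtures: tiny genomes and deterministic switch profiles.

toy_genome <- function() {
  genome_model(c(chr1 = 2e8, chr2 = 1.5e8, chr3 = 1e8),
               centromeres = data.frame(chrom = c("chr1", "chr2", "chr3"),
                                        start = c(9e7, 7e7, 4e7),
                                        end = c(9.5e7, 7.5e7, 4.5e7)))
}

# A single-chromosome profile with exactly k state switches, evenly spaced
# across `span`, alternating between `n_states` distinct states.
make_switch_profile <- function(k, span = 4e7, chrom_len = 2e8,
                                offset = 8e7, n_states = 2,
                                sample = "s1", chrom = "chr1") {
  boundaries <- if (k == 0) numeric(0)
    else if (k == 1) offset
    else round(seq(offset, offset + span, length.out = k))
  bounds <- c(0, boundaries, chrom_len)
  states <- rep(c(2, seq_len(n_states - 1) + 2), length.out = length(bounds) - 1)
  data.frame(sample = sample, chrom = chrom,
             start = bounds[-length(bounds)], end = bounds[-1],
             copy_number = states, state = states,
             stringsAsFactors = FALSE)
}

# Brute-force densest-window oracle: enumerate every switch index pair.
best_window_brute <- function(positions, window) {
  n <- length(positions)
  if (n == 0) return(0L)
  best <- 0L
  for (i in seq_len(n)) for (j in i:n)
    if (positions[j] - positions[i] <= window) best <- max(best, j - i + 1L)
  best
}

# Minimal call-table row for constructing fixtures.
call_row <- function(sample, chrom, start = 0, end = 3e7,
                     confidence = "high", n_switches = 12, n_states = 2) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             n_switches = n_switches, confidence = confidence,
             n_states = n_states, canonical = n_states <= 3,
             telomere = FALSE, centromere = FALSE, stringsAsFactors = FALSE)
}
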