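#' Chromothripsis prevalence per tumour entity
#'
#' @param calls chromothripsis call table.
#' @param metadata sample metadata with `sample` and `entity` columns; every
#'   metadata sample counts toward the denominator.
#' @param tier lowest confidence tier counting as positive.
#' @param min_cases entities with fewer cases are reported separately
#'   instead of in the main table.
#' @return list with `by_entity` (entities with at least `min_cases` cases:
#'   n, n positive, prevalence %), `small_entities` (the rest) and `overall`
#'   (cohort-wide prevalence % at each tier).
#' @export
prevalence <- function(calls, metadata, tier = "high", min_cases = 5) {
  pos <- positive_samples(calls, tier)
  tab <- do.call(rbind, lapply(split(metadata$sample, metadata$entity),
    function(s) data.frame(n = length(s), n_positive = sum(s %in% pos))))
  tab <- data.frame(entity = rownames(tab), tab, stringsAsFactors = FALSE)
  tab$prevalence <- 100 * tab$n_positive / tab$n
  rownames(tab) <- NULL
  overall <- vapply(c("high", "intermediate", "low"), function(t)
    100 * length(positive_samples(calls, t)) / nrow(metadata), numeric(1))
  list(by_entity = tab[tab$n >= min_cases, , drop = FALSE],
       small_entities = tab[tab$n < min_cases, , drop = FALSE],
       overall = data.frame(tier = names(overall),
                            prevalence = unname(overall)))
}

#' Two-hit contrast: somatic loss of the wild-type allele versus
#' chromothripsis in germline-variant carriers
#'
#' Restricted to carriers of a pathogenic germline variant, tests the 2x2
#' table (second hit yes/no x chromothripsis yes/no) with a two-sided
#' Fisher exact test.
#'
#' @param metadata sample metadata with `germline_gene` and `second_hit`.
#' @param calls chromothripsis call table.
#' @param tier lowest tier counting as positive.
#' @return list with `table`, `p`, per-group prevalence (%), and a
#'   `degenerate` flag set when a stratum is empty.
#' @export
two_hit_contrast <- function(metadata, calls, tier = "high") {
  carriers <- metadata[!is.na(metadata$germline_gene) &
                         metadata$germline_gene != "", , drop = FALSE]
  pos <- positive_samples(calls, tier)
  second <- factor(carriers$second_hit, levels = c(TRUE, FALSE),
                   labels = c("second-hit", "no-second-hit"))
  ct <- factor(carriers$sample %in% pos, levels = c(TRUE, FALSE),
               labels = c("chromothripsis", "negative"))
  tab <- table(second, ct)
  degenerate <- any(rowSums(tab) == 0)
  p <- if (degenerate) NA_real_ else stats::fisher.test(tab)$p.value
  if (degenerate) warning("empty stratum in two-hit table")
  list(table = tab, p = p,
       prevalence = 100 * prop.table(tab, 1)[, "chromothripsis"],
       degenerate = degenerate)
}

#' Chromothripsis prevalence by telomere-maintenance group
#'
#' Groups samples into TERT gain, ATRX/DAXX truncation, and neither, then
#' compares the chromothripsis-positive proportion of each altered group
#' against the "neither" group with pairwise Pearson chi-square tests
#' (high + intermediate tier by default).
#'
#' @param metadata sample metadata with `tert_status` and
#'   `atrx_daxx_trunc`.
#' @param calls chromothripsis call table.
#' @param tier lowest tier counting as positive.
#' @param correct apply the Yates continuity correction.
#' @return data.frame with one row per group: n, n positive, prevalence %,
#'   and the chi-square p versus "neither" (NA, flagged, when degenerate).
#' @export
tert_atrx_contrast <- function(metadata, calls, tier = "intermediate",
                               correct = FALSE) {
  pos <- positive_samples(calls, tier)
  group <- ifelse(metadata$tert_status == "gain", "TERT-gain",
           ifelse(metadata$atrx_daxx_trunc, "ATRX-trunc", "neither"))
  ct <- metadata$sample %in% pos
  res <- do.call(rbind, lapply(c("TERT-gain", "ATRX-trunc", "neither"),
    function(g) {
      sel <- group == g
      data.frame(group = g, n = sum(sel), n_positive = sum(ct[sel]),
                 prevalence = 100 * mean(ct[sel]), stringsAsFactors = FALSE)
    }))
  res$p_vs_neither <- NA_real_
  for (g in c("TERT-gain", "ATRX-trunc")) {
    sel <- group %in% c(g, "neither")
    tab <- table(factor(group[sel], levels = c(g, "neither")), ct[sel])
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0)) {
      warning("degenerate table for group ", g)
    } else {
      res$p_vs_neither[res$group == g] <-
        suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
    }
  }
  res
}

#' Genome-wide gain/loss frequency profiles by chromothripsis status
#'
#' Bins the genome and reports, per bin and per group (chromothripsis
#' positive/negative), the fraction of samples carrying a gain
#' (state > baseline) or a loss (state < baseline) overlapping the bin.
#'
#' @param segments cohort segment table.
#' @param calls chromothripsis call table.
#' @param genome a `genome_model`.
#' @param bin_size bin width in bp.
#' @param tier lowest tier counting as positive.
#' @param baseline ploidy baseline (default 2).
#' @return data.frame with `chrom`, `start`, `end`, `group`, `n_samples`,
#'   `gain_freq`, `loss_freq`.
#' @export
gainloss_profiles <- function(segments, calls, genome, bin_size = 1e7,
                              tier = "high", baseline = 2) {
  pos <- positive_samples(calls, tier)
  samples <- unique(segments$sample)
  group <- ifelse(samples %in% pos, "chromothripsis", "negative")
  bins <- do.call(rbind, lapply(seq_len(nrow(genome$chroms)), function(i) {
    L <- genome$chroms$length[i]
    s <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = genome$chroms$chrom[i], start = s,
               end = pmin(s + bin_size, L), stringsAsFactors = FALSE)
  }))
  aberrant <- segments[segments$state != baseline, , drop = FALSE]
  out <- lapply(unique(group), function(g) {
    gs <- samples[group == g]
    b <- bins
    b$group <- g
    b$n_samples <- length(gs)
    sub <- aberrant[aberrant$sample %in% gs, , drop = FALSE]
    b$gain_freq <- bin_freq(b, sub[sub$state > baseline, ], length(gs))
    b$loss_freq <- bin_freq(b, sub[sub$state < baseline, ], length(gs))
    b
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Fraction of samples with at least one overlapping aberrant segment per bin.
bin_freq <- function(bins, segs, n_samples) {
  if (n_samples == 0 || nrow(segs) == 0) return(rep(0, nrow(bins)))
  vapply(seq_len(nrow(bins)), function(i) {
    sel <- segs$chrom == bins$chrom[i] &
      intervals_overlap(segs$start, segs$end, bins$start[i], bins$end[i])
    length(unique(segs$sample[sel])) / n_samples
  }, numeric(1))
}

#' Signature-exposure contrast between chromothripsis groups
#'
#' Two-sided Wilcoxon rank-sum tests on log2(exposure + pseudo-count),
#' Bonferroni-corrected across the tested signatures.
#'
#' @param metadata sample metadata containing one numeric column per
#'   signature.
#' @param calls chromothripsis call table.
#' @param signatures signature column names to test.
#' @param tier lowest tier counting as positive.
#' @param pseudo pseudo-count added before the log2 transform.
#' @return data.frame per signature: group medians of the transformed
#'   exposure, `p`, `p_adj` and a `note` for constant exposures.
#' @export
signature_contrast <- function(metadata, calls, signatures,
                               tier = "high", pseudo = 1) {
  pos <- metadata$sample %in% positive_samples(calls, tier)
  if (all(pos) || !any(pos)) stop("one chromothripsis group is empty")
  out <- lapply(signatures, function(sig) {
    x <- metadata[[sig]]
    if (is.null(x)) stop("no exposure column '", sig, "' in metadata")
    if (any(x < 0)) stop("negative exposures for ", sig)
    lx <- log2(x + pseudo)
    if (stats::var(lx) == 0)
      return(data.frame(signature = sig,
                        median_positive = stats::median(lx[pos]),
                        median_negative = stats::median(lx[!pos]),
                        p = NA_real_, note = "constant exposures",
                        stringsAsFactors = FALSE))
    w <- stats::wilcox.test(lx[pos], lx[!pos], exact = FALSE)
    data.frame(signature = sig, median_positive = stats::median(lx[pos]),
               median_negative = stats::median(lx[!pos]), p = w$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_adj <- pmin(res$p * length(signatures), 1)
  rownames(res) <- NULL
  res
}

#' Longitudinal scenario of one matched sample pair
#'
#' Compares the chromothriptic chromosome sets of two timepoints:
#' both negative gives "both-negative"; positive only at the first,
#' "lost"; only at the second, "gained"; positive at both with identical
#' chromosome sets, "stable"; with differing sets, "changed". With
#' `jaccard < 1`, "stable" is relaxed to a Jaccard similarity of at least
#' that value.
#'
#' @param chroms_t1,chroms_t2 chromothriptic chromosome sets of the two
#'   timepoints (character vectors, possibly empty).
#' @param jaccard similarity threshold for "stable" (default 1: set
#'   equality).
#' @return one of "both-negative", "lost", "gained", "stable", "changed".
#' @export
longitudinal_verdict <- function(chroms_t1, chroms_t2, jaccard = 1) {
  p1 <- length(chroms_t1) > 0
  p2 <- length(chroms_t2) > 0
  if (!p1 && !p2) return("both-negative")
  if (p1 && !p2) return("lost")
  if (!p1 && p2) return("gained")
  jac <- length(intersect(chroms_t1, chroms_t2)) /
    length(union(chroms_t1, chroms_t2))
  if (jac >= jaccard) "stable" else "changed"
}

#' Classify longitudinal evolution for a table of matched pairs
#'
#' @param calls chromothripsis call table covering both timepoints.
#' @param pairs data.frame with columns `patient`, `sample_t1`,
#'   `sample_t2`.
#' @param metadata optional metadata; when given, both samples of a pair
#'   must share the pair's patient id (mismatch is an error).
#' @param tier lowest tier defining a chromothriptic chromosome.
#' @param jaccard passed to [longitudinal_verdict()].
#' @return `pairs` with an added `verdict` column.
#' @export
classify_longitudinal <- function(calls, pairs, metadata = NULL,
                                  tier = "high", jaccard = 1) {
  if (!is.null(metadata)) {
    pt1 <- metadata$patient[match(pairs$sample_t1, metadata$sample)]
    pt2 <- metadata$patient[match(pairs$sample_t2, metadata$sample)]
    if (any(pt1 != pairs$patient | pt2 != pairs$patient, na.rm = TRUE))
      stop("sample/patient mismatch in pair table")
  }
  pairs$verdict <- vapply(seq_len(nrow(pairs)), function(i) {
    longitudinal_verdict(
      chromothriptic_chroms(calls, pairs$sample_t1[i], tier),
      chromothriptic_chroms(calls, pairs$sample_t2[i], tier),
      jaccard)
  }, character(1))
  pairs
}
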