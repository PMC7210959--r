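#' Scoring thresholds for chromothripsis inference
#'
#' Defaults reproduce the study-standard visual-scoring tiers: 10 or more
#' switches between copy-number states within 50 Mb are called with high
#' confidence, 8-9 with intermediate and 6-7 with low confidence.
#'
#' @param window window span in bp within which switches are counted
#'   (inclusive span between first and last switch).
#' @param high,intermediate,low lower switch-count bound of each tier.
#' @param canonical_max_states maximum number of distinct copy-number states
#'   for a region to be labelled canonical.
#' @param telomere_margin distance (bp) from a chromosome end within which a
#'   region is annotated as telomere-involved.
#' @return a list of thresholds used by the scoring functions.
#' @export
score_thresholds <- function(window = 5e7, high = 10, intermediate = 8,
                             low = 6, canonical_max_states = 3,
                             telomere_margin = 1e6) {
  stopifnot(window > 0, low >= 1, intermediate > low, high > intermediate)
  list(window = window, high = high, intermediate = intermediate, low = low,
       canonical_max_states = canonical_max_states,
       telomere_margin = telomere_margin)
}

tier_rank <- c(low = 1, intermediate = 2, high = 3)

#' Count switches between copy-number states
#'
#' Runs of adjacent segments sharing the same integer state are merged first;
#' every boundary between merged segments with different states is one
#' switch, located at the start of the downstream segment.
#'
#' @param segments segments of one sample on one chromosome (sorted,
#'   non-overlapping, with integer `state`).
#' @return numeric vector of switch positions (bp), strictly increasing;
#'   length 0 when the chromosome has a single state.
#' @export
count_switches <- function(segments) {
  n <- nrow(segments)
  if (n == 0) return(numeric(0))
  if (length(unique(segments$sample)) > 1 ||
      length(unique(segments$chrom)) > 1)
    stop("count_switches expects segments of a single sample and chromosome")
  if (is.unsorted(segments$start, strictly = TRUE) ||
      any(segments$start[-1] < segments$end[-n]))
    stop("segments must be sorted and non-overlapping")
  st <- segments$state
  change <- which(st[-1] != st[-n])
  segments$start[change + 1]
}

#' Densest switch window
#'
#' Finds the largest number of consecutive switch positions whose inclusive
#' span (last - first) is at most `window`; ties are broken by the leftmost
#' window.
#'
#' @param positions sorted switch positions (bp).
#' @param window window span in bp.
#' @return list with `count`, `start`, `end` (NA when there are no switches).
#' @export
best_window <- function(positions, window = 5e7) {
  stopifnot(window > 0)
  n <- length(positions)
  if (n == 0) return(list(count = 0L, start = NA_real_, end = NA_real_))
  if (is.unsorted(positions, strictly = TRUE))
    stop("switch positions must be strictly increasing")
  best <- 0L; bs <- NA_real_; be <- NA_real_
  i <- 1L
  for (j in seq_len(n)) {
    while (positions[j] - positions[i] > window) i <- i + 1L
    cnt <- j - i + 1L
    if (cnt > best) { best <- cnt; bs <- positions[i]; be <- positions[j] }
  }
  list(count = best, start = bs, end = be)
}

# For each switch index i, the largest j with positions[j]-positions[i]<=window.
window_reach <- function(positions, window) {
  n <- length(positions)
  reach <- integer(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && positions[j + 1] - positions[i] <= window) j <- j + 1L
    reach[i] <- j
  }
  reach
}

#' Score one chromosome of one sample for chromothripsis
#'
#' Counts state switches, finds the densest window, assigns a confidence
#' tier, and annotates the call region: number of distinct copy-number
#' states (canonical when at most 3), centromere overlap and proximity to a
#' chromosome end. Switch clusters separated by more than one window span
#' are reported as separate calls.
#'
#' @param segments segments of one sample on one chromosome.
#' @param genome a `genome_model` containing the chromosome.
#' @param thresholds a [score_thresholds()] list.
#' @return data.frame of calls (0 or more rows) with columns `sample`,
#'   `chrom`, `start`, `end`, `n_switches`, `confidence`, `n_states`,
#'   `canonical`, `telomere`, `centromere`.
#' @export
score_chromosome <- function(segments, genome, thresholds = score_thresholds()) {
  th <- thresholds
  empty <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_switches = numeric(), confidence = character(),
                      n_states = numeric(), canonical = logical(),
                      telomere = logical(), centromere = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0) return(empty)
  chrom <- unique(segments$chrom)
  clen <- chrom_length(genome, chrom)  # errors if chromosome unknown
  pos <- count_switches(segments)
  n <- length(pos)
  if (n < th$low) return(empty)
  reach <- window_reach(pos, th$window)
  counts <- reach - seq_len(n) + 1L
  # switches lying in at least one window that meets the lowest tier
  qual <- rep(FALSE, n)
  for (i in which(counts >= th$low)) qual[i:reach[i]] <- TRUE
  if (!any(qual)) return(empty)
  qpos <- pos[qual]
  # split qualifying switches into clusters more than one window span apart
  cluster <- cumsum(c(1, diff(qpos) > th$window))
  calls <- lapply(split(qpos, cluster), function(p) {
    bw <- best_window(p, th$window)
    m <- bw$count
    if (m < th$low) return(NULL)
    tier <- if (m >= th$high) "high" else
            if (m >= th$intermediate) "intermediate" else "low"
    tmin <- th[[tier]]
    r <- window_reach(p, th$window)
    k <- r - seq_along(p) + 1L
    keep <- rep(FALSE, length(p))
    for (i in which(k >= tmin)) keep[i:r[i]] <- TRUE
    region <- c(min(p[keep]), max(p[keep]))
    ov <- intervals_overlap(segments$start, segments$end, region[1], region[2])
    n_states <- length(unique(segments$state[ov]))
    cen <- centromere_interval(genome, chrom)
    data.frame(
      sample = segments$sample[1], chrom = chrom,
      start = region[1], end = region[2],
      n_switches = m, confidence = tier, n_states = n_states,
      canonical = n_states <= th$canonical_max_states,
      telomere = region[1] <= th$telomere_margin |
                 region[2] >= clen - th$telomere_margin,
      centromere = !is.null(cen) &&
                   intervals_overlap(region[1], region[2], cen["start"], cen["end"]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Score all chromosomes of one sample
#'
#' @param segments all segments of one sample.
#' @inheritParams score_chromosome
#' @return list with `calls` (rbind of per-chromosome calls) and `summary`
#'   (one-row data.frame: per-tier positivity, number of chromothriptic
#'   chromosomes, multi-chromosome and heavy (>3 chromosomes) flags,
#'   any-telomere / any-centromere involvement).
#' @export
score_sample <- function(segments, genome, thresholds = score_thresholds()) {
  stopifnot(length(unique(segments$sample)) <= 1)
  calls <- do.call(rbind, lapply(split(segments, segments$chrom),
                                 score_chromosome, genome = genome,
                                 thresholds = thresholds))
  if (is.null(calls)) calls <- score_chromosome(segments[0, ], genome, thresholds)
  calls <- calls[order(match(calls$chrom, genome$chroms$chrom), calls$start), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  rk <- tier_rank[calls$confidence]
  nchrom <- length(unique(calls$chrom))
  summary <- data.frame(
    sample = if (nrow(segments)) segments$sample[1] else NA_character_,
    positive_high = any(rk >= tier_rank["high"]),
    positive_intermediate = any(rk >= tier_rank["intermediate"]),
    positive_low = any(rk >= tier_rank["low"]),
    n_chromosomes = nchrom,
    multi_chromosome = nchrom > 1,
    heavy = nchrom > 3,
    any_telomere = any(calls$telomere),
    any_centromere = any(calls$centromere),
    stringsAsFactors = FALSE)
  list(calls = calls, summary = summary)
}

#' Score a multi-sample cohort
#'
#' @param segments segment table covering any number of samples.
#' @inheritParams score_chromosome
#' @return list with `calls` (all samples) and `summaries` (one row per
#'   sample).
#' @export
score_cohort <- function(segments, genome, thresholds = score_thresholds()) {
  per <- lapply(split(segments, segments$sample), score_sample,
                genome = genome, thresholds = thresholds)
  calls <- do.call(rbind, lapply(per, `[[`, "calls"))
  summaries <- do.call(rbind, lapply(per, `[[`, "summary"))
  rownames(calls) <- rownames(summaries) <- NULL
  list(calls = calls, summaries = summaries)
}

# Samples positive at a tier ("high" counts for "intermediate" etc.).
positive_samples <- function(calls, tier = "high") {
  stopifnot(tier %in% names(tier_rank))
  unique(calls$sample[tier_rank[calls$confidence] >= tier_rank[tier]])
}

# Chromothriptic chromosome set of one sample at a tier.
chromothriptic_chroms <- function(calls, sample, tier = "high") {
  sel <- calls$sample == sample &
    tier_rank[calls$confidence] >= tier_rank[tier]
  unique(calls$chrom[sel])
}
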