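#' Place size-matched random regions on the genome
#'
#' Samples one random, non-overlapping genomic interval per requested size:
#' the start is uniform over all feasible start positions across the
#' autosome + X pool (chromosomes are therefore chosen with probability
#' proportional to their feasible length), and region sizes are preserved
#' exactly. Non-overlap is enforced within the supplied size set (one
#' tumour's regions), not across tumours.
#'
#' @param sizes region sizes in bp (one tumour's chromothriptic regions).
#' @param genome a `genome_model`.
#' @param exclude chromosome names excluded from the pool (default the Y
#'   chromosome).
#' @param max_tries rejection-sampling attempts before giving up.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
sample_null_regions <- function(sizes, genome, exclude = c("chrY", "Y"),
                                max_tries = 1000) {
  pool <- genome$chroms[!(genome$chroms$chrom %in% exclude), , drop = FALSE]
  if (any(sizes > max(pool$length)))
    stop("region size exceeds every chromosome in the pool")
  if (sum(sizes) > sum(pool$length))
    stop("region sizes cannot be packed into the genome")
  sizes <- sort(sizes, decreasing = TRUE)
  if (length(sizes) == 1) {  # fast path: no packing constraint
    feas <- pmax(pool$length - sizes + 1, 0)
    ci <- sample.int(nrow(pool), 1, prob = feas)
    s <- floor(stats::runif(1) * feas[ci])
    return(data.frame(chrom = pool$chrom[ci], start = s, end = s + sizes,
                      stringsAsFactors = FALSE))
  }
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  for (sz in sizes) {
    feas <- pmax(pool$length - sz + 1, 0)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(nrow(pool), 1, prob = feas)
      s <- floor(stats::runif(1) * feas[ci])
      e <- s + sz
      clash <- placed$chrom == pool$chrom[ci] &
        intervals_overlap(placed$start, placed$end, s, e)
      if (!any(clash)) {
        placed <- rbind(placed, data.frame(chrom = pool$chrom[ci], start = s,
                                           end = e, stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place non-overlapping regions after ",
                  max_tries, " tries")
  }
  rownames(placed) <- NULL
  placed
}

#' Permutation test for per-chromosome enrichment of chromothriptic events
#'
#' For each tumour, regions of exactly the observed sizes are re-placed at
#' random (see [sample_null_regions()]); events are counted per chromosome
#' in every permutation. Under the default "peak" success rule a permutation
#' counts as a success for chromosome `c` when its maximum per-chromosome
#' event count is greater than or equal to the observed count on `c`; the
#' "per-chromosome" rule compares the permuted count on `c` itself. The
#' empirical p-value uses the add-one correction
#' `p = (1 + successes) / (1 + N)` and is Bonferroni-adjusted across
#' chromosomes.
#'
#' @param calls chromothripsis call table of one tumour entity.
#' @param genome a `genome_model`.
#' @param n_perm number of permutations.
#' @param mode "peak" (default) or "per-chromosome".
#' @param tier lowest confidence tier included (default pools high and
#'   intermediate calls).
#' @param min_cases minimum number of chromothripsis-positive cases required
#'   to run the test.
#' @param seed optional integer seed.
#' @param exclude chromosomes excluded from the null pool.
#' @return object of class `enrichment_result`: data.frame with per-
#'   chromosome `observed`, `p` and `p_adj`, with attributes `n_perm` and
#'   `mode`.
#' @export
enrichment_test <- function(calls, genome, n_perm = 50000,
                            mode = c("peak", "per-chromosome"),
                            tier = "intermediate", min_cases = 10,
                            seed = NULL, exclude = c("chrY", "Y")) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  keep <- tier_rank[calls$confidence] >= tier_rank[tier]
  calls <- calls[keep, , drop = FALSE]
  n_cases <- length(unique(calls$sample))
  if (n_cases <= min_cases)
    stop("entity has ", n_cases, " positive cases; more than ", min_cases,
         " required")
  pool <- genome$chroms$chrom[!(genome$chroms$chrom %in% exclude)]
  observed <- vapply(pool, function(ch) sum(calls$chrom == ch), numeric(1))
  sizes_by_sample <- split(calls$end - calls$start, calls$sample)
  succ <- setNames(numeric(length(pool)), pool)
  for (b in seq_len(n_perm)) {
    counts <- setNames(numeric(length(pool)), pool)
    for (sz in sizes_by_sample) {
      pl <- sample_null_regions(sz, genome, exclude = exclude)
      tab <- table(pl$chrom)
      counts[names(tab)] <- counts[names(tab)] + tab
    }
    if (mode == "peak") {
      succ <- succ + (max(counts) >= observed)
    } else {
      succ <- succ + (counts >= observed)
    }
  }
  res <- data.frame(chrom = pool, observed = unname(observed),
                    p = unname((1 + succ) / (1 + n_perm)),
                    stringsAsFactors = FALSE)
  res$p_adj <- pmin(res$p * nrow(res), 1)
  attr(res, "n_perm") <- n_perm
  attr(res, "mode") <- mode
  class(res) <- c("enrichment_result", "data.frame")
  res
}
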