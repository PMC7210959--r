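#' Default TERT locus (GRCh37)
#'
#' @return list with `chrom`, `start`, `end` (chr5:1,253,282-1,295,184).
#' @export
tert_locus <- function() list(chrom = "chr5", start = 1253282, end = 1295184)

#' Genome walking from a locus over structural-variant adjacencies
#'
#' Scans outward from the locus in both directions along the chromosome.
#' Every structural-variant breakend encountered within the remaining
#' distance budget may be traversed (one hop): the walk jumps to the partner
#' breakend and continues in the orientation implied by the join (a head
#' partner breakend continues toward decreasing coordinates, a tail breakend
#' toward increasing ones). At most `max_hops` SVs are followed per
#' direction and the cumulative intra-chromosomal scanned distance is capped
#' at `max_dist`; the jump itself adds no distance. The walk is linked when,
#' after at least one SV traversal, a visited breakend or scanned interval
#' overlaps a chromothriptic region.
#'
#' @param svs structural variants of one sample (validated table).
#' @param regions data.frame of chromothriptic regions with columns `chrom`,
#'   `start`, `end` (e.g. the sample's rows of a call table).
#' @param genome a `genome_model`.
#' @param locus list with `chrom`, `start`, `end`; default [tert_locus()].
#' @param max_hops maximum SV traversals per direction.
#' @param max_dist maximum cumulative walked distance in bp.
#' @return list of class `walk_result` with `linked` (logical) and `paths`
#'   (data.frame of linking paths: SV ids, hop count, cumulative walked
#'   distance and terminal interval).
#' @export
walk_from_locus <- function(svs, regions, genome, locus = tert_locus(),
                            max_hops = 2, max_dist = 5e7) {
  locus$chrom <- normalize_chrom(locus$chrom, genome, "locus")
  hits <- list()
  breakends <- rbind(
    data.frame(sv_id = svs$sv_id, chrom = svs$chrom1, pos = svs$pos1,
               partner_chrom = svs$chrom2, partner_pos = svs$pos2,
               partner_orient = svs$orient2, stringsAsFactors = FALSE),
    data.frame(sv_id = svs$sv_id, chrom = svs$chrom2, pos = svs$pos2,
               partner_chrom = svs$chrom1, partner_pos = svs$pos1,
               partner_orient = svs$orient1, stringsAsFactors = FALSE))

  region_hit <- function(chrom, lo, hi) {
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    nrow(r) > 0 && any(intervals_overlap(r$start, r$end, lo, hi))
  }
  # distance from pos (scanning in direction dir) to the nearest overlapping
  # region point, NA when the scan does not reach a region
  scan_settles <- function(chrom, pos, dir, budget) {
    lo <- if (dir > 0) pos else max(pos - budget, 0)
    hi <- if (dir > 0) min(pos + budget, chrom_length(genome, chrom)) else pos
    if (lo >= hi) lo <- hi  # zero-length scan still checks the point
    region_hit(chrom, lo, max(hi, lo + 1))
  }

  walk <- function(chrom, pos, dir, hops_left, budget, path, used_dist) {
    if (length(path) > 0 && scan_settles(chrom, pos, dir, budget)) {
      hits[[length(hits) + 1]] <<- data.frame(
        sv_ids = paste(path, collapse = ","), n_hops = length(path),
        walked_bp = used_dist,
        terminal_chrom = chrom,
        terminal_start = if (dir > 0) pos else max(pos - budget, 0),
        terminal_end = if (dir > 0) min(pos + budget,
                                        chrom_length(genome, chrom)) else pos,
        stringsAsFactors = FALSE)
    }
    if (hops_left == 0) return(invisible())
    be <- breakends[breakends$chrom == chrom &
                      !(breakends$sv_id %in% path), , drop = FALSE]
    d <- (be$pos - pos) * dir
    be <- be[d >= 0 & d <= budget, , drop = FALSE]
    for (i in seq_len(nrow(be))) {
      dd <- abs(be$pos[i] - pos)
      ndir <- if (be$partner_orient[i] == "head") -1 else 1
      walk(be$partner_chrom[i], be$partner_pos[i], ndir,
           hops_left - 1, budget - dd, c(path, be$sv_id[i]), used_dist + dd)
    }
  }

  walk(locus$chrom, locus$end, +1, max_hops, max_dist, character(0), 0)
  walk(locus$chrom, locus$start, -1, max_hops, max_dist, character(0), 0)
  paths <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sv_ids = character(), n_hops = integer(),
               walked_bp = numeric(), terminal_chrom = character(),
               terminal_start = numeric(), terminal_end = numeric(),
               stringsAsFactors = FALSE)
  structure(list(linked = nrow(paths) > 0, paths = paths),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat("walk_result: linked =", x$linked, "(", nrow(x$paths),
      "linking path(s) )\n")
  invisible(x)
}

#' TERT linkage across a cohort of chromothripsis-positive samples
#'
#' Runs [walk_from_locus()] per sample against that sample's chromothriptic
#' regions.
#'
#' @param svs cohort SV table.
#' @param calls chromothripsis call table; samples with at least one call at
#'   `tier` or better are walked.
#' @inheritParams walk_from_locus
#' @param tier lowest confidence tier defining a chromothriptic region.
#' @return data.frame with one row per chromothripsis-positive sample:
#'   `sample`, `linked`, `n_paths`.
#' @export
tert_linkage <- function(svs, calls, genome, locus = tert_locus(),
                         max_hops = 2, max_dist = 5e7, tier = "high") {
  keep <- tier_rank[calls$confidence] >= tier_rank[tier]
  calls <- calls[keep, , drop = FALSE]
  samples <- unique(calls$sample)
  out <- lapply(samples, function(s) {
    wr <- walk_from_locus(svs[svs$sample == s, , drop = FALSE],
                          calls[calls$sample == s, , drop = FALSE],
                          genome, locus, max_hops, max_dist)
    data.frame(sample = s, linked = wr$linked, n_paths = nrow(wr$paths),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(), linked = logical(),
                      n_paths = integer(), stringsAsFactors = FALSE)
  res
}

#' Contrast TERT-gain status against TERT-chromothripsis linkage
#'
#' Builds the 2x2 table (TERT gain yes/no x linked yes/no) over
#' chromothripsis-positive samples and tests it with a Pearson chi-square
#' (no continuity correction by default).
#'
#' @param walk_results data.frame from [tert_linkage()] (columns `sample`,
#'   `linked`).
#' @param metadata sample metadata with columns `sample` and `tert_status`.
#' @param correct logical; apply the Yates continuity correction.
#' @return list with `table` (2x2), `statistic`, `p`, and the linkage
#'   proportion per TERT group; `p` is NA (with a warning) for degenerate
#'   tables.
#' @export
tert_linkage_contrast <- function(walk_results, metadata, correct = FALSE) {
  m <- merge(walk_results, metadata[, c("sample", "tert_status")],
             by = "sample")
  gain <- factor(m$tert_status == "gain", levels = c(TRUE, FALSE),
                 labels = c("gain", "no-gain"))
  linked <- factor(m$linked, levels = c(TRUE, FALSE),
                   labels = c("linked", "not-linked"))
  tab <- table(gain, linked)
  props <- prop.table(tab, 1)[, "linked"]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table; chi-square p undefined")
    return(list(table = tab, statistic = NA_real_, p = NA_real_,
                proportions = props))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
       proportions = props)
}
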