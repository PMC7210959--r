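#' Breakpoint homology bins
#'
#' The five repair-pathway-informative bins of breakpoint homology length:
#' blunt end to 1 bp (non-homologous end joining), 2 bp, 3-5 bp
#' (alternative end joining), 6-9 bp, and 10 bp or more (homology-mediated
#' repair).
#'
#' @return character vector of the five bin labels.
#' @export
homology_bins <- function() c("0-1", "2", "3-5", "6-9", ">=10")

#' Assign homology lengths to bins
#'
#' @param len non-negative integer homology lengths.
#' @return factor over the five bins of [homology_bins()].
#' @export
bin_homology_length <- function(len) {
  len <- as.numeric(len)
  stopifnot(all(is.na(len) | len >= 0))
  cut(len, breaks = c(-Inf, 1, 2, 5, 9, Inf), labels = homology_bins())
}

#' Bin the homology lengths of one unit into a profile
#'
#' @param homlen homology lengths of one unit's structural variants;
#'   unknown (NA) lengths are excluded.
#' @return one-row data.frame with `n_sv`, one count column `n_<bin>` and
#'   one proportion column `p_<bin>` per bin (`NA` proportions and a TRUE
#'   `empty` flag when no SV has a known homology length).
#' @export
bin_homologies <- function(homlen) {
  homlen <- homlen[!is.na(homlen)]
  counts <- table(bin_homology_length(homlen))
  total <- sum(counts)
  props <- if (total > 0) as.numeric(counts) / total else
    rep(NA_real_, length(counts))
  out <- data.frame(n_sv = total, empty = total == 0)
  for (i in seq_along(counts)) out[[paste0("n_", names(counts)[i])]] <- as.numeric(counts[i])
  for (i in seq_along(counts)) out[[paste0("p_", names(counts)[i])]] <- props[i]
  out
}

#' Per-unit homology profiles for a cohort
#'
#' @param svs cohort SV table with `sample` and `homlen` columns; an
#'   optional `region_class` column (from [split_by_region()]) splits each
#'   sample into chromothriptic / other units.
#' @param by "sample" (case-wise) or "region" (sample x region-class,
#'   requires `region_class`).
#' @return data.frame with `unit`, `sample` (and `region_class` for
#'   region-wise profiles) plus the [bin_homologies()] columns.
#' @export
homology_profiles <- function(svs, by = c("sample", "region")) {
  by <- match.arg(by)
  if (by == "region" && is.null(svs$region_class))
    stop("region-wise profiles need a region_class column; run split_by_region")
  key <- if (by == "sample") svs$sample else
    paste(svs$sample, svs$region_class, sep = ":")
  parts <- split(svs, key)
  out <- do.call(rbind, lapply(names(parts), function(k) {
    prof <- bin_homologies(parts[[k]]$homlen)
    meta <- data.frame(unit = k, sample = parts[[k]]$sample[1],
                       stringsAsFactors = FALSE)
    if (by == "region") meta$region_class <- parts[[k]]$region_class[1]
    cbind(meta, prof)
  }))
  rownames(out) <- NULL
  out
}

#' Partition SVs into chromothriptic and other units per sample
#'
#' An SV belongs to the chromothriptic unit of its sample when either
#' breakend lies on a chromothriptic chromosome of that sample (or, with
#' `level = "region"`, inside a chromothriptic region).
#'
#' @param svs cohort SV table.
#' @param calls chromothripsis call table.
#' @param tier lowest confidence tier defining chromothriptic chromosomes.
#' @param level "chromosome" (default) or "region".
#' @return `svs` with an added `region_class` column
#'   ("chromothriptic"/"other").
#' @export
split_by_region <- function(svs, calls, tier = "high",
                            level = c("chromosome", "region")) {
  level <- match.arg(level)
  keep <- tier_rank[calls$confidence] >= tier_rank[tier]
  calls <- calls[keep, , drop = FALSE]
  in_ct <- function(sample, chrom, pos) {
    r <- calls[calls$sample == sample & calls$chrom == chrom, , drop = FALSE]
    if (nrow(r) == 0) return(FALSE)
    if (level == "chromosome") TRUE else any(pos >= r$start & pos < r$end)
  }
  hit <- vapply(seq_len(nrow(svs)), function(i) {
    in_ct(svs$sample[i], svs$chrom1[i], svs$pos1[i]) ||
      in_ct(svs$sample[i], svs$chrom2[i], svs$pos2[i])
  }, logical(1))
  svs$region_class <- ifelse(hit, "chromothriptic", "other")
  svs
}

#' Beta-regression contrast of homology-bin proportions between groups
#'
#' For each of the five homology bins, the bin proportion is modelled by a
#' maximum-likelihood beta regression with logit mean link on the group
#' indicator (single precision parameter). Proportions on the boundary are
#' shrunk by the usual `(y * (n - 1) + 0.5) / n` transformation before
#' fitting. P-values are Bonferroni-corrected across the five bins. Units
#' whose entity does not meet the eligibility filter (at least `min_total`
#' cases of which at least `min_per_group` in each group) are excluded.
#'
#' @param profiles per-unit profiles from [homology_profiles()] (empty
#'   profiles are dropped).
#' @param group logical or two-level factor, one entry per profile row; the
#'   effect is reported for the second level (TRUE) versus the first.
#' @param entity optional entity label per profile row; when given, the
#'   eligibility filter is applied within entity and ineligible entities are
#'   dropped.
#' @param min_total,min_per_group eligibility thresholds.
#' @return data.frame with one row per bin: `bin`, `estimate` (log-odds
#'   difference of the mean proportion), `se`, `p`, `p_adj`, `n_units`, and
#'   a `note` column flagging non-identifiable fits.
#' @export
homology_contrast <- function(profiles, group, entity = NULL,
                              min_total = 15, min_per_group = 5) {
  stopifnot(length(group) == nrow(profiles))
  grp <- if (is.logical(group)) factor(group, levels = c(FALSE, TRUE))
         else factor(group)
  if (nlevels(grp) != 2) stop("group must have exactly two levels")
  keep <- !profiles$empty
  if (!is.null(entity)) {
    stopifnot(length(entity) == nrow(profiles))
    tab <- table(entity[keep], grp[keep])
    eligible <- rownames(tab)[rowSums(tab) >= min_total &
                                apply(tab >= min_per_group, 1, all)]
    keep <- keep & entity %in% eligible
  } else {
    tab <- table(grp[keep])
    if (sum(tab) < min_total || any(tab < min_per_group))
      stop("groups do not meet the eligibility filter (n >= ", min_total,
           ", >= ", min_per_group, " per group)")
  }
  prof <- profiles[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  if (nlevels(grp) != 2) stop("one group is empty after filtering")
  n <- nrow(prof)
  out <- lapply(homology_bins(), function(b) {
    y <- prof[[paste0("p_", b)]]
    ys <- (y * (n - 1) + 0.5) / n  # keep the response inside (0, 1)
    if (stats::var(ys) == 0)
      return(data.frame(bin = b, estimate = NA_real_, se = NA_real_,
                        p = NA_real_, n_units = n,
                        note = "non-identifiable: constant proportions",
                        stringsAsFactors = FALSE))
    fit <- mgcv::gam(ys ~ grp, family = mgcv::betar(link = "logit"))
    sm <- summary(fit)$p.table
    data.frame(bin = b, estimate = sm[2, "Estimate"], se = sm[2, "Std. Error"],
               p = sm[2, 4], n_units = n, note = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_adj <- pmin(res$p * length(homology_bins()), 1)
  rownames(res) <- NULL
  res
}
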