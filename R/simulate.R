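#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of [simulate_cohort()] with defaults chosen to
#' emulate the statistical structure the downstream analyses assume:
#' clustered breakpoints with oscillating integer copy-number states,
#' uniform fragment-join orientations, sparse long background CNVs, sporadic
#' background SVs, group-dependent breakpoint-homology distributions,
#' TERT-gain status correlated with chromothripsis, a planted fusion rate
#' ratio, and matched longitudinal pairs under three evolution scenarios.
#'
#' @param seed integer RNG seed; identical configs give identical output.
#' @param genome a `genome_model` (default GRCh37-like).
#' @param n_samples number of unpaired cohort samples.
#' @param entities named numeric vector: per-entity probability that a
#'   sample carries chromothripsis.
#' @param entity_weights sampling weights over entities (default equal).
#' @param breakpoint_mean,breakpoint_min breakpoints per planted event are
#'   `rpois(breakpoint_mean) + breakpoint_min`.
#' @param span_range range (bp) of the planted region span.
#' @param k_weights weights over 2..6 distinct copy-number states per event.
#' @param p_telomere probability a planted region abuts a chromosome end.
#' @param p_centromere probability a (non-telomeric) region spans the
#'   centromere midpoint.
#' @param n_events_weights weights over 1..5 chromothriptic chromosomes per
#'   positive sample.
#' @param chrom_weights optional named list (by entity) of chromosome
#'   preference weights; default is length-proportional.
#' @param background_cnv_mean,background_sv_mean Poisson means of sporadic
#'   CNV and SV counts per sample.
#' @param background_cnv_span range (bp) of sporadic CNV lengths (long and
#'   sparse so they rarely mimic a switch cluster).
#' @param homology_probs list with elements `chromothriptic` and
#'   `background`: probabilities over the five homology bins
#'   0-1, 2, 3-5, 6-9, >=10 bp.
#' @param fusion_base_rate expected fusions per structural variant in
#'   chromothripsis-negative samples.
#' @param fusion_rate_ratio multiplicative excess of fusions per SV in
#'   chromothripsis-positive samples.
#' @param tert_p_gain_pos,tert_p_gain_neg P(TERT gain | chromothripsis
#'   positive / negative).
#' @param p_tert_promoter probability of a TERT promoter mutation among
#'   non-gain samples.
#' @param p_atrx_trunc probability of an ATRX/DAXX truncation among
#'   non-gain samples.
#' @param p_germline probability a sample carries a pathogenic germline
#'   variant; `p_second_hit` probability of somatic loss of the wild-type
#'   allele among carriers.
#' @param p_second_hit see `p_germline`.
#' @param tcc_range tumour cell content range.
#' @param signatures signature exposure column names to simulate.
#' @param signature_shift named multiplicative shift applied to exposures of
#'   chromothripsis-positive samples.
#' @param longitudinal_pairs number of matched two-timepoint pairs to add.
#' @param scenario_mix named weights over the `stable`, `lost`, `gained`
#'   evolution scenarios.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(
    seed = 1L,
    genome = grch37_genome(),
    n_samples = 200L,
    entities = c(sarcoma = 0.6, carcinoma = 0.4),
    entity_weights = NULL,
    breakpoint_mean = 25, breakpoint_min = 10,
    span_range = c(2e7, 4.5e7),
    k_weights = c(`2` = 0.35, `3` = 0.35, `4` = 0.15, `5` = 0.10, `6` = 0.05),
    p_telomere = 0.35, p_centromere = 0.5,
    n_events_weights = c(`1` = 0.35, `2` = 0.30, `3` = 0.15, `4` = 0.12,
                         `5` = 0.08),
    chrom_weights = NULL,
    background_cnv_mean = 2, background_sv_mean = 30,
    background_cnv_span = c(5e6, 3e7),
    homology_probs = list(
      chromothriptic = c(0.42, 0.18, 0.25, 0.10, 0.05),
      background     = c(0.25, 0.10, 0.20, 0.15, 0.30)),
    fusion_base_rate = 0.02, fusion_rate_ratio = 5,
    tert_p_gain_pos = 0.35, tert_p_gain_neg = 0.15,
    p_tert_promoter = 0.05, p_atrx_trunc = 0.08,
    p_germline = 0.12, p_second_hit = 0.4,
    tcc_range = c(0.3, 1),
    signatures = c("AC1", "AC2", "AC3", "AC13"),
    signature_shift = c(AC2 = 2, AC13 = 2),
    longitudinal_pairs = 0L,
    scenario_mix = c(stable = 1/3, lost = 1/3, gained = 1/3)) {
  cfg <- as.list(environment())
  probs <- c(cfg$entities, cfg$p_telomere, cfg$p_centromere,
             cfg$tert_p_gain_pos, cfg$tert_p_gain_neg, cfg$p_tert_promoter,
             cfg$p_atrx_trunc, cfg$p_germline, cfg$p_second_hit)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (nm in c("k_weights", "n_events_weights", "scenario_mix"))
    cfg[[nm]] <- cfg[[nm]] / sum(cfg[[nm]])
  cfg$homology_probs <- lapply(cfg$homology_probs, function(p) p / sum(p))
  stopifnot(inherits(cfg$genome, "genome_model"),
            all(lengths(cfg$homology_probs) == 5),
            cfg$fusion_rate_ratio > 0, cfg$fusion_base_rate >= 0)
  class(cfg) <- "cohort_config"
  cfg
}

#' Plant one chromothriptic event into a chromosome profile
#'
#' Places `n_breakpoints` uniform breakpoints inside the region and assigns
#' oscillating integer copy-number states drawn from a pool of exactly `k`
#' distinct states (including the baseline) such that adjacent segments
#' never share a state; one structural variant with uniformly random join
#' orientation is emitted per internal junction. The first region segment
#' always carries the baseline state and the last one does where the
#' oscillation parity permits, so the realized switch count is
#' `n_breakpoints` or `n_breakpoints + 1`.
#'
#' @param sample,chrom identifiers stamped onto the output.
#' @param region numeric length-2 vector (start, end) in bp.
#' @param n_breakpoints number of internal breakpoints (>= 2).
#' @param k number of distinct copy-number states (2..6, `k <=
#'   n_breakpoints`).
#' @param baseline baseline copy-number state outside the event.
#' @return list with `segments` (covering the region), `svs` (one per
#'   internal junction, orientations uniform over the four join classes) and
#'   `n_switches` (realized switch count attributable to the event).
#' @export
plant_chromothripsis <- function(sample, chrom, region, n_breakpoints, k,
                                 baseline = 2) {
  stopifnot(length(region) == 2, region[1] < region[2])
  if (n_breakpoints < 2) stop("need at least 2 breakpoints")
  if (k < 2) stop("need at least 2 copy-number states")
  if (k > n_breakpoints) stop("k states require at least k breakpoints")
  bp <- sort(unique(round(stats::runif(n_breakpoints, region[1] + 1,
                                       region[2] - 1))))
  tries <- 0
  while (length(bp) < n_breakpoints && tries < 100) {
    bp <- sort(unique(c(bp, round(stats::runif(n_breakpoints - length(bp),
                                               region[1] + 1, region[2] - 1)))))
    tries <- tries + 1
  }
  if (length(bp) < n_breakpoints) stop("could not place distinct breakpoints")
  n <- length(bp)
  pool <- c(baseline, sample(setdiff(0:6, baseline), k - 1))
  states <- oscillating_states(n + 1, pool, baseline)
  bounds <- c(region[1], bp, region[2])
  segments <- data.frame(
    sample = sample, chrom = chrom,
    start = bounds[-length(bounds)], end = bounds[-1],
    copy_number = states, state = states, stringsAsFactors = FALSE)
  other <- vapply(seq_len(n), function(i) {
    j <- if (n == 1) i else sample(setdiff(seq_len(n), i), 1)
    bp[j]
  }, numeric(1))
  svs <- data.frame(
    sv_id = NA_character_, sample = sample,
    chrom1 = chrom, pos1 = bp,
    orient1 = sample(c("head", "tail"), n, replace = TRUE),
    chrom2 = chrom, pos2 = other,
    orient2 = sample(c("head", "tail"), n, replace = TRUE),
    homlen = NA_real_, stringsAsFactors = FALSE)
  list(segments = segments, svs = svs,
       n_switches = n + (states[n + 1] != baseline))
}

# A state sequence of given length over `pool`, starting at baseline,
# adjacent entries always different, using every pool state when possible,
# and ending at baseline when the oscillation allows it.
oscillating_states <- function(len, pool, baseline) {
  k <- length(pool)
  draw <- function() {
    s <- numeric(len)
    s[1] <- baseline
    for (i in seq_len(len - 1) + 1) {
      cand <- setdiff(pool, s[i - 1])
      if (i == len && baseline %in% cand) s[i] <- baseline
      else s[i] <- if (length(cand) == 1) cand else sample(cand, 1)
    }
    s
  }
  for (try in 1:50) {
    s <- draw()
    if (length(unique(s)) == k) return(s)
  }
  # deterministic fallback: cycle through the pool, then close at baseline
  s <- rep(pool, length.out = len)
  if (len %% k != 1 && s[len] == s[1]) s[len] <- pool[2]
  if (s[len] != baseline && baseline != s[len - 1]) s[len] <- baseline
  s
}

#' Simulate a synthetic tumour cohort with planted chromothripsis
#'
#' @param config a [cohort_config()].
#' @return list with elements `genome`, `segments`, `svs`, `fusions`,
#'   `metadata`, `truth` (one row per planted event: sample, chromosome,
#'   region, realized switch count, state count, telomere/centromere
#'   involvement, canonical flag) and `pairs` (longitudinal pair table with
#'   the planted scenario).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  ents <- names(cfg$entities)
  w <- cfg$entity_weights %||% rep(1, length(ents))
  n <- cfg$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  entity <- sample(ents, n, replace = TRUE, prob = w)
  positive <- stats::rbinom(n, 1, cfg$entities[entity]) == 1

  seg_l <- list(); sv_l <- list(); truth_l <- list()
  for (i in seq_len(n)) {
    sim <- simulate_sample(ids[i], entity[i], positive[i], cfg)
    seg_l[[i]] <- sim$segments; sv_l[[i]] <- sim$svs
    truth_l[[i]] <- sim$truth
  }

  pairs <- NULL
  if (cfg$longitudinal_pairs > 0) {
    scen <- sample(names(cfg$scenario_mix), cfg$longitudinal_pairs,
                   replace = TRUE, prob = cfg$scenario_mix)
    for (j in seq_len(cfg$longitudinal_pairs)) {
      patient <- sprintf("P%03d", j)
      pr <- simulate_longitudinal_pair(scen[j], patient,
                                       sample(ents, 1, prob = w), cfg)
      seg_l <- c(seg_l, list(pr$segments)); sv_l <- c(sv_l, list(pr$svs))
      truth_l <- c(truth_l, list(pr$truth))
      pairs <- rbind(pairs, pr$pair)
      ids <- c(ids, pr$pair$sample_t1, pr$pair$sample_t2)
      entity <- c(entity, rep(pr$pair$entity, 2))
      positive <- c(positive, pr$positive_t1, pr$positive_t2)
    }
  }

  segments <- do.call(rbind, seg_l)
  svs <- do.call(rbind, sv_l)
  svs$sv_id <- sprintf("sv%05d", seq_len(nrow(svs)))
  svs <- as_svs(svs, cfg$genome)
  truth <- do.call(rbind, truth_l)
  if (is.null(truth))
    truth <- data.frame(sample = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        n_breakpoints = numeric(), n_switches = numeric(),
                        k_states = numeric(), canonical = logical(),
                        telomere = logical(), centromere = logical(),
                        stringsAsFactors = FALSE)
  rownames(segments) <- rownames(svs) <- rownames(truth) <- NULL

  metadata <- simulate_metadata(ids, entity, positive, cfg)
  if (!is.null(pairs)) {
    metadata$patient[match(pairs$sample_t1, metadata$sample)] <- pairs$patient
    metadata$patient[match(pairs$sample_t2, metadata$sample)] <- pairs$patient
    metadata$timepoint[match(pairs$sample_t2, metadata$sample)] <- "relapse"
  }
  fusions <- simulate_fusions(svs, ids, positive, cfg)
  list(genome = cfg$genome, segments = as_segments(segments, cfg$genome),
       svs = svs, fusions = fusions, metadata = metadata, truth = truth,
       pairs = pairs, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One sample: baseline diploid genome, planted events on distinct
# chromosomes, sparse long background CNVs, sporadic background SVs.
simulate_sample <- function(id, entity, positive, cfg, svs_wanted = TRUE) {
  gm <- cfg$genome
  chroms <- gm$chroms$chrom
  lens <- gm$chroms$length
  events <- list(); truth <- NULL
  ev_sv <- list()
  if (positive) {
    n_ev <- as.integer(sample(names(cfg$n_events_weights), 1,
                              prob = cfg$n_events_weights))
    cw <- cfg$chrom_weights[[entity]] %||% lens
    ev_chroms <- sample(chroms, n_ev, prob = cw)
    for (ch in ev_chroms) {
      L <- lens[match(ch, chroms)]
      span <- min(round(stats::runif(1, cfg$span_range[1], cfg$span_range[2])),
                  floor(0.45 * L))
      place <- place_region(ch, L, span, gm, cfg)
      n_bp <- stats::rpois(1, cfg$breakpoint_mean) + cfg$breakpoint_min
      k <- as.integer(sample(names(cfg$k_weights), 1, prob = cfg$k_weights))
      k <- min(k, n_bp)
      ev <- plant_chromothripsis(id, ch, place, n_bp, k)
      events[[ch]] <- ev$segments
      ev_sv[[ch]] <- ev$svs
      # regions flush with the chromosome end have no downstream flank, so
      # the parity edge switch at the region end never materializes
      last_state <- ev$segments$state[nrow(ev$segments)]
      realized <- (nrow(ev$segments) - 1) +
        (last_state != 2 && place[2] < L)
      cen <- centromere_interval(gm, ch)
      truth <- rbind(truth, data.frame(
        sample = id, chrom = ch, start = place[1], end = place[2],
        n_breakpoints = n_bp, n_switches = realized,
        k_states = length(unique(ev$segments$state)),
        canonical = length(unique(ev$segments$state)) <= 3,
        telomere = place[1] <= 1e6 | place[2] >= L - 1e6,
        centromere = !is.null(cen) &&
          intervals_overlap(place[1], place[2], cen["start"], cen["end"]),
        stringsAsFactors = FALSE))
    }
  }
  seg_l <- lapply(seq_along(chroms), function(ci) {
    ch <- chroms[ci]; L <- lens[ci]
    if (!is.null(events[[ch]])) {
      ev <- events[[ch]]
      rs <- min(ev$start); re <- max(ev$end)
      parts <- list()
      if (rs > 0)
        parts <- c(parts, list(data.frame(sample = id, chrom = ch, start = 0,
                                          end = rs, copy_number = 2, state = 2,
                                          stringsAsFactors = FALSE)))
      parts <- c(parts, list(ev))
      if (re < L)
        parts <- c(parts, list(data.frame(sample = id, chrom = ch, start = re,
                                          end = L, copy_number = 2, state = 2,
                                          stringsAsFactors = FALSE)))
      do.call(rbind, parts)
    } else {
      data.frame(sample = id, chrom = ch, start = 0, end = L,
                 copy_number = 2, state = 2, stringsAsFactors = FALSE)
    }
  })
  segments <- do.call(rbind, seg_l)
  segments <- add_background_cnvs(segments, id, cfg)
  svs <- do.call(rbind, ev_sv)
  if (svs_wanted) {
    n_bg <- stats::rpois(1, cfg$background_sv_mean)
    if (n_bg > 0) {
      c1 <- sample(chroms, n_bg, replace = TRUE, prob = lens)
      c2 <- sample(chroms, n_bg, replace = TRUE, prob = lens)
      bg <- data.frame(
        sv_id = NA_character_, sample = id,
        chrom1 = c1, pos1 = floor(stats::runif(n_bg) * lens[match(c1, chroms)]),
        orient1 = sample(c("head", "tail"), n_bg, replace = TRUE),
        chrom2 = c2, pos2 = floor(stats::runif(n_bg) * lens[match(c2, chroms)]),
        orient2 = sample(c("head", "tail"), n_bg, replace = TRUE),
        homlen = sample_homology_lengths(n_bg, cfg$homology_probs$background),
        stringsAsFactors = FALSE)
      svs <- rbind(svs, bg)
    }
    if (!is.null(svs) && nrow(svs)) {
      na <- is.na(svs$homlen)
      svs$homlen[na] <-
        sample_homology_lengths(sum(na), cfg$homology_probs$chromothriptic)
    }
  }
  if (is.null(svs))
    svs <- data.frame(sv_id = character(), sample = character(),
                      chrom1 = character(), pos1 = numeric(),
                      orient1 = character(), chrom2 = character(),
                      pos2 = numeric(), orient2 = character(),
                      homlen = numeric(), stringsAsFactors = FALSE)
  list(segments = segments, svs = svs, truth = truth)
}

place_region <- function(ch, L, span, gm, cfg) {
  if (stats::runif(1) < cfg$p_telomere) {
    if (stats::runif(1) < 0.5) return(c(0, span)) else return(c(L - span, L))
  }
  cen <- centromere_interval(gm, ch)
  if (!is.null(cen) && stats::runif(1) < cfg$p_centromere) {
    mid <- mean(cen)
    rs <- round(mid - stats::runif(1, 0.25, 0.75) * span)
    rs <- min(max(rs, 0), L - span)
    return(c(rs, rs + span))
  }
  rs <- round(stats::runif(1, 0, L - span))
  c(rs, rs + span)
}

# Sporadic long CNVs carved into baseline (state 2) stretches only, so they
# never corrupt the planted event geometry.
add_background_cnvs <- function(segments, id, cfg) {
  n_cnv <- stats::rpois(1, cfg$background_cnv_mean)
  gm <- cfg$genome
  for (i in seq_len(n_cnv)) {
    len <- round(stats::runif(1, cfg$background_cnv_span[1],
                              cfg$background_cnv_span[2]))
    st <- sample(c(1, 3), 1)
    for (try in 1:20) {
      ch <- sample(gm$chroms$chrom, 1, prob = gm$chroms$length)
      L <- chrom_length(gm, ch)
      if (len >= L) next
      s <- round(stats::runif(1, 0, L - len))
      idx <- which(segments$chrom == ch & segments$state == 2 &
                     segments$start <= s & segments$end >= s + len)
      if (length(idx) == 1) {
        host <- segments[idx, ]
        repl <- data.frame(
          sample = id, chrom = ch,
          start = c(host$start, s, s + len),
          end = c(s, s + len, host$end),
          copy_number = c(2, st, 2), state = c(2, st, 2),
          stringsAsFactors = FALSE)
        repl <- repl[repl$start < repl$end, ]
        segments <- rbind(segments[-idx, ], repl)
        break
      }
    }
  }
  segments[order(match(segments$chrom, gm$chroms$chrom), segments$start), ]
}

#' Sample breakpoint homology lengths from the five-bin model
#'
#' Draws a bin from the categorical distribution over the bins 0-1, 2, 3-5,
#' 6-9, >=10 bp, then a length uniformly within the bin (10-50 bp for the
#' top bin).
#'
#' @param n number of lengths.
#' @param probs probabilities over the five bins.
#' @return integer vector of homology lengths.
#' @export
sample_homology_lengths <- function(n, probs) {
  stopifnot(length(probs) == 5)
  if (n == 0) return(numeric(0))
  bin <- sample.int(5, n, replace = TRUE, prob = probs)
  lo <- c(0, 2, 3, 6, 10)[bin]
  hi <- c(1, 2, 5, 9, 50)[bin]
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' Simulate per-sample fusion counts under the planted rate-ratio model
#'
#' Fusion counts are Poisson with mean `base_rate * sv_count` multiplied by
#' `rate_ratio` in chromothripsis-positive samples — the generative model
#' whose status coefficient the fusion count regression recovers.
#'
#' @param sv_count vector of structural-variant counts.
#' @param positive logical vector of chromothripsis status.
#' @param base_rate,rate_ratio model parameters.
#' @return integer vector of fusion counts.
#' @export
simulate_fusion_counts <- function(sv_count, positive, base_rate = 0.02,
                                   rate_ratio = 5) {
  stats::rpois(length(sv_count),
               base_rate * sv_count * ifelse(positive, rate_ratio, 1))
}

simulate_fusions <- function(svs, ids, positive, cfg) {
  out <- NULL
  for (i in seq_along(ids)) {
    ssv <- svs[svs$sample == ids[i], ]
    nf <- simulate_fusion_counts(nrow(ssv), positive[i],
                                 cfg$fusion_base_rate, cfg$fusion_rate_ratio)
    if (nf > 0 && nrow(ssv) > 0) {
      pick <- ssv[sample.int(nrow(ssv), nf, replace = TRUE), ]
      off_a <- round(stats::runif(nf, 0, 5e4)) *
        sample(c(-1, 1), nf, replace = TRUE)
      off_b <- round(stats::runif(nf, 0, 5e4)) *
        sample(c(-1, 1), nf, replace = TRUE)
      pa <- pmin(pmax(pick$pos1 + off_a, 0),
                 chrom_length(cfg$genome, pick$chrom1) - 1)
      pb <- pmin(pmax(pick$pos2 + off_b, 0),
                 chrom_length(cfg$genome, pick$chrom2) - 1)
      out <- rbind(out, data.frame(
        sample = ids[i],
        gene_a = sprintf("GENEA%04d", sample.int(9999, nf)),
        gene_b = sprintf("GENEB%04d", sample.int(9999, nf)),
        chrom_a = pick$chrom1, pos_a = pa,
        chrom_b = pick$chrom2, pos_b = pb,
        confidence = sample(c("high", "medium"), nf, replace = TRUE,
                            prob = c(0.7, 0.3)),
        stringsAsFactors = FALSE))
    }
    n_low <- stats::rpois(1, 0.2)
    if (n_low > 0) {
      ch <- sample(cfg$genome$chroms$chrom, n_low, replace = TRUE)
      out <- rbind(out, data.frame(
        sample = ids[i],
        gene_a = sprintf("GENEA%04d", sample.int(9999, n_low)),
        gene_b = sprintf("GENEB%04d", sample.int(9999, n_low)),
        chrom_a = ch,
        pos_a = floor(stats::runif(n_low) * chrom_length(cfg$genome, ch)),
        chrom_b = ch,
        pos_b = floor(stats::runif(n_low) * chrom_length(cfg$genome, ch)),
        confidence = "low", stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(sample = character(), gene_a = character(),
                      gene_b = character(), chrom_a = character(),
                      pos_a = numeric(), chrom_b = character(),
                      pos_b = numeric(), confidence = character(),
                      stringsAsFactors = FALSE)
  as_fusions(out, cfg$genome)
}

simulate_metadata <- function(ids, entity, positive, cfg) {
  n <- length(ids)
  gain <- stats::rbinom(n, 1, ifelse(positive, cfg$tert_p_gain_pos,
                                     cfg$tert_p_gain_neg)) == 1
  promoter <- !gain & stats::rbinom(n, 1, cfg$p_tert_promoter) == 1
  tert <- ifelse(gain, "gain", ifelse(promoter, "promoter-mutation", "none"))
  atrx <- !gain & stats::rbinom(n, 1, cfg$p_atrx_trunc) == 1
  carrier <- stats::rbinom(n, 1, cfg$p_germline) == 1
  genes <- c("TP53", "ATM", "BRCA1", "BRCA2", "MSH2", "NBN")
  md <- data.frame(
    sample = ids, entity = entity, arm = "WGS", patient = ids,
    timepoint = "primary", tert_status = tert, atrx_daxx_trunc = atrx,
    germline_gene = ifelse(carrier, sample(genes, n, replace = TRUE),
                           NA_character_),
    second_hit = carrier & stats::rbinom(n, 1, cfg$p_second_hit) == 1,
    tumour_cell_content = stats::runif(n, cfg$tcc_range[1], cfg$tcc_range[2]),
    stringsAsFactors = FALSE)
  for (sig in cfg$signatures) {
    shift <- if (sig %in% names(cfg$signature_shift))
      cfg$signature_shift[[sig]] else 1
    md[[sig]] <- stats::rlnorm(n, log(300), 1) *
      ifelse(positive, shift, 1)
  }
  md
}

#' Simulate a matched longitudinal sample pair
#'
#' Generates two samples of one patient under a planted evolution scenario:
#' `stable` (the same chromothriptic chromosomes at both timepoints), `lost`
#' (events in the first sample only) or `gained` (events in the second
#' sample only).
#'
#' @param scenario one of "stable", "lost", "gained".
#' @param patient patient identifier shared by both samples.
#' @param entity entity label.
#' @param cfg a [cohort_config()].
#' @return list with combined `segments`, `svs`, `truth`, a one-row `pair`
#'   table and the per-timepoint positivity flags.
#' @export
simulate_longitudinal_pair <- function(scenario, patient, entity,
                                       cfg = cohort_config()) {
  if (!scenario %in% c("stable", "lost", "gained"))
    stop("unknown scenario: ", scenario)
  id1 <- paste0(patient, "-T1"); id2 <- paste0(patient, "-T2")
  pos1 <- scenario %in% c("stable", "lost")
  pos2 <- scenario %in% c("stable", "gained")
  s1 <- simulate_sample(id1, entity, pos1, cfg)
  if (scenario == "stable") {
    # identical chromothriptic chromosomes: reuse the first profile
    s2 <- list(
      segments = transform(s1$segments, sample = id2),
      svs = transform(s1$svs, sample = id2),
      truth = if (!is.null(s1$truth)) transform(s1$truth, sample = id2))
  } else {
    s2 <- simulate_sample(id2, entity, pos2, cfg)
  }
  pair <- data.frame(patient = patient, entity = entity,
                     sample_t1 = id1, sample_t2 = id2,
                     scenario = scenario, stringsAsFactors = FALSE)
  list(segments = rbind(s1$segments, s2$segments),
       svs = rbind(s1$svs, s2$svs),
       truth = rbind(s1$truth, s2$truth),
       pair = pair, positive_t1 = pos1, positive_t2 = pos2)
}

#' Write every file of a simulated cohort to a directory
#'
#' Emits `genome.sizes`, `centromeres.bed`, `segments.seg`, `svs.bedpe`,
#' `fusions.tsv`, `metadata.tsv`, `truth.tsv` and (when present)
#' `pairs.tsv`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome_model(sim$genome, p("genome.sizes"), p("centromeres.bed"))
  seg <- sim$segments[, c("sample", "chrom", "start", "end", "copy_number")]
  seg$start <- fmt_bp(seg$start); seg$end <- fmt_bp(seg$end)
  utils::write.table(seg, p("segments.seg"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_svs(sim$svs, p("svs.bedpe"))
  utils::write.table(sim$fusions, p("fusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  for (col in c("start", "end")) tr[[col]] <- fmt_bp(tr[[col]])
  utils::write.table(tr, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sim$pairs))
    utils::write.table(sim$pairs, p("pairs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(dir)
}
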