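#' Validate fusion calls against structural-variant breakends
#'
#' Medium- and high-confidence fusions are matched breakpoint-by-breakpoint
#' against the SV breakends of the same sample: a fusion is validated when
#' both of its breakpoints have an SV breakend within `threshold` bp on the
#' same chromosome (strand/orientation is ignored; the two breakpoints may
#' match the two ends of one SV or of two different SVs). Low-confidence
#' fusions are dropped before matching.
#'
#' @param fusions fusion table (see [read_fusions()]).
#' @param svs SV table of the same cohort.
#' @param threshold maximum breakpoint-to-breakend distance in bp.
#' @return data.frame with one row per medium/high-confidence fusion:
#'   `fusion_id`, `sample`, `validated`, nearest SV id and distance per
#'   breakpoint.
#' @export
validate_fusions <- function(fusions, svs, threshold = 2e5) {
  fus <- fusions[fusions$confidence %in% c("medium", "high"), , drop = FALSE]
  be <- rbind(
    data.frame(sv_id = svs$sv_id, sample = svs$sample, chrom = svs$chrom1,
               pos = svs$pos1, stringsAsFactors = FALSE),
    data.frame(sv_id = svs$sv_id, sample = svs$sample, chrom = svs$chrom2,
               pos = svs$pos2, stringsAsFactors = FALSE))
  nearest <- function(sample, chrom, pos) {
    cand <- be[be$sample == sample & be$chrom == chrom, , drop = FALSE]
    if (nrow(cand) == 0)
      return(list(sv_id = NA_character_, dist = Inf))
    d <- abs(cand$pos - pos)
    i <- which.min(d)
    list(sv_id = cand$sv_id[i], dist = d[i])
  }
  rows <- lapply(seq_len(nrow(fus)), function(i) {
    a <- nearest(fus$sample[i], fus$chrom_a[i], fus$pos_a[i])
    b <- nearest(fus$sample[i], fus$chrom_b[i], fus$pos_b[i])
    data.frame(fusion_id = fus$fusion_id[i], sample = fus$sample[i],
               validated = a$dist <= threshold & b$dist <= threshold,
               sv_id_a = a$sv_id, dist_a = a$dist,
               sv_id_b = b$sv_id, dist_b = b$dist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fusion_id = character(), sample = character(),
                      validated = logical(), sv_id_a = character(),
                      dist_a = numeric(), sv_id_b = character(),
                      dist_b = numeric(), stringsAsFactors = FALSE)
  out
}

#' Count regression of fusions on structural-variant burden and
#' chromothripsis status
#'
#' Fits `fusion_count ~ log(sv_count) + status` with a logarithmic link:
#' negative binomial by default (robust to overdispersion), Poisson on
#' request. The exponentiated status coefficient is the fusions-per-SV rate
#' ratio of chromothripsis-positive versus -negative tumours; because the
#' status effect is additive on the log scale, it equals the ratio of
#' fitted fusion counts at any fixed SV count.
#'
#' @param fusion_count,sv_count,status per-sample fusion counts, SV counts
#'   (>= 1) and chromothripsis status (logical).
#' @param family "nb" (negative binomial, default) or "poisson".
#' @param conf_level confidence level for the Wald interval of the rate
#'   ratio.
#' @return list of class `fusion_fit`: `coefficients`, `rate_ratio`, `ci`,
#'   `family`, and the underlying `fit` object.
#' @export
fit_fusion_regression <- function(fusion_count, sv_count, status,
                                  family = c("nb", "poisson"),
                                  conf_level = 0.95) {
  family <- match.arg(family)
  stopifnot(length(fusion_count) == length(sv_count),
            length(status) == length(sv_count))
  if (any(sv_count < 1)) stop("sv_count must be >= 1 for included samples")
  status <- as.logical(status)
  if (length(unique(status)) < 2)
    stop("chromothripsis status is constant; the status effect is not identifiable")
  df <- data.frame(y = fusion_count, lsv = log(sv_count), status = status)
  fit <- if (family == "nb") {
    suppressWarnings(MASS::glm.nb(y ~ lsv + status, data = df))
  } else {
    stats::glm(y ~ lsv + status, family = stats::poisson(), data = df)
  }
  co <- summary(fit)$coefficients
  beta <- co["statusTRUE", "Estimate"]
  se <- co["statusTRUE", "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(coefficients = stats::coef(fit),
                 rate_ratio = exp(beta),
                 ci = exp(beta + c(-1, 1) * z * se),
                 p = co["statusTRUE", 4],
                 family = if (family == "nb") "negative-binomial" else "poisson",
                 fit = fit),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("fusion count regression (", x$family, " family)\n", sep = "")
  cat(sprintf("  fusions-per-SV rate ratio: %.3f (CI %.3f-%.3f), p = %.3g\n",
              x$rate_ratio, x$ci[1], x$ci[2], x$p))
  invisible(x)
}
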