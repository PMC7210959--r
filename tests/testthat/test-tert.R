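# All walking tests use the GRCh37-like genome so the default TERT locus
# (chr5:1,253,282-1,295,184) applies.

mk_svs <- function(df, gm = grch37_genome()) {
  df$sv_id <- sprintf("sv%d", seq_len(nrow(df)))
  df$sample <- "s"
  df$homlen <- NA_real_
  as_svs(df, gm)
}

# An n-hop chain from just downstream of TERT through intermediate
# chromosomes into a terminal landing point, each leg `leg` bp long.
mk_chain <- function(n_hops, leg, land_chrom = "chr12", land_pos = 5e6) {
  loc <- tert_locus()
  mids <- c("chr10", "chr11", "chr13", "chr14")[seq_len(n_hops - 1)]
  chroms1 <- c("chr5", mids)
  pos1 <- c(loc$end + leg, rep(2e6 + leg, n_hops - 1))
  chroms2 <- c(mids, land_chrom)
  pos2 <- c(rep(2e6, n_hops - 1), land_pos)
  mk_svs(data.frame(
    chrom1 = chroms1, pos1 = pos1, orient1 = "tail",
    chrom2 = chroms2, pos2 = pos2, orient2 = "tail",
    stringsAsFactors = FALSE))
}

test_that("no structural variant in reach means no linkage", {
  gm <- grch37_genome()
  svs <- mk_svs(data.frame(chrom1 = "chr5", pos1 = tert_locus()$end + 6e7,
                           orient1 = "tail", chrom2 = "chr12", pos2 = 5e6,
                           orient2 = "tail"))
  regions <- data.frame(chrom = "chr12", start = 4e6, end = 6e6)
  expect_false(walk_from_locus(svs, regions, gm)$linked)
  expect_false(walk_from_locus(svs[0, ], regions, gm)$linked)
})

test_that("one SV jumping into a chromothriptic region links in one hop", {
  gm <- grch37_genome()
  svs <- mk_svs(data.frame(chrom1 = "chr5", pos1 = tert_locus()$end + 1e5,
                           orient1 = "tail", chrom2 = "chr12", pos2 = 5e6,
                           orient2 = "tail"))
  regions <- data.frame(chrom = "chr12", start = 4e6, end = 6e6)
  wr <- walk_from_locus(svs, regions, gm)
  expect_true(wr$linked)
  expect_true(any(wr$paths$n_hops == 1))
  expect_equal(min(wr$paths$walked_bp), 1e5)
})

test_that("the hop cap is enforced per direction", {
  gm <- grch37_genome()
  regions <- data.frame(chrom = "chr12", start = 4e6, end = 6e6)
  expect_true(walk_from_locus(mk_chain(2, 1e6), regions, gm)$linked)
  expect_false(walk_from_locus(mk_chain(3, 1e6), regions, gm)$linked)
  expect_true(walk_from_locus(mk_chain(3, 1e6), regions, gm,
                              max_hops = 3)$linked)
})

test_that("the walking distance cap is enforced cumulatively", {
  gm <- grch37_genome()
  regions <- data.frame(chrom = "chr12", start = 4.999e6, end = 5.001e6)
  # two legs of 24 Mb: within 50 Mb; two legs of 26 Mb: beyond
  expect_true(walk_from_locus(mk_chain(2, 2.4e7), regions, gm)$linked)
  expect_false(walk_from_locus(mk_chain(2, 2.6e7), regions, gm)$linked)
  expect_true(walk_from_locus(mk_chain(2, 2.6e7), regions, gm,
                              max_dist = 6e7)$linked)
})

test_that("partner orientation sets the outgoing scan direction", {
  gm <- grch37_genome()
  loc <- tert_locus()
  # head partner continues toward decreasing coordinates: region upstream of
  # the landing point is reached, region downstream is not
  svs <- mk_svs(data.frame(chrom1 = "chr5", pos1 = loc$end + 1e5,
                           orient1 = "tail", chrom2 = "chr12", pos2 = 5e7,
                           orient2 = "head"))
  up <- data.frame(chrom = "chr12", start = 2e7, end = 2.5e7)
  down <- data.frame(chrom = "chr12", start = 7e7, end = 7.5e7)
  expect_true(walk_from_locus(svs, up, gm)$linked)
  expect_false(walk_from_locus(svs, down, gm)$linked)
})

test_that("linkage is monotone in hop and distance caps and mirror-symmetric", {
  gm <- grch37_genome()
  set.seed(9)
  L <- gm$chroms$length
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    ch1 <- sample(gm$chroms$chrom, n, replace = TRUE)
    ch2 <- sample(gm$chroms$chrom, n, replace = TRUE)
    svs <- mk_svs(data.frame(
      chrom1 = ch1, pos1 = floor(runif(n) * L[match(ch1, gm$chroms$chrom)]),
      orient1 = sample(c("head", "tail"), n, TRUE),
      chrom2 = ch2, pos2 = floor(runif(n) * L[match(ch2, gm$chroms$chrom)]),
      orient2 = sample(c("head", "tail"), n, TRUE),
      stringsAsFactors = FALSE))
    rc <- sample(gm$chroms$chrom, 1)
    rl <- chrom_length(gm, rc)
    rs <- floor(runif(1) * (rl - 1e7))
    regions <- data.frame(chrom = rc, start = rs, end = rs + 1e7)
    l1 <- walk_from_locus(svs, regions, gm, max_hops = 1)$linked
    l2 <- walk_from_locus(svs, regions, gm, max_hops = 2)$linked
    l3 <- walk_from_locus(svs, regions, gm, max_hops = 3)$linked
    expect_true(!l1 || l2)
    expect_true(!l2 || l3)
    d1 <- walk_from_locus(svs, regions, gm, max_dist = 2e7)$linked
    d2 <- walk_from_locus(svs, regions, gm, max_dist = 5e7)$linked
    expect_true(!d1 || d2)

    mirror <- svs
    mirror$pos1 <- L[match(svs$chrom1, gm$chroms$chrom)] - 1 - svs$pos1
    mirror$pos2 <- L[match(svs$chrom2, gm$chroms$chrom)] - 1 - svs$pos2
    flip <- c(head = "tail", tail = "head")
    mirror$orient1 <- unname(flip[svs$orient1])
    mirror$orient2 <- unname(flip[svs$orient2])
    mirror <- as_svs(mirror, gm)
    mregions <- data.frame(chrom = rc, start = rl - regions$end,
                           end = rl - regions$start)
    mlocus <- list(chrom = "chr5",
                   start = chrom_length(gm, "chr5") - tert_locus()$end,
                   end = chrom_length(gm, "chr5") - tert_locus()$start)
    expect_equal(walk_from_locus(mirror, mregions, gm, locus = mlocus)$linked,
                 l2)
  }
})

test_that("the TERT-linkage contrast matches the closed-form chi-square", {
  wr <- data.frame(sample = sprintf("s%d", 1:100),
                   linked = rep(c(TRUE, FALSE, TRUE, FALSE),
                                c(10, 40, 3, 47)))
  md <- data.frame(sample = sprintf("s%d", 1:100),
                   tert_status = rep(c("gain", "none"), each = 50))
  res <- tert_linkage_contrast(wr, md)
  # Pearson X^2 = N (ad - bc)^2 / (r1 r2 c1 c2), 1 df, no continuity corr.
  x2 <- 100 * (10 * 47 - 40 * 3)^2 / (50 * 50 * 13 * 87)
  expect_equal(res$statistic, x2, tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(x2, 1, lower.tail = FALSE))
  expect_equal(unname(res$proportions), c(0.2, 0.06))

  wr$linked <- TRUE
  expect_warning(res2 <- tert_linkage_contrast(wr, md), "degenerate")
  expect_true(is.na(res2$p))
})

test_that("a planted linkage difference is detected with high power", {
  set.seed(10)
  hits <- vapply(1:100, function(r) {
    gain <- rep(c(TRUE, FALSE), each = 200)
    linked <- stats::rbinom(400, 1, ifelse(gain, 0.3, 0.05)) == 1
    wr <- data.frame(sample = sprintf("s%d", 1:400), linked = linked)
    md <- data.frame(sample = wr$sample,
                     tert_status = ifelse(gain, "gain", "none"))
    tert_linkage_contrast(wr, md)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort-level linkage walks each positive sample", {
  gm <- grch37_genome()
  svs <- mk_chain(1, 1e5)
  calls <- rbind(call_row("s", "chr12", 4e6, 6e6),
                 call_row("t", "chr12", 4e6, 6e6))
  res <- tert_linkage(svs, calls, gm)
  expect_equal(res$linked[res$sample == "s"], TRUE)
  expect_equal(res$linked[res$sample == "t"], FALSE)  # t has no SVs
})
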