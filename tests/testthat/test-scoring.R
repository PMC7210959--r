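test_that("switch counting merges equal-state neighbours", {
  gm <- toy_genome()
  one <- data.frame(sample = "s", chrom = "chr1", start = 0, end = 1e6,
                    copy_number = 2, state = 2)
  expect_equal(count_switches(one), numeric(0))

  bounds <- c(0, 1e6, 2e6, 3e6, 4e6, 5e6)
  st <- c(2, 3, 2, 2, 3)
  seg <- data.frame(sample = "s", chrom = "chr1",
                    start = bounds[-6], end = bounds[-1],
                    copy_number = st, state = st)
  expect_equal(count_switches(seg), c(1e6, 2e6, 4e6))

  bad <- seg[c(2, 1, 3, 4, 5), ]
  expect_error(count_switches(bad), "sorted")
})

test_that("switch counting agrees with an rle oracle on random profiles", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 1000
    bounds <- sort(sample.int(2e8, n + 1))
    st <- sample(0:5, n, replace = TRUE)
    seg <- data.frame(sample = "s", chrom = "chr1",
                      start = bounds[-(n + 1)], end = bounds[-1],
                      copy_number = st, state = st)
    expect_equal(length(count_switches(seg)), length(rle(st)$values) - 1)
  }
})

test_that("densest window matches brute force and boundary conventions", {
  expect_equal(best_window(numeric(0))$count, 0)
  bw <- best_window(seq(1e6, 1e7, by = 1e6), 5e7)
  expect_equal(bw$count, 10)
  expect_equal(bw$end - bw$start, 9e6)
  # inclusive span: 0 and exactly 50 Mb are one window
  expect_equal(best_window(c(0, 5e7))$count, 2)
  expect_equal(best_window(c(0, 5e7 + 1))$count, 1)

  set.seed(7)
  for (rep in 1:50) {
    pos <- sort(sample.int(2e8, sample(2:40, 1)))
    w <- sample(c(1e6, 1e7, 5e7), 1)
    expect_equal(best_window(pos, w)$count, best_window_brute(pos, w))
  }
})

test_that("tier thresholds follow switch counts inside the window", {
  gm <- toy_genome()
  high <- score_chromosome(make_switch_profile(10), gm)
  expect_equal(high$confidence, "high")
  expect_true(high$canonical)
  expect_equal(high$n_states, 2)

  expect_equal(score_chromosome(make_switch_profile(9), gm)$confidence,
               "intermediate")
  expect_equal(score_chromosome(make_switch_profile(7), gm)$confidence, "low")
  expect_equal(nrow(score_chromosome(make_switch_profile(5), gm)), 0)
  expect_error(score_chromosome(make_switch_profile(10, chrom = "chrZ"), gm),
               "chrZ")
})

test_that("canonical flag tracks the number of distinct states", {
  gm <- toy_genome()
  expect_true(score_chromosome(make_switch_profile(12, n_states = 3), gm)$canonical)
  expect_false(score_chromosome(make_switch_profile(12, n_states = 4), gm)$canonical)
})

test_that("adding a switch inside the window never lowers the tier", {
  gm <- toy_genome()
  rank <- c(none = 0, low = 1, intermediate = 2, high = 3)
  set.seed(11)
  for (k in 5:12) {
    seg <- make_switch_profile(k)
    tier1 <- score_chromosome(seg, gm)
    t1 <- if (nrow(tier1)) rank[tier1$confidence[1]] else 0
    # split one in-window segment, adding one switch
    i <- sample(which(seg$start >= 8e7 & seg$end <= 1.2e8), 1)
    mid <- floor((seg$start[i] + seg$end[i]) / 2)
    newst <- max(seg$state) + 1
    extra <- rbind(seg[seq_len(i - 1), ],
                   transform(seg[i, ], end = mid),
                   transform(seg[i, ], start = mid, copy_number = newst,
                             state = newst),
                   seg[-seq_len(i), ])
    tier2 <- score_chromosome(extra, gm)
    t2 <- if (nrow(tier2)) rank[tier2$confidence[1]] else 0
    expect_gte(t2, t1)
  }
})

test_that("scoring is invariant to scaling coordinates and window together", {
  gm <- toy_genome()
  gm10 <- genome_model(c(chr1 = 2e9))
  seg <- make_switch_profile(9)
  seg10 <- transform(seg, start = start * 10, end = end * 10)
  a <- score_chromosome(seg, gm)
  b <- score_chromosome(seg10, gm10,
                        score_thresholds(window = 5e8, telomere_margin = 1e7))
  expect_equal(b$n_switches, a$n_switches)
  expect_equal(b$confidence, a$confidence)
})

test_that("distant switch clusters become separate calls", {
  gm <- toy_genome()
  a <- make_switch_profile(10, span = 2e7, offset = 5e6)
  b <- make_switch_profile(7, span = 2e7, offset = 1.5e8)
  bounds <- sort(unique(c(a$start, a$end, b$start, b$end)))
  st <- integer(length(bounds) - 1)
  for (i in seq_along(st)) {
    mid <- (bounds[i] + bounds[i + 1]) / 2
    src <- if (mid < 1e8) a else b
    st[i] <- src$state[src$start <= mid & src$end > mid]
  }
  seg <- data.frame(sample = "s1", chrom = "chr1", start = bounds[-length(bounds)],
                    end = bounds[-1], copy_number = st, state = st)
  calls <- score_chromosome(seg, gm)
  expect_equal(nrow(calls), 2)
  expect_equal(sort(calls$confidence), c("high", "low"))
})

test_that("telomere and centromere involvement are annotated from the region", {
  gm <- toy_genome()
  tel <- score_chromosome(make_switch_profile(10, span = 4e7, offset = 5e5), gm)
  expect_true(tel$telomere)
  cen <- score_chromosome(make_switch_profile(10, span = 4e7, offset = 7e7), gm)
  expect_true(cen$centromere)  # chr1 centromere 90-95 Mb
  mid <- score_chromosome(make_switch_profile(10, span = 1e7, offset = 3e7), gm)
  expect_false(mid$telomere)
  expect_false(mid$centromere)
})

test_that("sample summaries aggregate calls across chromosomes", {
  gm <- toy_genome()
  seg <- rbind(make_switch_profile(12, chrom = "chr1"),
               make_switch_profile(8, span = 2e7, offset = 2e7, chrom = "chr2"))
  res <- score_sample(seg, gm)
  expect_equal(res$summary$n_chromosomes, 2)
  expect_true(res$summary$multi_chromosome)
  expect_false(res$summary$heavy)
  expect_true(res$summary$positive_high)
  expect_true(res$summary$positive_intermediate)

  quiet <- score_sample(make_switch_profile(0), gm)
  expect_false(any(unlist(quiet$summary[, c("positive_high",
                                            "positive_intermediate",
                                            "positive_low")])))
})
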