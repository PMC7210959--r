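md_fixture <- function(n, entity = "sarcoma") {
  data.frame(sample = sprintf("%s%03d", substr(entity, 1, 1), seq_len(n)),
             entity = entity, stringsAsFactors = FALSE)
}

test_that("prevalence tables follow tiers and the minimum-case rule", {
  md <- rbind(md_fixture(6, "sarcoma"), md_fixture(3, "rare"))
  calls <- rbind(call_row("s001", "chr1"), call_row("s002", "chr2"),
                 call_row("s003", "chr1"),
                 call_row("r001", "chr1", confidence = "intermediate"))
  res <- prevalence(calls, md)
  expect_equal(res$by_entity$entity, "sarcoma")
  expect_equal(res$by_entity$prevalence, 50)
  expect_equal(res$small_entities$entity, "rare")
  expect_equal(res$overall$prevalence[res$overall$tier == "high"],
               100 * 3 / 9)
  expect_equal(res$overall$prevalence[res$overall$tier == "intermediate"],
               100 * 4 / 9)
  # row order of inputs does not matter
  res2 <- prevalence(calls[c(3, 1, 2), ], md[sample(9, 9), ])
  expect_equal(res2$by_entity, res$by_entity)
})

test_that("prevalence recovers the generator's planted rate", {
  cfg <- cohort_config(seed = 21, n_samples = 120,
                       entities = c(sarcoma = 0.6))
  sim <- simulate_cohort(cfg)
  sc <- score_cohort(sim$segments, sim$genome)
  res <- prevalence(sc$calls, sim$metadata)
  p_hat <- res$by_entity$prevalence / 100
  ci <- stats::binom.test(round(p_hat * 120), 120, 0.6)$p.value
  expect_gt(ci, 0.01)  # planted 0.6 not rejected
})

test_that("the two-hit Fisher test equals hypergeometric enumeration", {
  # carriers: 10 with second hit (5 CT+), 10 without (2 CT+)
  md <- data.frame(sample = sprintf("s%02d", 1:20),
                   germline_gene = "TP53",
                   second_hit = rep(c(TRUE, FALSE), each = 10),
                   stringsAsFactors = FALSE)
  ct_samples <- c(sprintf("s%02d", 1:5), sprintf("s%02d", 11:12))
  calls <- do.call(rbind, lapply(ct_samples, call_row, chrom = "chr1"))
  res <- two_hit_contrast(md, calls)
  expect_equal(matrix(res$table, 2), matrix(c(5, 2, 5, 8), 2))
  # independent oracle: enumerate the hypergeometric tail probabilities
  m <- 7; n_neg <- 13; k <- 10
  probs <- stats::dhyper(0:7, m, n_neg, k)
  p_exact <- sum(probs[probs <= stats::dhyper(5, m, n_neg, k) * (1 + 1e-7)])
  expect_equal(res$p, p_exact, tolerance = 1e-10)
  expect_equal(unname(res$prevalence), c(50, 20))
})

test_that("two-hit contrast flags degenerate strata and handles equality", {
  md <- data.frame(sample = c("a", "b"), germline_gene = "ATM",
                   second_hit = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_warning(res <- two_hit_contrast(md, call_row("a", "chr1")),
                 "stratum")
  expect_true(res$degenerate)

  md2 <- data.frame(sample = sprintf("s%d", 1:8), germline_gene = "ATM",
                    second_hit = rep(c(TRUE, FALSE), each = 4),
                    stringsAsFactors = FALSE)
  calls2 <- rbind(call_row("s1", "chr1"), call_row("s5", "chr1"))
  expect_equal(two_hit_contrast(md2, calls2)$p, 1)
})

test_that("a planted two-hit enrichment is detected in most replicates", {
  set.seed(11)
  hits <- vapply(1:40, function(r) {
    second <- rep(c(TRUE, FALSE), each = 40)
    ct <- stats::rbinom(80, 1, ifelse(second, 0.5, 0.25)) == 1
    md <- data.frame(sample = sprintf("s%02d", 1:80), germline_gene = "TP53",
                     second_hit = second, stringsAsFactors = FALSE)
    calls <- do.call(rbind,
                     lapply(md$sample[ct], call_row, chrom = "chr1"))
    two_hit_contrast(md, calls)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("TERT/ATRX contrast compares each group against neither", {
  set.seed(12)
  n <- c(gain = 160, atrx = 50, neither = 400)
  status <- rep(names(n), n)
  ct <- stats::rbinom(sum(n), 1,
                      c(gain = 0.61, atrx = 0.5, neither = 0.44)[status]) == 1
  md <- data.frame(sample = sprintf("s%03d", seq_len(sum(n))),
                   tert_status = ifelse(status == "gain", "gain", "none"),
                   atrx_daxx_trunc = status == "atrx",
                   stringsAsFactors = FALSE)
  calls <- do.call(rbind,
                   lapply(md$sample[ct], call_row, chrom = "chr1"))
  res <- tert_atrx_contrast(md, calls)
  expect_equal(res$group, c("TERT-gain", "ATRX-trunc", "neither"))
  expect_lt(res$p_vs_neither[1], 0.05)
  expect_true(is.na(res$p_vs_neither[3]))
  # degenerate: no ATRX samples at all
  md2 <- md[status != "atrx", ]
  md2$atrx_daxx_trunc <- FALSE
  expect_warning(tert_atrx_contrast(md2, calls), "degenerate")
})

test_that("type-I error of the TERT contrast is near nominal under the null", {
  set.seed(13)
  rej <- vapply(1:200, function(r) {
    gain <- rep(c(TRUE, FALSE), c(60, 120))
    ct <- stats::rbinom(180, 1, 0.5) == 1
    md <- data.frame(sample = sprintf("s%03d", 1:180),
                     tert_status = ifelse(gain, "gain", "none"),
                     atrx_daxx_trunc = FALSE, stringsAsFactors = FALSE)
    calls <- do.call(rbind,
                     lapply(md$sample[ct], call_row, chrom = "chr1"))
    suppressWarnings(tert_atrx_contrast(md, calls)$p_vs_neither[1]) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.08)  # <= 1.6 x nominal
})

test_that("gain/loss profiles report per-bin per-group frequencies", {
  gm <- toy_genome()
  md <- md_fixture(4)
  base <- do.call(rbind, lapply(md$sample, function(s)
    data.frame(sample = s, chrom = "chr1", start = 0, end = 2e8,
               copy_number = 2, state = 2, stringsAsFactors = FALSE)))
  res0 <- gainloss_profiles(base, call_row("s001", "chr1"), gm)
  expect_true(all(res0$gain_freq == 0) && all(res0$loss_freq == 0))

  seg <- base
  seg[seg$sample == "s001", c("copy_number", "state")] <- 3
  res <- gainloss_profiles(seg, call_row("s001", "chr1"), gm)
  ct1 <- res[res$group == "chromothripsis" & res$chrom == "chr1", ]
  expect_true(all(ct1$gain_freq == 1))
  expect_true(all(res$gain_freq >= 0 & res$gain_freq <= 1))
  expect_equal(sum(unique(res$n_samples[res$group == "chromothripsis"]),
                   unique(res$n_samples[res$group == "negative"])), 4)
})

test_that("signature contrasts use Wilcoxon on log2 exposures with Bonferroni", {
  md <- md_fixture(40)
  md$sigA <- rep(c(100, 200), 20)  # identical multisets in both groups
  md$sigB <- c(stats::rlnorm(20, log(600), 0.5), stats::rlnorm(20, log(150), 0.5))
  calls <- do.call(rbind, lapply(md$sample[1:20], call_row, chrom = "chr1"))
  set.seed(14)
  res <- signature_contrast(md, calls, c("sigA", "sigB"))
  expect_equal(res$p_adj[res$signature == "sigA"], 1)
  expect_lt(res$p_adj[res$signature == "sigB"], 0.05)
  expect_gt(res$median_positive[res$signature == "sigB"],
            res$median_negative[res$signature == "sigB"])
  # oracle: p matches a direct wilcox.test on the transformed values
  w <- stats::wilcox.test(log2(md$sigB[1:20] + 1), log2(md$sigB[21:40] + 1),
                          exact = FALSE)
  expect_equal(res$p[res$signature == "sigB"], w$p.value)
  expect_error(signature_contrast(md, calls[0, ], "sigA"), "empty")
})

test_that("longitudinal verdicts enumerate the five scenarios", {
  expect_equal(longitudinal_verdict("chr5", "chr5"), "stable")
  expect_equal(longitudinal_verdict("chr5", character(0)), "lost")
  expect_equal(longitudinal_verdict(character(0), "chr3"), "gained")
  expect_equal(longitudinal_verdict(character(0), character(0)),
               "both-negative")
  expect_equal(longitudinal_verdict(c("chr5", "chr7"), "chr5"), "changed")
  expect_equal(longitudinal_verdict(c("chr5", "chr7"), "chr5", jaccard = 0.5),
               "stable")
})

test_that("pair classification joins calls and checks patient identity", {
  calls <- rbind(call_row("p1-T1", "chr5"), call_row("p1-T2", "chr5"),
                 call_row("p2-T1", "chr3"))
  pairs <- data.frame(patient = c("p1", "p2"),
                      sample_t1 = c("p1-T1", "p2-T1"),
                      sample_t2 = c("p1-T2", "p2-T2"),
                      stringsAsFactors = FALSE)
  res <- classify_longitudinal(calls, pairs)
  expect_equal(res$verdict, c("stable", "lost"))

  md <- data.frame(sample = c("p1-T1", "p1-T2", "p2-T1", "p2-T2"),
                   patient = c("p1", "px", "p2", "p2"),
                   stringsAsFactors = FALSE)
  expect_error(classify_longitudinal(calls, pairs, metadata = md),
               "mismatch")
})
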