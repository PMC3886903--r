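random_call_panel <- function(n, seed) {
  set.seed(seed)
  total <- sample(40:200, n, replace = TRUE)
  data.frame(
    chromosome = sample(c("chr1", "chr2"), n, replace = TRUE),
    position = sample(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_count = stats::rbinom(n, total, stats::runif(n, 0, 0.4)),
    total_count = total,
    caller_p = 10^-runif(n, 0, 16),
    bq20 = runif(n) > 0.1,
    bq30 = runif(n) > 0.2,
    stringsAsFactors = FALSE)
}

# brute-force oracle: evaluate every rule per call, in the documented order
oracle_filter <- function(calls, anc, oth, mean_depth, cfg) {
  key <- paste(calls$chromosome, calls$position, calls$alt, sep = ":")
  anc_key <- if (is.null(anc)) character(0) else
    paste(anc$chromosome, anc$position, anc$alt, sep = ":")
  oth_key <- if (is.null(oth)) character(0) else
    paste(oth$chromosome, oth$position, oth$alt, sep = ":")
  vapply(seq_len(nrow(calls)), function(i) {
    f <- calls$alt_count[i] / calls$total_count[i]
    if (cfg$exclude_ancestor_calls && key[i] %in% anc_key)
      return("present_in_ancestor")
    if (cfg$require_population_unique && key[i] %in% oth_key)
      return("not_unique_to_population")
    if (cfg$require_both_bq_tiers && !(calls$bq20[i] && calls$bq30[i]))
      return("missing_bq_tier")
    if (calls$caller_p[i] > cfg$p_cutoff) return("caller_p_above_cutoff")
    if (calls$total_count[i] < cfg$min_depth_fraction_of_mean * mean_depth)
      return("insufficient_depth")
    if (f < cfg$min_frequency) return("below_frequency_floor")
    NA_character_
  }, character(1))
}

test_that("allele frequency is alt over total with domain checks", {
  expect_equal(read_allele_frequency(c(8, 80), c(160, 160)), c(0.05, 0.5))
  expect_error(read_allele_frequency(1, 0), "positive")
  expect_error(read_allele_frequency(10, 5), "lie in")
})

test_that("population filter matches the per-call rule oracle", {
  calls <- random_call_panel(300, 1)
  anc <- calls[sample(300, 30), c("chromosome", "position", "alt")]
  oth <- random_call_panel(100, 2)[, c("chromosome", "position", "alt")]
  cfg <- filter_config()
  res <- filter_population_variants(calls, anc, oth, mean_depth = 160,
                                    config = cfg)
  truth <- oracle_filter(calls, anc, oth, 160, cfg)
  expect_equal(nrow(res$retained), sum(is.na(truth)))
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(calls))
  key <- function(d) paste(d$chromosome, d$position, d$alt, d$alt_count)
  expect_setequal(key(res$retained), key(calls)[is.na(truth)])
  truth_rej <- truth[!is.na(truth)]
  names(truth_rej) <- key(calls)[!is.na(truth)]
  expect_equal(unname(truth_rej[key(res$rejected)]), res$rejected$reason)
  expect_equal(res$retained$frequency,
               res$retained$alt_count / res$retained$total_count)
})

test_that("filtering is idempotent and invariant to input order", {
  calls <- random_call_panel(120, 3)
  res <- filter_population_variants(calls, NULL, NULL, mean_depth = 120)
  again <- filter_population_variants(
    res$retained[, names(calls)], NULL, NULL, mean_depth = 120)
  expect_equal(nrow(again$rejected), 0)
  expect_setequal(variant_key(again$retained), variant_key(res$retained))
  shuffled <- filter_population_variants(calls[sample(120), ], NULL, NULL,
                                         mean_depth = 120)
  expect_setequal(variant_key(shuffled$retained), variant_key(res$retained))
})

test_that("each rule toggle disables exactly its rule", {
  calls <- random_call_panel(200, 4)
  anc <- calls[1:20, c("chromosome", "position", "alt")]
  base <- filter_population_variants(calls, anc, NULL, 160)
  off <- filter_population_variants(
    calls, anc, NULL, 160,
    config = filter_config(exclude_ancestor_calls = FALSE))
  expect_false("present_in_ancestor" %in% off$rejected$reason)
  expect_gte(nrow(off$retained), nrow(base$retained))
  nobq <- filter_population_variants(
    calls, anc, NULL, 160,
    config = filter_config(require_both_bq_tiers = FALSE))
  expect_false("missing_bq_tier" %in% nobq$rejected$reason)
})

test_that("detection power is the exact binomial tail", {
  # oracle by direct pmf summation
  oracle <- function(d, f, m) sum(stats::dbinom(m:d, d, f))
  for (cs in list(c(160, 0.05, 4), c(160, 0.05, 8), c(50, 0.2, 5))) {
    expect_equal(detection_power(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  expect_gt(detection_power(160, 0.05, 4), 0.95)
  expect_equal(detection_power(10, 0.5, 11), 0)
  expect_equal(detection_power(10, 0.5, 0), 1)
})

test_that("zygosity classification respects ploidy and bands", {
  expect_equal(
    classify_zygosity(c(0.97, 0.5, 0.5, 0.97, 0.75, 0.2),
                      ploidy = c(1, 1, 2, 2, 2, 2)),
    c("haploid", "ambiguous", "heterozygous", "homozygous", "ambiguous",
      "ambiguous"))
  expect_equal(classify_zygosity(c(0.35, 0.65), 2),
               c("heterozygous", "heterozygous"))
  expect_error(classify_zygosity(0.5, 3), "ploidy")
})

test_that("CNV segment filter enforces both thresholds at the boundary", {
  seg <- data.frame(chromosome = "chr1",
                    start = c(1, 1, 1, 1),
                    end = c(10000, 9999, 10000, 20000),
                    log2_ratio = c(0.6, 0.6, 0.5, -0.51))
  out <- filter_cnv_segments(seg)
  # length 10000 passes (>=), 9999 fails; |log2| exactly 0.5 fails (strict)
  expect_equal(out$end, c(10000, 20000))
  expect_equal(out$log2_ratio, c(0.6, -0.51))
})

test_that("mutation-spectrum binomial tests match the exact values", {
  ct <- coding_bias_test(60, 72)
  expect_equal(ct$p.value, 0.03499243, tolerance = 1e-6)
  nt <- nonsynonymous_fraction_test(52, 72)
  expect_equal(nt$p.value, 0.1911867, tolerance = 1e-6)
  expect_lt(coding_bias_test(60, 72, alternative = "greater")$p.value,
            ct$p.value)
  expect_error(coding_bias_test(10, 20, coding_fraction = 1), "lie in")
})

test_that("per-clone summary averages over all sequenced clones", {
  records <- data.frame(
    clone_id = rep(paste0("cl", 1:18), length.out = 80),
    class = c(rep("SNP_coding_nonsynonymous", 52),
              rep("SNP_coding_synonymous", 8),
              rep("SNP_intergenic", 12), rep("indel", 8)))
  sm <- per_clone_summary(records, clones = paste0("cl", 1:18))
  expect_equal(sm$mean_snps_per_clone, 4)
  expect_equal(sm$mean_indels_per_clone, 8 / 18)
  expect_equal(unname(sm$class_counts["indel"]), 8)
  expect_error(per_clone_summary(data.frame(clone_id = "c", class = "weird")),
               "unknown mutation classes")
})

test_that("expected SNP burden defaults are near one substitution", {
  expect_equal(expected_snp_burden(), 3.3e-10 * 12e6 * 250)
  expect_equal(expected_snp_burden(), 1, tolerance = 0.02)
})

test_that("binomial call score equals the error-model tail", {
  expect_equal(score_calls_binomial(5, 100, 0.005),
               sum(stats::dbinom(5:100, 100, 0.005)), tolerance = 1e-12)
  expect_lt(score_calls_binomial(20, 160, 0.005), 1e-8)
  expect_gt(score_calls_binomial(1, 160, 0.005), 0.5)
})
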