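#' Allele frequency from read counts
#'
#' Number of reads containing the alternative base divided by the total
#' number of bases mapping to the position.
#'
#' @param alt_count,total_count read counts (vectorized).
#' @return frequency in [0,1].
#' @export
read_allele_frequency <- function(alt_count, total_count) {
  if (any(total_count == 0)) stop("total_count must be positive")
  if (any(alt_count < 0) || any(alt_count > total_count))
    stop("alt_count must lie in [0, total_count]")
  alt_count / total_count
}

#' Filtering configuration for population variant calls
#'
#' Defaults encode the heuristics tuned for pooled-population sequencing at
#' ~160x depth: caller p-value at most 1e-8, site depth at least 50% of the
#' sample's mean depth, frequency at least 5% (the detection floor), call
#' present at both the lenient (BQ20) and strict (BQ30) base-quality tiers,
#' absent from the ancestor, and unique to one population.
#'
#' @param p_cutoff maximum caller p-value.
#' @param min_depth_fraction_of_mean minimum site depth as a fraction of mean depth.
#' @param min_frequency minimum allele frequency.
#' @param require_both_bq_tiers,exclude_ancestor_calls,require_population_unique
#'   rule toggles.
#' @export
filter_config <- function(p_cutoff = 1e-8,
                          min_depth_fraction_of_mean = 0.5,
                          min_frequency = 0.05,
                          require_both_bq_tiers = TRUE,
                          exclude_ancestor_calls = TRUE,
                          require_population_unique = TRUE) {
  stopifnot(p_cutoff > 0, p_cutoff <= 1,
            min_frequency > 0, min_frequency < 1,
            min_depth_fraction_of_mean >= 0)
  structure(list(p_cutoff = p_cutoff,
                 min_depth_fraction_of_mean = min_depth_fraction_of_mean,
                 min_frequency = min_frequency,
                 require_both_bq_tiers = require_both_bq_tiers,
                 exclude_ancestor_calls = exclude_ancestor_calls,
                 require_population_unique = require_population_unique),
            class = "filter_config")
}

variant_key <- function(calls) {
  paste(calls$chromosome, calls$position, calls$alt, sep = ":")
}

#' Filter SNP calls from a heterogeneous population
#'
#' Applies, in order: (1) absent from the ancestor; (2) unique to this
#' population among the provided populations; (3) present at both
#' base-quality tiers; (4) caller p-value at most the cutoff; (5) site depth
#' at least the configured fraction of the mean depth; (6) allele frequency
#' at least the floor. The first failing rule per call is logged. The result
#' is independent of input order and idempotent.
#'
#' @param calls data.frame of candidate calls with columns
#'   \code{chromosome}, \code{position}, \code{ref}, \code{alt},
#'   \code{alt_count}, \code{total_count}, \code{caller_p},
#'   \code{bq20}, \code{bq30} (logical presence at each tier).
#' @param ancestor_calls calls identified in the ancestor (same columns or
#'   at least chromosome/position/alt); NULL disables rule 1.
#' @param other_population_calls calls from the other sequenced populations;
#'   NULL disables rule 2.
#' @param mean_depth mean read depth of this sample.
#' @param config a [filter_config()].
#' @return list with \code{retained} (calls plus \code{frequency}) and
#'   \code{rejected} (calls plus \code{reason}).
#' @export
filter_population_variants <- function(calls, ancestor_calls = NULL,
                                       other_population_calls = NULL,
                                       mean_depth, config = filter_config()) {
  stopifnot(mean_depth > 0, inherits(config, "filter_config"))
  if (!nrow(calls))
    return(list(retained = calls, rejected = cbind(calls, reason = character(0))))
  freq <- read_allele_frequency(calls$alt_count, calls$total_count)
  anc <- if (!is.null(ancestor_calls) && nrow(ancestor_calls))
    variant_key(ancestor_calls) else character(0)
  oth <- if (!is.null(other_population_calls) && nrow(other_population_calls))
    variant_key(other_population_calls) else character(0)
  key <- variant_key(calls)

  reason <- rep(NA_character_, nrow(calls))
  fail <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  if (config$exclude_ancestor_calls)
    fail(key %in% anc, "present_in_ancestor")
  if (config$require_population_unique)
    fail(key %in% oth, "not_unique_to_population")
  if (config$require_both_bq_tiers)
    fail(!(calls$bq20 & calls$bq30), "missing_bq_tier")
  fail(calls$caller_p > config$p_cutoff, "caller_p_above_cutoff")
  fail(calls$total_count < config$min_depth_fraction_of_mean * mean_depth,
       "insufficient_depth")
  fail(freq < config$min_frequency, "below_frequency_floor")

  keep <- is.na(reason)
  retained <- calls[keep, , drop = FALSE]
  retained$frequency <- freq[keep]
  rejected <- calls[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Probability of detecting a variant at given depth and frequency
#'
#' Exact binomial tail: the probability that at least \code{min_alt_reads}
#' of \code{depth} reads carry the variant when its true frequency is
#' \code{true_freq}. At the study's operating point (~160x, 5%) detection
#' power exceeds 0.95 for modest read-count thresholds.
#'
#' @param depth reads at the site.
#' @param true_freq true allele frequency.
#' @param min_alt_reads minimum supporting reads required to call.
#' @export
detection_power <- function(depth, true_freq, min_alt_reads) {
  stopifnot(depth >= 1, true_freq >= 0, true_freq <= 1)
  if (min_alt_reads > depth) return(0)
  if (min_alt_reads <= 0) return(1)
  stats::pbinom(min_alt_reads - 1, depth, true_freq, lower.tail = FALSE)
}

#' Classify zygosity from call frequency
#'
#' Haploid clones require call frequencies near 1; diploidized clones may
#' carry heterozygous mutations with call frequency near 0.5. The haploid /
#' homozygous threshold and the heterozygous band quantify "close to 1.0"
#' and "near 0.5".
#'
#' @param frequency call frequency (vectorized).
#' @param ploidy 1 or 2.
#' @param het_band inclusive frequency band for heterozygous calls.
#' @param hom_min minimum frequency for haploid/homozygous calls.
#' @return character vector in \{"haploid","heterozygous","homozygous",
#'   "ambiguous"\}.
#' @export
classify_zygosity <- function(frequency, ploidy, het_band = c(0.35, 0.65),
                              hom_min = 0.90) {
  stopifnot(all(ploidy %in% c(1, 2)))
  ploidy <- rep_len(ploidy, length(frequency))
  out <- rep("ambiguous", length(frequency))
  out[ploidy == 1 & frequency >= hom_min] <- "haploid"
  out[ploidy == 2 & frequency >= hom_min] <- "homozygous"
  out[ploidy == 2 & frequency >= het_band[1] &
        frequency <= het_band[2]] <- "heterozygous"
  out
}

#' Filter copy-number segments for reporting
#'
#' Keeps amplified or deleted segments with length of at least
#' \code{min_length} (1-based inclusive: end - start + 1) and mean |log2
#' ratio| strictly greater than \code{min_abs_log2}.
#'
#' @param segments data.frame with \code{chromosome}, \code{start},
#'   \code{end}, \code{log2_ratio}.
#' @param min_length minimum segment length in bp (default 10 kb).
#' @param min_abs_log2 log2-ratio magnitude threshold (default 0.5).
#' @export
filter_cnv_segments <- function(segments, min_length = 10000,
                                min_abs_log2 = 0.5) {
  stopifnot(all(segments$start <= segments$end))
  len <- segments$end - segments$start + 1
  keep <- len >= min_length & abs(segments$log2_ratio) > min_abs_log2
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact binomial test for coding-region bias of SNPs
#'
#' Tests whether the observed fraction of SNPs in coding sequence deviates
#' from the genome's coding fraction (0.72 for yeast). The two-sided p-value
#' follows the minimal-likelihood convention of the exact binomial test; the
#' one-sided (enrichment) alternative is also available.
#'
#' @param n_in_coding SNPs found in coding regions.
#' @param n_total total SNPs.
#' @param coding_fraction null proportion.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return an object of class \code{htest} from [stats::binom.test()].
#' @export
coding_bias_test <- function(n_in_coding, n_total, coding_fraction = 0.72,
                             alternative = "two.sided") {
  if (coding_fraction <= 0 || coding_fraction >= 1)
    stop("coding_fraction must lie in (0,1)")
  stopifnot(n_in_coding >= 0, n_in_coding <= n_total)
  stats::binom.test(n_in_coding, n_total, coding_fraction,
                    alternative = alternative)
}

#' Exact binomial test for the nonsynonymous fraction of coding SNPs
#'
#' Compares the observed nonsynonymous fraction against the expected fraction
#' under no selection on protein-coding changes (0.79 for random mutations in
#' yeast coding sequence).
#'
#' @param n_nonsyn nonsynonymous SNPs.
#' @param n_coding_snps coding SNPs.
#' @param expected_fraction null proportion.
#' @inheritParams coding_bias_test
#' @return an \code{htest} object.
#' @export
nonsynonymous_fraction_test <- function(n_nonsyn, n_coding_snps,
                                        expected_fraction = 0.79,
                                        alternative = "two.sided") {
  if (expected_fraction <= 0 || expected_fraction >= 1)
    stop("expected_fraction must lie in (0,1)")
  stopifnot(n_nonsyn >= 0, n_nonsyn <= n_coding_snps)
  stats::binom.test(n_nonsyn, n_coding_snps, expected_fraction,
                    alternative = alternative)
}

MUTATION_CLASSES <- c("SNP_coding_synonymous", "SNP_coding_nonsynonymous",
                      "SNP_intergenic", "indel", "CNV_amplification",
                      "CNV_deletion", "aneuploidy",
                      "whole_genome_duplication")

#' Per-clone mutation-spectrum summary
#'
#' Mean SNPs and indels per clone and tallies per mutation class. Clones with
#' no recorded mutations still count in the denominator, so pass the full
#' clone list when some clones are mutation-free.
#'
#' @param records data.frame with \code{clone_id} and \code{class} (one of
#'   the closed class set; SNP classes are those prefixed "SNP_").
#' @param clones character vector of all sequenced clones (default: those
#'   appearing in \code{records}).
#' @return list with \code{n_clones}, \code{mean_snps_per_clone},
#'   \code{mean_indels_per_clone}, \code{class_counts}.
#' @export
per_clone_summary <- function(records, clones = unique(records$clone_id)) {
  if (!length(clones)) stop("at least one clone required")
  bad <- setdiff(records$class, MUTATION_CLASSES)
  if (length(bad)) stop("unknown mutation classes: ",
                        paste(unique(bad), collapse = ", "))
  n_snp <- sum(startsWith(records$class, "SNP_"))
  n_indel <- sum(records$class == "indel")
  counts <- table(factor(records$class, levels = MUTATION_CLASSES))
  list(n_clones = length(clones),
       mean_snps_per_clone = n_snp / length(clones),
       mean_indels_per_clone = n_indel / length(clones),
       class_counts = counts)
}

#' Expected SNP burden from the spontaneous substitution rate
#'
#' Point expectation of the number of substitutions accumulated per lineage:
#' rate per site per generation, times genome size, times generations.
#' Defaults use the measured spontaneous nucleotide substitution rate for
#' yeast (3.3e-10 per site per generation), a 12 Mb genome and 250
#' generations, giving ~1.0 -- the benchmark against which the observed mean
#' of 4 SNPs per clone is elevated.
#'
#' @param substitution_rate per site per generation.
#' @param genome_size sites.
#' @param n_generations generations of selection.
#' @export
expected_snp_burden <- function(substitution_rate = 3.3e-10,
                                genome_size = 12e6, n_generations = 250) {
  stopifnot(substitution_rate >= 0, genome_size > 0, n_generations > 0)
  substitution_rate * genome_size * n_generations
}

#' Binomial error-model score for synthetic variant calls
#'
#' A simple stand-in caller statistic for simulated data: the binomial tail
#' probability of observing at least the seen number of alternative reads
#' under a pure sequencing-error model. This is not the statistic of any
#' published caller; real data should carry the upstream caller's p-value in
#' \code{caller_p}.
#'
#' @param alt_count,total_count read counts.
#' @param error_rate per-base sequencing error rate.
#' @export
score_calls_binomial <- function(alt_count, total_count, error_rate = 0.005) {
  stopifnot(error_rate > 0, error_rate < 1)
  stats::pbinom(alt_count - 1, total_count, error_rate, lower.tail = FALSE)
}
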