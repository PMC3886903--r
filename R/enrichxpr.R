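#' Expression profile of one sample
#'
#' Per-gene log2 ratios against the common hybridization reference, tagged
#' with the growth environment so that clone profiles can be normalized to
#' the ancestor grown in the same environment.
#'
#' @param sample_id sample identifier.
#' @param environment growth-environment label.
#' @param log2_ratio named numeric vector (names = gene ids, values finite).
#' @export
expression_profile <- function(sample_id, environment, log2_ratio) {
  stopifnot(is.numeric(log2_ratio), !is.null(names(log2_ratio)),
            !anyDuplicated(names(log2_ratio)), all(is.finite(log2_ratio)))
  structure(list(sample_id = sample_id, environment = environment,
                 log2_ratio = log2_ratio),
            class = "expression_profile")
}

#' Normalize a clone's expression to the ancestor in the same environment
#'
#' Subtracts the ancestor's log2 ratios gene-by-gene (division of
#' abundances), removing the environmental component of the response so that
#' what remains is expression variation specific to the evolved clone.
#'
#' @param clone_profile,ancestor_profile \code{expression_profile} objects
#'   on the same gene universe; environments must match.
#' @return an \code{expression_profile} of adjusted log2 ratios.
#' @export
normalize_to_ancestor <- function(clone_profile, ancestor_profile) {
  stopifnot(inherits(clone_profile, "expression_profile"),
            inherits(ancestor_profile, "expression_profile"))
  if (!identical(clone_profile$environment, ancestor_profile$environment))
    stop("environment mismatch: clone grown in '", clone_profile$environment,
         "', ancestor in '", ancestor_profile$environment, "'")
  g <- names(clone_profile$log2_ratio)
  if (!setequal(g, names(ancestor_profile$log2_ratio)))
    stop("gene universes differ between clone and ancestor profiles")
  adj <- clone_profile$log2_ratio -
    ancestor_profile$log2_ratio[g]
  expression_profile(clone_profile$sample_id, clone_profile$environment, adj)
}

#' Permutation test for expression divergence of a gene set
#'
#' Statistic: mean absolute log2 expression ratio over the set (default
#' scale: the 38-gene NCR regulon). Null distribution: the same statistic on
#' \code{n_perm} random gene sets of equal size drawn without replacement
#' from all measured genes. The p-value is the probability of a null value
#' at least as large as observed; by default the add-one estimator
#' \eqn{(1 + \#\{null \ge stat\}) / (n_{perm} + 1)} is used so a finite
#' number of permutations never reports p = 0 (set \code{add_one = FALSE}
#' for the plain fraction).
#'
#' @param log2_ratio named numeric vector of per-gene log2 ratios (or an
#'   \code{expression_profile}).
#' @param set character vector of member genes.
#' @param n_perm number of random sets (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @param add_one use the add-one p estimator (default TRUE).
#' @return list: \code{statistic}, \code{p}, \code{n_perm},
#'   \code{null_mean}, \code{null_sd}, \code{null_q95}.
#' @export
gene_set_divergence_test <- function(log2_ratio, set, n_perm = 1000,
                                     seed = NULL, add_one = TRUE) {
  if (inherits(log2_ratio, "expression_profile"))
    log2_ratio <- log2_ratio$log2_ratio
  stopifnot(n_perm >= 1)
  missing <- setdiff(set, names(log2_ratio))
  if (length(missing))
    stop("set members missing from profile: ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  stat <- mean(abs(log2_ratio[set]))
  n <- length(log2_ratio); k <- length(set)
  absx <- abs(log2_ratio)
  null <- vapply(seq_len(n_perm),
                 function(i) mean(absx[sample.int(n, k)]), numeric(1))
  p <- if (add_one) (1 + sum(null >= stat)) / (n_perm + 1)
  else mean(null >= stat)
  list(statistic = stat, p = p, n_perm = n_perm,
       null_mean = mean(null), null_sd = stats::sd(null),
       null_q95 = unname(stats::quantile(null, 0.95)))
}

#' Functional-term enrichment of mutated loci
#'
#' One-tailed Fisher exact test per functional term with Bonferroni
#' correction. Counting rules: hit genes without any annotation are excluded
#' first; loci with multiple independent alleles contribute one count per
#' allele; terms annotated to fewer than \code{min_term_size} or more than
#' \code{max_term_size} genes (within the universe) are dropped before
#' testing, and the Bonferroni multiplier is the number of terms actually
#' tested. The 2x2 table counts mutation events in the hit margin and genes
#' in the universe margin.
#'
#' @param hits named integer vector (gene id -> number of independent
#'   mutation events) or a character vector of hit genes (possibly
#'   repeated), e.g. the output of [map_mutations_to_genes()].
#' @param term2gene data.frame with columns \code{term} and \code{gene}.
#' @param universe all assayed genes (default: all annotated genes).
#' @param min_term_size,max_term_size inclusive size bounds (defaults 2 and
#'   100).
#' @return data.frame per term: \code{term}, \code{size}, \code{count},
#'   \code{expected}, \code{odds_ratio}, \code{p}, \code{p_bonferroni},
#'   sorted by p.
#' @export
functional_enrichment <- function(hits, term2gene,
                                  universe = unique(term2gene$gene),
                                  min_term_size = 2, max_term_size = 100) {
  if (is.character(hits)) {
    tab <- table(hits)
    hits <- stats::setNames(as.integer(tab), names(tab))
  }
  stopifnot(all(hits >= 1))
  if (!length(hits)) stop("empty mutated set")
  term2gene <- term2gene[term2gene$gene %in% universe, , drop = FALSE]
  annotated <- unique(term2gene$gene)
  hits <- hits[names(hits) %in% annotated]   # drop loci with no annotation
  if (!length(hits)) stop("no mutated locus carries any annotation")
  n_events <- sum(hits)
  N <- length(universe)

  genes_by_term <- split(term2gene$gene, term2gene$term)
  sizes <- lengths(lapply(genes_by_term, unique))
  keep <- sizes >= min_term_size & sizes <= max_term_size
  genes_by_term <- genes_by_term[keep]
  sizes <- sizes[keep]
  m <- length(genes_by_term)
  if (!m) stop("no terms within the size bounds")

  res <- lapply(seq_len(m), function(i) {
    gs <- unique(genes_by_term[[i]])
    k <- sum(hits[names(hits) %in% gs])
    tab <- matrix(c(k, n_events - k,
                    max(sizes[i] - k, 0),
                    max(N - sizes[i] - (n_events - k), 0)),
                  nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(term = names(genes_by_term)[i], size = sizes[i],
               count = k, expected = n_events * sizes[i] / N,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * m)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map mutations to gene hits for enrichment counting
#'
#' Coding mutations count toward their gene; intergenic mutations count
#' toward both neighboring genes; multiple independent alleles at one locus
#' each add a count.
#'
#' @param positions numeric vector of mutated positions on the toy
#'   chromosome.
#' @param annotation an \code{annotation_set}.
#' @return named integer vector gene -> event count.
#' @export
map_mutations_to_genes <- function(positions, annotation) {
  gene_hits <- unlist(lapply(positions, function(p)
    locate_position(annotation, p)$genes))
  if (!length(gene_hits)) return(stats::setNames(integer(0), character(0)))
  tab <- table(gene_hits)
  stats::setNames(as.integer(tab), names(tab))
}

#' Correlation between gene copy number and expression
#'
#' Pearson correlation (with two-sided t-test) between per-gene DNA log2
#' ratios and mRNA log2 ratios; amplified regions driving expression up
#' produce the small positive correlation seen in aCGH/transcriptome
#' comparisons.
#'
#' @param cnv_log2,expr_log2 paired per-gene values (same genes, same order
#'   or both named).
#' @return list \code{r}, \code{p}, \code{n}; \code{r} is NA with a note
#'   when either vector has zero variance.
#' @export
copy_number_expression_correlation <- function(cnv_log2, expr_log2) {
  if (!is.null(names(cnv_log2)) && !is.null(names(expr_log2)))
    expr_log2 <- expr_log2[names(cnv_log2)]
  stopifnot(length(cnv_log2) == length(expr_log2))
  if (length(cnv_log2) < 3) stop("need at least 3 paired genes")
  if (stats::sd(cnv_log2) == 0 || stats::sd(expr_log2) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(cnv_log2),
                note = "zero variance: correlation undefined"))
  ct <- stats::cor.test(cnv_log2, expr_log2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cnv_log2))
}

#' Transcriptome divergence among profiles
#'
#' Distribution of all pairwise Pearson correlation coefficients between
#' expression profiles on a shared gene universe; similar clones give
#' correlations near 1, diverged clones spread the distribution.
#'
#' @param profiles gene x sample numeric matrix (column names = samples).
#' @return list with \code{pairs} (data.frame \code{sample_a},
#'   \code{sample_b}, \code{r}) and \code{quantiles}.
#' @export
transcriptome_divergence <- function(profiles) {
  stopifnot(is.matrix(profiles))
  if (ncol(profiles) < 2) stop("need at least 2 profiles")
  cm <- stats::cor(profiles)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(sample_a = colnames(profiles)[idx[, 1]],
                      sample_b = colnames(profiles)[idx[, 2]],
                      r = cm[idx], stringsAsFactors = FALSE)
  list(pairs = pairs,
       quantiles = stats::quantile(pairs$r, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Filter a gene set to responsive genes
#'
#' Keeps set members with at least one observation whose |log2 ratio|
#' exceeds the threshold (default 1.5), the display filter used for the NCR
#' expression heatmap (29 of the 38 NCR genes passed it).
#'
#' @param profiles gene x sample matrix of log2 ratios.
#' @param set gene set (subset of rownames).
#' @param min_abs_log2 strict magnitude threshold.
#' @return character vector of retained genes.
#' @export
expression_response_filter <- function(profiles, set, min_abs_log2 = 1.5) {
  missing <- setdiff(set, rownames(profiles))
  if (length(missing))
    stop("set members missing from profiles: ",
         paste(missing, collapse = ", "))
  mx <- apply(abs(profiles[set, , drop = FALSE]), 1, max)
  names(mx)[mx > min_abs_log2]
}
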