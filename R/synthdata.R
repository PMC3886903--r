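#' Simulation configuration for chemostat evolution
#'
#' Bundles the parameters of the genotype-tree Wright-Fisher simulator that
#' emulates an asexual population adapting in a nutrient-limited chemostat.
#' Time is discrete in generations; chemostat continuity enters only through
#' the dilution rate, which sets the wall-clock doubling time (ln2/D) and is
#' otherwise informational.
#'
#' @param population_size constant number of cells (desk-scale default 1e5;
#'   census size in a 200 mL chemostat is ~1e10).
#' @param n_generations number of generations to simulate (default 250).
#' @param dilution_rate chemostat dilution rate in 1/hr (default 0.12).
#' @param mutation_rate beneficial mutations per genome per generation.
#' @param effect_distribution see [effect_distribution()].
#' @param epistasis_overrides named list mapping comma-joined sorted locus sets
#'   (e.g. \code{"gat1,lst4"}) to the total selection coefficient of genotypes
#'   carrying exactly that locus set, replacing additivity. Loci referenced
#'   here must appear in \code{scheduled_mutations}.
#' @param seed RNG seed recorded in all outputs; \code{NULL} leaves the RNG
#'   state untouched.
#' @param sample_generations generations at which observation models sample
#'   the population (default the study design \code{c(24,61,102,137,173,213,250)}).
#' @param founder_freq,founder_s frequencies and selection coefficients of the
#'   founder genotypes (defaults: one neutral founder at frequency 1).
#' @param scheduled_mutations optional data.frame with columns
#'   \code{generation}, \code{parent} (genotype id), \code{locus}, \code{s}
#'   (per-locus effect); each row seeds one new genotype in one cell at the
#'   stated generation. Used to script reproducible sweep scenarios.
#' @param deterministic if TRUE, propagate expected frequencies with no
#'   sampling and no spontaneous mutation (scheduled mutations still fire).
#' @param locus_pool optional character vector; spontaneous mutations draw
#'   locus names from this pool with replacement (enables recurrent alleles
#'   at one locus, tracked as distinct genotype-tree nodes). Default: unique
#'   auto-generated names.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(population_size = 1e5,
                       n_generations = 250,
                       dilution_rate = 0.12,
                       mutation_rate = 0,
                       effect_distribution = NULL,
                       epistasis_overrides = NULL,
                       seed = NULL,
                       sample_generations = c(24, 61, 102, 137, 173, 213, 250),
                       founder_freq = 1,
                       founder_s = 0,
                       scheduled_mutations = NULL,
                       deterministic = FALSE,
                       locus_pool = NULL) {
  stopifnot(population_size >= 1, n_generations >= 1, mutation_rate >= 0,
            dilution_rate > 0, length(founder_freq) == length(founder_s))
  if (is.null(effect_distribution))
    effect_distribution <- chemevolve::effect_distribution()
  if (any(sample_generations > n_generations) || any(sample_generations < 0))
    stop("all sample_generations must lie in [0, n_generations]")
  if (abs(sum(founder_freq) - 1) > 1e-9)
    stop("founder frequencies must sum to 1")
  if (!is.null(scheduled_mutations)) {
    req <- c("generation", "parent", "locus", "s")
    if (!all(req %in% names(scheduled_mutations)))
      stop("scheduled_mutations needs columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(epistasis_overrides)) {
    known <- if (is.null(scheduled_mutations)) character(0) else
      unique(scheduled_mutations$locus)
    ov_loci <- unique(unlist(strsplit(names(epistasis_overrides), ",", fixed = TRUE)))
    bad <- setdiff(ov_loci, known)
    if (length(bad))
      stop("epistasis_overrides reference unknown loci: ",
           paste(bad, collapse = ", "))
  }
  structure(list(population_size = population_size,
                 n_generations = n_generations,
                 dilution_rate = dilution_rate,
                 mutation_rate = mutation_rate,
                 effect_distribution = effect_distribution,
                 epistasis_overrides = epistasis_overrides,
                 seed = seed,
                 sample_generations = sort(sample_generations),
                 founder_freq = founder_freq,
                 founder_s = founder_s,
                 scheduled_mutations = scheduled_mutations,
                 deterministic = deterministic,
                 locus_pool = locus_pool),
            class = "sim_config")
}

#' Distribution of per-mutation selection coefficients
#'
#' @param kind "point" (finite set of effects with probabilities) or
#'   "exponential" (effects drawn from Exp(mean)).
#' @param s effect values for the point distribution.
#' @param prob probabilities for \code{s} (default uniform).
#' @param mean mean of the exponential distribution.
#' @param cnv_prob probability that a mutation belongs to a distinct
#'   large-effect "CNV-like" class (transporter amplifications dominate
#'   adaptation in nutrient-limited chemostats).
#' @param cnv_s selection coefficient of the CNV-like class.
#' @export
effect_distribution <- function(kind = c("point", "exponential"),
                                s = 0.1, prob = NULL, mean = 0.05,
                                cnv_prob = 0, cnv_s = 0.3) {
  kind <- match.arg(kind)
  if (is.null(prob)) prob <- rep(1 / length(s), length(s))
  stopifnot(length(prob) == length(s), all(prob >= 0),
            cnv_prob >= 0, cnv_prob <= 1)
  structure(list(kind = kind, s = s, prob = prob / sum(prob), mean = mean,
                 cnv_prob = cnv_prob, cnv_s = cnv_s),
            class = "effect_distribution")
}

draw_effects <- function(n, dist) {
  if (n == 0) return(numeric(0))
  base <- switch(dist$kind,
                 point = sample(dist$s, n, replace = TRUE, prob = dist$prob),
                 exponential = stats::rexp(n, rate = 1 / dist$mean))
  if (dist$cnv_prob > 0) {
    is_cnv <- stats::runif(n) < dist$cnv_prob
    base[is_cnv] <- dist$cnv_s
  }
  base
}

genotype_s <- function(loci, per_locus_s, overrides) {
  if (!length(loci)) return(0)
  key <- paste(sort(loci), collapse = ",")
  if (!is.null(overrides) && key %in% names(overrides))
    return(unname(overrides[[key]]))
  sum(per_locus_s)
}

#' Simulate adaptive evolution of an asexual population
#'
#' Discrete-generation genotype-tree simulator. Each generation the genotype
#' counts are resampled (multinomially at constant population size) with
#' weights proportional to \code{exp(s)} -- the Malthusian form whose
#' deterministic limit reproduces the logistic sweep
#' \eqn{x_t = x_0 e^{st} / (1 - x_0 + x_0 e^{st})} and whose log-ratio slope
#' between two genotypes equals their selection-coefficient difference, the
#' quantity competition assays measure. New mutations arise on each genotype
#' at rate \code{mutation_rate} per cell; every mutation event founds a new
#' genotype-tree node carrying one additional locus, so recurrent alleles at
#' one locus remain distinct nodes. Genotype fitness is \code{1 + sum(s)} over
#' carried loci unless an \code{epistasis_overrides} entry replaces the sum.
#'
#' @param config a [sim_config()].
#' @return an \code{evolution_result}: list with \code{tree} (data.frame:
#'   \code{id}, \code{parent}, \code{locus}, \code{s_locus}, \code{s},
#'   \code{origin_generation}), \code{loci} (list of locus sets per genotype),
#'   \code{freq} (genotype x generation matrix, columns generations 0..n),
#'   and the \code{config}.
#' @export
simulate_chemostat_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$population_size
  n_gen <- config$n_generations
  ov <- config$epistasis_overrides

  n_found <- length(config$founder_freq)
  ids <- paste0("g", seq_len(n_found) - 1L)
  parent <- rep(NA_character_, n_found)
  locus <- rep(NA_character_, n_found)
  s_locus <- rep(NA_real_, n_found)
  s_geno <- config$founder_s
  origin <- rep(0L, n_found)
  loci <- rep(list(character(0)), n_found)
  counts <- config$founder_freq * N

  freq <- matrix(0, nrow = n_found, ncol = n_gen + 1L)
  freq[, 1L] <- counts / N
  next_id <- n_found
  next_locus <- 1L
  sched <- config$scheduled_mutations

  per_locus_list <- rep(list(numeric(0)), n_found)

  add_genotype <- function(parent_idx, loc, s_loc, gen) {
    new_loci <- c(loci[[parent_idx]], loc)
    per_locus <- c(per_locus_list[[parent_idx]], s_loc)
    ids[next_id + 1L] <<- paste0("g", next_id)
    parent[next_id + 1L] <<- ids[parent_idx]
    locus[next_id + 1L] <<- loc
    s_locus[next_id + 1L] <<- s_loc
    loci[[next_id + 1L]] <<- new_loci
    per_locus_list[[next_id + 1L]] <<- per_locus
    s_geno[next_id + 1L] <<- genotype_s(new_loci, per_locus, ov)
    origin[next_id + 1L] <<- gen
    freq <<- rbind(freq, 0)
    next_id <<- next_id + 1L
  }

  for (g in seq_len(n_gen)) {
    w <- exp(s_geno)
    p <- counts * w
    p <- p / sum(p)
    if (config$deterministic) {
      counts <- N * p
    } else {
      counts <- as.numeric(stats::rmultinom(1L, N, p))
    }

    # spontaneous mutations: at most one new locus per founding cell
    if (!config$deterministic && config$mutation_rate > 0) {
      n_new <- stats::rpois(length(counts), counts * config$mutation_rate)
      n_new <- pmin(n_new, floor(counts))
      for (i in which(n_new > 0)) {
        effs <- draw_effects(n_new[i], config$effect_distribution)
        for (e in effs) {
          loc <- if (is.null(config$locus_pool)) {
            sprintf("L%04d", next_locus)
          } else sample(config$locus_pool, 1L)
          next_locus <- next_locus + 1L
          add_genotype(i, loc, e, g)
          counts[i] <- counts[i] - 1
          counts[next_id] <- 1
        }
      }
    }

    if (!is.null(sched)) {
      for (r in which(sched$generation == g)) {
        pidx <- match(sched$parent[r], ids)
        if (is.na(pidx)) stop("scheduled mutation parent not found: ",
                              sched$parent[r])
        if (counts[pidx] < 1)
          stop("scheduled mutation at generation ", g,
               ": parent genotype ", sched$parent[r], " has no cells")
        add_genotype(pidx, sched$locus[r], sched$s[r], g)
        counts[pidx] <- counts[pidx] - 1
        counts[next_id] <- 1
      }
    }
    freq[, g + 1L] <- counts / N
  }

  tree <- data.frame(id = ids, parent = parent, locus = locus,
                     s_locus = s_locus, s = s_geno,
                     origin_generation = origin,
                     stringsAsFactors = FALSE)
  rownames(freq) <- ids
  colnames(freq) <- as.character(0:n_gen)
  structure(list(tree = tree, loci = loci, freq = freq, config = config),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat("Chemostat evolution simulation\n")
  cat(sprintf("  %d genotypes over %d generations (N = %g)\n",
              nrow(x$tree), x$config$n_generations,
              x$config$population_size))
  fin <- x$freq[, ncol(x$freq)]
  top <- order(fin, decreasing = TRUE)[seq_len(min(5, length(fin)))]
  for (i in top)
    cat(sprintf("  %s [%s] final freq %.3f\n", x$tree$id[i],
                paste(x$loci[[i]], collapse = "+"), fin[i]))
  invisible(x)
}

# sum of frequencies over a node and all its descendants
subtree_frequency <- function(result, node_id, generations = NULL) {
  kids <- split(result$tree$id, result$tree$parent)
  members <- node_id
  queue <- node_id
  while (length(queue)) {
    nxt <- unlist(kids[queue], use.names = FALSE)
    members <- c(members, nxt)
    queue <- nxt
  }
  cols <- if (is.null(generations)) seq_len(ncol(result$freq)) else
    match(as.character(generations), colnames(result$freq))
  colSums(result$freq[members, cols, drop = FALSE])
}

#' True allele frequency of a locus
#'
#' Sum of the frequencies of all genotypes carrying any mutation event at the
#' locus.
#'
#' @param result an \code{evolution_result}.
#' @param locus locus name.
#' @param generation generation(s); default all recorded.
#' @export
allele_frequency_true <- function(result, locus, generation = NULL) {
  carriers <- vapply(result$loci, function(l) locus %in% l, logical(1))
  cols <- if (is.null(generation)) seq_len(ncol(result$freq)) else
    match(as.character(generation), colnames(result$freq))
  colSums(result$freq[carriers, cols, drop = FALSE])
}

#' True frequencies of every mutation event
#'
#' One row per genotype-tree node (excluding founders); the frequency of a
#' mutation event is the summed frequency of the node's subtree (all carriers).
#'
#' @inheritParams allele_frequency_true
#' @param generations generations to report (default: the configured
#'   sample_generations).
#' @return matrix, rows = mutation node ids, columns = generations.
#' @export
mutation_frequency_matrix <- function(result,
                                      generations = result$config$sample_generations) {
  nodes <- result$tree$id[!is.na(result$tree$parent)]
  out <- t(vapply(nodes, function(id)
    subtree_frequency(result, id, generations),
    numeric(length(generations))))
  colnames(out) <- as.character(generations)
  out
}

#' Observation model for allele-frequency measurements
#'
#' @param mode "sanger" (truth + Gaussian noise, clipped to [0,1], with values
#'   below the detection floor reported as 0) or "deepseq" (binomial read
#'   counts at fixed depth).
#' @param noise_sd Gaussian sd in frequency units (sanger).
#' @param detection_floor minimum reportable frequency, default 0.05 -- the
#'   background-noise level of Sanger-based frequency estimates.
#' @param read_depth reads per site, default 160 (the study's average depth).
#' @export
observation_model <- function(mode = c("sanger", "deepseq"),
                              noise_sd = 0.02, detection_floor = 0.05,
                              read_depth = 160) {
  mode <- match.arg(mode)
  stopifnot(detection_floor >= 0, detection_floor < 1,
            read_depth >= 1, noise_sd >= 0)
  structure(list(mode = mode, noise_sd = noise_sd,
                 detection_floor = detection_floor, read_depth = read_depth),
            class = "observation_model")
}

#' Observe allele-frequency trajectories through a measurement model
#'
#' Applies the observation model to the true per-mutation frequencies at the
#' configured sample generations. The detection floor applies to reporting
#' only, never to the underlying truth. A terminal deep-sequencing frequency
#' (binomial at \code{read_depth}) is attached to every trajectory regardless
#' of mode, mirroring the study design in which Sanger time courses were
#' anchored by deep sequencing of the final population.
#'
#' @param result an \code{evolution_result}.
#' @param model an [observation_model()].
#' @return data.frame with columns \code{mutation_id}, \code{locus},
#'   \code{generation}, \code{frequency}, \code{final_deepseq_freq}.
#' @export
observe_allele_frequencies <- function(result, model = observation_model()) {
  stopifnot(inherits(result, "evolution_result"),
            inherits(model, "observation_model"))
  gens <- result$config$sample_generations
  if (!length(gens)) stop("no sample generations configured")
  truth <- mutation_frequency_matrix(result, gens)
  if (!nrow(truth))
    return(data.frame(mutation_id = character(0), locus = character(0),
                      generation = numeric(0), frequency = numeric(0),
                      final_deepseq_freq = numeric(0)))
  n <- nrow(truth); m <- ncol(truth)
  obs <- switch(model$mode,
    sanger = {
      x <- truth + matrix(stats::rnorm(n * m, 0, model$noise_sd), n, m)
      x <- pmin(pmax(x, 0), 1)
      x[x < model$detection_floor] <- 0
      x
    },
    deepseq = {
      matrix(stats::rbinom(n * m, model$read_depth, as.vector(truth)),
             n, m) / model$read_depth
    })
  final_truth <- truth[, m]
  final_deep <- stats::rbinom(n, model$read_depth, final_truth) /
    model$read_depth
  idx <- match(rownames(truth), result$tree$id)
  data.frame(
    mutation_id = rep(rownames(truth), each = m),
    locus = rep(result$tree$locus[idx], each = m),
    generation = rep(gens, times = n),
    frequency = as.vector(t(obs)),
    final_deepseq_freq = rep(final_deep, each = m),
    stringsAsFactors = FALSE)
}

#' Simulate a two-strain competition time course
#'
#' The log abundance ratio of an evolved clone against a fluorescent reference
#' drifts linearly at rate \code{s_true} per generation:
#' \eqn{\ln R_t = \ln R_0 + s t + \epsilon}. Defaults mirror the assay design:
#' a 1:5 starting ratio, sampling every 2-3 generations over ~20 generations
#' (an alternating 2,3-generation grid giving 9 points).
#'
#' @param s_true per-generation selection coefficient of evolved vs reference.
#' @param init_ratio starting evolved:reference ratio (default 1/5).
#' @param n_generations span of the assay (default 20).
#' @param sampling_interval scalar interval, or vector of candidate intervals
#'   used alternately (default \code{c(2,3)}).
#' @param noise_sd sd of Gaussian noise on the ln ratio.
#' @param seed optional RNG seed.
#' @param label assay identifier.
#' @return a [competition_series()].
#' @export
simulate_competition <- function(s_true, init_ratio = 1 / 5,
                                 n_generations = 20,
                                 sampling_interval = c(2, 3),
                                 noise_sd = 0.05, seed = NULL,
                                 label = "assay") {
  stopifnot(init_ratio > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  t <- 0
  gens <- 0
  i <- 0L
  repeat {
    step <- sampling_interval[(i %% length(sampling_interval)) + 1L]
    i <- i + 1L
    if (t + step > n_generations) break
    t <- t + step
    gens <- c(gens, t)
  }
  lr <- log(init_ratio) + s_true * gens +
    stats::rnorm(length(gens), 0, noise_sd)
  competition_series(generations = gens, ratio = exp(lr), label = label)
}

#' Simulate a log2-ratio expression matrix with a shifted gene set
#'
#' Background genes get i.i.d. Gaussian log2 ratios; a target set (default
#' size 38, the scale of the NCR regulon) is displaced by \code{shift} with
#' random sign per gene, shared across samples.
#'
#' @param n_genes number of genes (default 6000, the scale of the yeast ORF
#'   complement on a microarray).
#' @param target_set_size size of the shifted set.
#' @param shift mean absolute log2 displacement of the target set.
#' @param noise_sd background sd.
#' @param n_samples number of profiles (columns).
#' @param seed optional RNG seed.
#' @return list with \code{expr} (gene x sample matrix) and
#'   \code{target_set} (character vector of shifted gene ids).
#' @export
simulate_expression <- function(n_genes = 6000, target_set_size = 38,
                                shift = 2, noise_sd = 0.5, n_samples = 1,
                                seed = NULL) {
  stopifnot(target_set_size <= n_genes)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                 nrow = n_genes,
                 dimnames = list(genes, paste0("sample", seq_len(n_samples))))
  target <- sort(sample(genes, target_set_size))
  signs <- sample(c(-1, 1), target_set_size, replace = TRUE)
  expr[target, ] <- expr[target, ] + signs * shift
  list(expr = expr, target_set = target)
}

#' Generate a toy genome annotation
#'
#' Packs non-overlapping gene intervals onto one linear chromosome so that
#' genes cover approximately \code{coding_fraction} of the genome (default
#' 0.72, the coding fraction of the yeast genome), assigns strands and
#' functional terms, and supports intergenic neighbor lookup.
#'
#' @param n_genes number of genes.
#' @param coding_fraction fraction of the genome covered by genes.
#' @param n_terms number of functional terms.
#' @param term_size_range inclusive range of genes per term.
#' @param genome_length chromosome length in bp.
#' @param seed optional RNG seed.
#' @return an \code{annotation_set}: list with \code{genes} (a
#'   \code{GRanges} with \code{gene_id}), \code{terms} (data.frame
#'   \code{term}, \code{gene}), \code{genome_length}.
#' @export
generate_annotation <- function(n_genes = 100, coding_fraction = 0.72,
                                n_terms = 20, term_size_range = c(2, 20),
                                genome_length = 1e6, seed = NULL) {
  stopifnot(coding_fraction > 0, coding_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  coding_total <- round(coding_fraction * genome_length)
  if (coding_total < n_genes)
    stop("infeasible packing: coding span smaller than gene count")
  gap_total <- genome_length - coding_total
  # near-equal gene lengths with multinomial jitter, exact total coverage
  glen <- rep(coding_total %/% n_genes, n_genes)
  glen[seq_len(coding_total %% n_genes)] <- glen[seq_len(coding_total %% n_genes)] + 1L
  ngaps <- n_genes + 1L
  gaps <- rep(gap_total %/% ngaps, ngaps)
  gaps[seq_len(gap_total %% ngaps)] <- gaps[seq_len(gap_total %% ngaps)] + 1L
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pos <- pos + glen[i]
  }
  genes <- GenomicRanges::GRanges(
    seqnames = "chrI",
    ranges = IRanges::IRanges(start = starts, width = glen),
    strand = sample(c("+", "-"), n_genes, replace = TRUE))
  genes$gene_id <- sprintf("gene%05d", seq_len(n_genes))
  # term sizes cannot exceed the number of genes available
  sizes <- sample(seq(min(term_size_range[1], n_genes),
                      min(term_size_range[2], n_genes)),
                  n_terms, replace = TRUE)
  terms <- do.call(rbind, lapply(seq_len(n_terms), function(i)
    data.frame(term = sprintf("TERM%04d", i),
               gene = sample(genes$gene_id, sizes[i]),
               stringsAsFactors = FALSE)))
  structure(list(genes = genes, terms = terms,
                 genome_length = genome_length),
            class = "annotation_set")
}

#' Locate a genomic position within the toy annotation
#'
#' Returns the gene containing the position, or for intergenic positions both
#' flanking neighbor genes -- the counting rule used when attributing
#' intergenic SNPs to genes in enrichment analysis.
#'
#' @param annotation an \code{annotation_set}.
#' @param position 1-based position on the toy chromosome.
#' @return list with \code{coding} (logical) and \code{genes} (character
#'   vector of one containing gene or up to two neighbors).
#' @export
locate_position <- function(annotation, position) {
  stopifnot(inherits(annotation, "annotation_set"),
            position >= 1, position <= annotation$genome_length)
  g <- annotation$genes
  q <- GenomicRanges::GRanges("chrI", IRanges::IRanges(position, position))
  hit <- GenomicRanges::findOverlaps(q, g)
  if (length(hit))
    return(list(coding = TRUE,
                genes = g$gene_id[S4Vectors::subjectHits(hit)]))
  st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
  left <- which(en < position)
  right <- which(st > position)
  nb <- c(if (length(left)) g$gene_id[left[which.max(en[left])]],
          if (length(right)) g$gene_id[right[which.min(st[right])]])
  list(coding = FALSE, genes = nb)
}
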