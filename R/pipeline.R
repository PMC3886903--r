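#' Pipeline configuration
#'
#' Stage toggles and per-stage parameter overrides for the end-to-end demo
#' workflow on synthetic data. Unknown stage names or parameter blocks are
#' rejected at construction time.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed; every stage derives its RNG state from it, so a
#'   rerun with the same configuration is byte-identical.
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("simulate","fitness","lineage","landscape","variants","enrich")};
#'   execution follows dependency order.
#' @param params named list of per-stage parameter lists; recognized keys
#'   match the defaults in [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("simulate", "fitness", "lineage",
                                       "landscape", "variants", "enrich"),
                            params = list()) {
  known <- c("simulate", "fitness", "lineage", "landscape", "variants",
             "enrich")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  badp <- setdiff(names(params), known)
  if (length(badp))
    stop("unknown parameter block(s): ", paste(badp, collapse = ", "))
  structure(list(out_dir = out_dir, seed = seed,
                 stages = intersect(known, stages), params = params),
            class = "pipeline_config")
}

#' Scripted sweep scenario emulating clonal-interference dynamics
#'
#' A three-locus gene-network scenario: two interfering lineages acquire
#' mutations in a transcription-factor locus, a transporter locus and a
#' trafficking locus in different orders, producing nested soft sweeps of
#' the kind seen in ammonium-limited selections. The scripted dynamics are
#' propagated deterministically (a single new mutant at 1/N would otherwise
#' be lost to drift in most runs, breaking the script); stochasticity enters
#' through the observation model applied downstream.
#'
#' @param population_size,n_generations simulator scale.
#' @param seed recorded in the configuration (selection dynamics are
#'   deterministic; observation noise is seeded separately).
#' @return a [sim_config()].
#' @export
demo_gnp_scenario <- function(population_size = 1e5, n_generations = 250,
                              seed = 1) {
  sched <- data.frame(
    generation = c(8, 15, 55, 95),
    parent = c("g0", "g0", "g1", "g2"),
    locus = c("gat1-a", "mep2-b", "lst4-a", "gat1-b"),
    s = c(0.10, 0.12, 0.08, 0.13),
    stringsAsFactors = FALSE)
  sim_config(population_size = population_size,
             n_generations = n_generations,
             mutation_rate = 0, seed = seed, deterministic = TRUE,
             scheduled_mutations = sched)
}

stage_seed <- function(config, k) (config$seed %% 100000L) * 13L + k

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' \describe{
#'   \item{simulate}{scripted chemostat evolution; writes truth JSON and
#'     observed trajectories, plus competition assays for the fitness stage.}
#'   \item{fitness}{selection-coefficient estimates for all assays.}
#'   \item{lineage}{trajectory clustering, genotype-tree reconstruction,
#'     introduction times, Muller table, Newick tree.}
#'   \item{landscape}{a complete 3-locus landscape measured by simulated
#'     competition assays; epistasis terms, accessible paths, DOT graph.}
#'   \item{variants}{a synthetic population call panel filtered with the
#'     heuristic rules; retained calls and rejection log.}
#'   \item{enrich}{expression simulation, gene-set divergence test, and
#'     functional enrichment of mutated loci on the toy annotation.}
#' }
#' Every output file is recorded in a JSON manifest with its md5 checksum;
#' rerunning with the same configuration and seed reproduces identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with parameters, seed, per-stage
#'   summaries, and file checksums).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  summaries <- list()
  p <- function(stage, defaults) {
    utils::modifyList(defaults, config$params[[stage]] %||% list())
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  sim <- NULL; trajs <- NULL

  if ("simulate" %in% config$stages) {
    sp <- p("simulate", list(population_size = 1e5, n_generations = 250,
                             noise_sd = 0.02))
    sc <- demo_gnp_scenario(sp$population_size, sp$n_generations,
                            seed = stage_seed(config, 1L))
    sim <- simulate_chemostat_evolution(sc)
    set.seed(stage_seed(config, 2L))
    trajs <- observe_allele_frequencies(
      sim, observation_model("sanger", noise_sd = sp$noise_sd))
    write_evolution_json(sim, out("truth.json"))
    write_trajectories_tsv(trajs, out("trajectories.tsv"))
    set.seed(stage_seed(config, 3L))
    assays <- do.call(rbind, lapply(seq_len(4), function(i) {
      s_true <- c(0.10, 0.12, 0.18, 0.25)[i]
      ser <- simulate_competition(s_true, noise_sd = 0.05,
                                  label = paste0("assay", i))
      data.frame(assay_id = ser$label, generation = ser$generations,
                 ratio = ser$ratio, stringsAsFactors = FALSE)
    }))
    write_competition_tsv(assays, out("assays.tsv"))
    files <- c(files, out("truth.json"), out("trajectories.tsv"),
               out("assays.tsv"))
    summaries$simulate <- list(genotypes = nrow(sim$tree),
                               mutations = sum(!is.na(sim$tree$parent)))
  }

  if ("fitness" %in% config$stages) {
    assays <- read_competition_tsv(out("assays.tsv"))
    est <- estimate_fitness_table(assays)
    write_tsv(est, out("fitness_estimates.tsv"))
    files <- c(files, out("fitness_estimates.tsv"))
    summaries$fitness <- list(n_assays = nrow(est),
                              s_range = range(est$s))
  }

  if ("lineage" %in% config$stages) {
    lp <- p("lineage", list(r_min = 0.97, max_final_diff = 0.04,
                            detection_floor = 0.05))
    trajs <- read_trajectories_tsv(out("trajectories.tsv"))
    cl <- cluster_trajectories(trajs, r_min = lp$r_min,
                               max_final_diff = lp$max_final_diff)
    tree <- infer_genotype_nesting(cl)
    intro <- estimate_introduction_times(tree, lp$detection_floor)
    muller <- to_muller_table(tree)
    write_tree_json(tree, out("genotype_tree.json"))
    writeLines(tree_to_newick(tree), out("genotype_tree.nwk"))
    write_tsv(intro, out("introduction_times.tsv"))
    write_tsv(muller, out("muller.tsv"))
    files <- c(files, out("genotype_tree.json"), out("genotype_tree.nwk"),
               out("introduction_times.tsv"), out("muller.tsv"))
    summaries$lineage <- list(n_clusters = length(cl),
                              n_edges = nrow(tree$nodes) - 1L)
  }

  if ("landscape" %in% config$stages) {
    # complete 3-locus panel with sign epistasis at the trafficking locus
    lpars <- p("landscape", list(noise_sd = 0.03, alpha = 0.05))
    truth_s <- c("000" = 0, "100" = 0.10, "010" = 0.12, "001" = 0.002,
                 "110" = 0.25, "101" = 0.17, "011" = 0.18, "111" = 0.20)
    set.seed(stage_seed(config, 4L))
    est <- lapply(names(truth_s), function(g) {
      ser <- simulate_competition(truth_s[[g]], noise_sd = lpars$noise_sd,
                                  label = g)
      estimate_selection_coefficient(ser)
    })
    names(est) <- names(truth_s)
    land <- fitness_landscape(c("gat1", "mep2", "lst4"), est)
    eps <- epistasis_terms(land)
    paths <- accessible_paths(land, alpha = lpars$alpha)
    graph <- build_fitness_graph(land, alpha = lpars$alpha)
    write_landscape_tsv(land, out("landscape.tsv"))
    write_tsv(eps, out("epistasis.tsv"))
    write_tsv(paths, out("paths.tsv"))
    export_dot(graph, out("landscape.dot"))
    files <- c(files, out("landscape.tsv"), out("epistasis.tsv"),
               out("paths.tsv"), out("landscape.dot"))
    summaries$landscape <- list(n_accessible = sum(paths$accessible))
  }

  if ("variants" %in% config$stages) {
    vp <- p("variants", list(mean_depth = 160, n_decoys = 12))
    set.seed(stage_seed(config, 5L))
    real_freq <- c(0.45, 0.30, 0.12, 0.07)
    n <- length(real_freq) + vp$n_decoys
    pos <- sort(sample.int(1e6, n))
    depth <- stats::rpois(n, vp$mean_depth)
    truef <- c(real_freq, rep(0.002, vp$n_decoys))
    alt <- stats::rbinom(n, depth, truef)
    calls <- data.frame(chromosome = "chrI", position = pos,
                        ref = "A", alt = "T",
                        alt_count = alt, total_count = depth,
                        caller_p = score_calls_binomial(alt, depth),
                        bq20 = TRUE, bq30 = TRUE,
                        sample_id = "pop1", sample_kind = "population",
                        stringsAsFactors = FALSE)
    res <- filter_population_variants(calls, mean_depth = vp$mean_depth)
    write_tsv(res$retained, out("variants_retained.tsv"))
    write_tsv(res$rejected, out("variants_rejected.tsv"))
    files <- c(files, out("variants_retained.tsv"),
               out("variants_rejected.tsv"))
    summaries$variants <- list(n_retained = nrow(res$retained),
                               n_rejected = nrow(res$rejected))
  }

  if ("enrich" %in% config$stages) {
    ep <- p("enrich", list(n_genes = 2000, set_size = 38, shift = 1.5,
                           n_perm = 1000))
    sim_x <- simulate_expression(ep$n_genes, ep$set_size, shift = ep$shift,
                                 seed = stage_seed(config, 6L))
    div <- gene_set_divergence_test(sim_x$expr[, 1], sim_x$target_set,
                                    n_perm = ep$n_perm,
                                    seed = stage_seed(config, 7L))
    ann <- generate_annotation(n_genes = 200, n_terms = 30,
                               seed = stage_seed(config, 8L))
    set.seed(stage_seed(config, 9L))
    target_term <- ann$terms$term[1]
    hit_genes <- sample(ann$terms$gene[ann$terms$term == target_term], 3)
    hits <- stats::setNames(c(2L, 1L, 1L), hit_genes)
    enr <- functional_enrichment(hits, ann$terms,
                                 universe = ann$genes$gene_id)
    write_expression_tsv(sim_x$expr, out("expression.tsv"))
    jsonlite::write_json(div, out("divergence.json"), auto_unbox = TRUE,
                         digits = NA)
    write_tsv(enr, out("enrichment.tsv"))
    files <- c(files, out("expression.tsv"), out("divergence.json"),
               out("enrichment.tsv"))
    summaries$enrich <- list(divergence_p = div$p,
                             top_term = enr$term[1])
  }

  manifest <- list(seed = config$seed, stages = config$stages,
                   params = config$params,
                   package_version = as.character(utils::packageVersion("chemevolve")),
                   summaries = summaries,
                   files = data.frame(
                     path = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Write / read a pipeline configuration file
#'
#' Serializes a [pipeline_config()] to YAML (\code{.yaml}/\code{.yml}) or
#' JSON (any other extension). Reading re-validates through
#' [pipeline_config()], so files with unknown stages or parameter blocks are
#' rejected with the offending key named.
#'
#' @param config a \code{pipeline_config}.
#' @param path file path; the extension selects the format.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- list(out_dir = config$out_dir, seed = config$seed,
              stages = as.list(config$stages), params = config$params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(obj, path)
  else
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$out_dir) || is.null(obj$seed))
    stop("pipeline configuration needs out_dir and seed")
  params <- lapply(obj$params, as.list)
  pipeline_config(out_dir = obj$out_dir, seed = obj$seed,
                  stages = unlist(obj$stages), params = params)
}
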