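make_constant_result <- function(freq_value = 0.5, n_gen = 250) {
  # hand-built truth: one mutation held at a constant frequency
  freq <- matrix(rep(c(1 - freq_value, freq_value), n_gen + 1), nrow = 2,
                 dimnames = list(c("g0", "g1"), as.character(0:n_gen)))
  structure(list(
    tree = data.frame(id = c("g0", "g1"), parent = c(NA, "g0"),
                      locus = c(NA, "A"), s_locus = c(NA, 0), s = c(0, 0),
                      origin_generation = c(0L, 1L),
                      stringsAsFactors = FALSE),
    loci = list(character(0), "A"),
    freq = freq,
    config = sim_config(n_generations = n_gen)),
    class = "evolution_result")
}

test_that("a monomorphic founder without mutation stays fixed", {
  cfg <- sim_config(population_size = 1000, n_generations = 50,
                    mutation_rate = 0, seed = 1,
                    sample_generations = c(10, 50))
  res <- simulate_chemostat_evolution(cfg)
  expect_equal(nrow(res$tree), 1L)
  expect_true(all(res$freq == 1))
})

test_that("neutral founders drift without directional bias", {
  finals <- vapply(seq_len(500), function(i) {
    cfg <- sim_config(population_size = 200, n_generations = 20,
                      founder_freq = c(0.5, 0.5), founder_s = c(0, 0),
                      seed = 1000 + i, sample_generations = 20)
    simulate_chemostat_evolution(cfg)$freq["g0", "20"]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * se)
})

test_that("deterministic selection follows the logistic closed form", {
  sched <- data.frame(generation = 1, parent = "g0", locus = "A", s = 0.1)
  cfg <- sim_config(population_size = 100, n_generations = 60,
                    deterministic = TRUE, scheduled_mutations = sched,
                    sample_generations = c(10, 30, 60))
  res <- simulate_chemostat_evolution(cfg)
  x0 <- 0.01; t <- 0:59
  closed <- x0 * exp(0.1 * t) / (1 - x0 + x0 * exp(0.1 * t))
  traj <- allele_frequency_true(res, "A")[as.character(1:60)]
  expect_lt(max(abs(traj - unname(closed))), 1e-6)
})

test_that("genotype frequencies stay normalized and children never exceed carriers", {
  cfg <- sim_config(population_size = 5000, n_generations = 100,
                    mutation_rate = 2e-5, seed = 7,
                    effect_distribution = effect_distribution(s = c(0.05, 0.1)),
                    sample_generations = c(50, 100))
  res <- simulate_chemostat_evolution(cfg)
  expect_true(all(res$freq >= 0 & res$freq <= 1))
  expect_true(all(abs(colSums(res$freq) - 1) < 1e-9))
  kids <- res$tree$id[!is.na(res$tree$parent)]
  for (id in kids) {
    parent <- res$tree$parent[match(id, res$tree$id)]
    expect_true(all(subtree_frequency(res, id) <=
                      subtree_frequency(res, parent) + 1e-9))
  }
})

test_that("fixed seed reproduces identical simulations", {
  mk <- function() simulate_chemostat_evolution(
    sim_config(population_size = 2000, n_generations = 50,
               mutation_rate = 1e-4, seed = 99, sample_generations = 50))
  expect_identical(mk(), mk())
})

test_that("epistasis overrides must reference scheduled loci", {
  expect_error(
    sim_config(epistasis_overrides = list("A,B" = 0.3)),
    "unknown loci")
  sched <- data.frame(generation = c(1, 2), parent = c("g0", "g1"),
                      locus = c("A", "B"), s = c(0.1, 0.1))
  cfg <- sim_config(n_generations = 10, deterministic = TRUE,
                    scheduled_mutations = sched,
                    sample_generations = 10,
                    epistasis_overrides = list("A,B" = 0.5))
  res <- simulate_chemostat_evolution(cfg)
  expect_equal(res$tree$s[res$tree$id == "g2"], 0.5)
})

test_that("noiseless sanger observation reproduces the truth", {
  res <- make_constant_result(0.5)
  obs <- observe_allele_frequencies(
    res, observation_model("sanger", noise_sd = 0))
  expect_true(all(obs$frequency == 0.5))
  expect_equal(unique(obs$locus), "A")
})

test_that("frequencies below the detection floor are reported as zero", {
  res <- make_constant_result(0.04)
  obs <- observe_allele_frequencies(
    res, observation_model("sanger", noise_sd = 0, detection_floor = 0.05))
  expect_true(all(obs$frequency == 0))
})

test_that("deep-sequencing noise matches the binomial variance", {
  res <- make_constant_result(0.5)
  res$config <- sim_config(n_generations = 250, sample_generations = 0:250)
  set.seed(11)
  vals <- unlist(lapply(1:40, function(i)
    observe_allele_frequencies(
      res, observation_model("deepseq", read_depth = 160))$frequency))
  expect_gt(length(vals), 1e4 - 100)
  expect_lt(abs(stats::sd(vals) - sqrt(0.25 / 160)) / sqrt(0.25 / 160), 0.05)
  expect_lt(abs(mean(vals) - 0.5), 3 * sqrt(0.25 / 160) / sqrt(length(vals)))
})

test_that("competition series defaults mirror the assay design", {
  ser <- simulate_competition(0, noise_sd = 0)
  expect_true(all(exp(log(1 / 5)) == ser$ratio))
  expect_gte(length(ser$generations), 7)
  expect_lte(length(ser$generations), 10)
  expect_true(all(diff(ser$generations) %in% c(2, 3)))
  ser2 <- simulate_competition(0.25, noise_sd = 0)
  expect_equal(log(ser2$ratio[ser2$generations == 20]), log(0.2) + 5.0)
})

test_that("expression simulation displaces the target set as constructed", {
  sim <- simulate_expression(n_genes = 2000, target_set_size = 38,
                             shift = 2, noise_sd = 0.1, seed = 3)
  expect_length(sim$target_set, 38)
  expect_lt(abs(mean(abs(sim$expr[sim$target_set, 1])) - 2), 0.1)
  null <- simulate_expression(n_genes = 2000, target_set_size = 38,
                              shift = 0, noise_sd = 0.1, seed = 3)
  expect_lt(mean(abs(null$expr[null$target_set, 1])), 0.15)
})

test_that("toy annotation covers the requested coding fraction", {
  ann <- generate_annotation(n_genes = 100, coding_fraction = 0.72,
                             genome_length = 1e6, seed = 5)
  span <- sum(GenomicRanges::width(ann$genes))
  expect_lt(abs(span - 720000) / 720000, 0.01)
  full <- generate_annotation(n_genes = 50, coding_fraction = 1,
                              genome_length = 1e4, seed = 5)
  for (p in c(1, 17, 5000, 9999))
    expect_true(locate_position(full, p)$coding)
  expect_error(generate_annotation(n_genes = 100, coding_fraction = 0.5,
                                   genome_length = 100),
               "infeasible")
})

test_that("intergenic positions report both neighboring genes", {
  ann <- generate_annotation(n_genes = 10, coding_fraction = 0.5,
                             genome_length = 1e4, seed = 2)
  st <- GenomicRanges::start(ann$genes)
  gap_pos <- st[2] - 2  # inside the gap before gene 2
  loc <- locate_position(ann, gap_pos)
  expect_false(loc$coding)
  expect_setequal(loc$genes, ann$genes$gene_id[1:2])
})
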