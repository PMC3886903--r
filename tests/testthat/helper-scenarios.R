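# Shared scenario builders and truth-comparison utilities.

# Two interfering lineages: root -> A -> B -> D and root -> C, with
# pairwise-distinct trajectories (all r < 0.97 or final diff > 4%) so that
# noiseless clustering yields one singleton cluster per mutation.
nested_sweep_config <- function(population_size = 1e5) {
  sched <- data.frame(
    generation = c(5, 70, 40, 120),
    parent = c("g0", "g1", "g0", "g3"),
    locus = c("A", "B", "C", "D"),
    s = c(0.10, 0.06, 0.13, 0.05),
    stringsAsFactors = FALSE)
  sim_config(population_size = population_size, n_generations = 250,
             deterministic = TRUE, scheduled_mutations = sched)
}

# true parent mutation (nearest mutated ancestor, or "root") per mutation node
truth_parent_map <- function(result) {
  tr <- result$tree
  vapply(tr$id[!is.na(tr$parent)], function(id) {
    p <- tr$parent[match(id, tr$id)]
    while (!is.na(p) && is.na(tr$locus[match(p, tr$id)]))
      p <- tr$parent[match(p, tr$id)]
    if (is.na(p)) "root" else p
  }, character(1))
}

# long trajectory table from a noiseless truth matrix
trajs_from_truth <- function(result) {
  m <- mutation_frequency_matrix(result)
  gens <- as.numeric(colnames(m))
  idx <- match(rownames(m), result$tree$id)
  data.frame(
    mutation_id = rep(rownames(m), each = length(gens)),
    locus = rep(result$tree$locus[idx], each = length(gens)),
    generation = rep(gens, times = nrow(m)),
    frequency = as.vector(t(m)),
    final_deepseq_freq = rep(m[, ncol(m)], each = length(gens)),
    stringsAsFactors = FALSE)
}

# fraction of true (mutation -> parent-mutation) edges recovered by a tree:
# the parent mutation must sit in the same cluster or the parent cluster.
edge_recovery <- function(tree, truth_parent) {
  mut2cl <- list()
  for (cid in setdiff(tree$nodes$id, "root"))
    for (m in tree$members[[cid]]) mut2cl[[m]] <- cid
  ok <- vapply(names(truth_parent), function(m) {
    tp <- truth_parent[[m]]
    mc <- mut2cl[[m]]
    if (is.null(mc)) return(FALSE)
    pc <- tree$nodes$parent[match(mc, tree$nodes$id)]
    if (tp == "root") return(pc == "root")
    tp %in% c(tree$members[[mc]],
              if (pc != "root") tree$members[[pc]])
  }, logical(1))
  mean(ok)
}

# the three-locus landscape mirroring the study's qualitative pattern: the
# trafficking-locus allele (bit 3) is neutral alone, beneficial on either
# single-mutant background, deleterious on the double-mutant background.
sign_epistasis_landscape <- function(se = 0.005) {
  s <- c("000" = 0, "100" = 0.10, "010" = 0.12, "001" = 0.002,
         "110" = 0.25, "101" = 0.17, "011" = 0.18, "111" = 0.20)
  fitness_landscape(
    c("gat1", "mep2", "lst4"),
    data.frame(genotype = names(s), s = unname(s), se = se))
}
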