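long_trajs <- function(mat, gens, finals) {
  data.frame(
    mutation_id = rep(rownames(mat), each = length(gens)),
    generation = rep(gens, times = nrow(mat)),
    frequency = as.vector(t(mat)),
    final_deepseq_freq = rep(finals, each = length(gens)),
    stringsAsFactors = FALSE)
}

test_that("co-moving trajectories merge and dissimilar ones stay apart", {
  gens <- seq(0, 100, by = 10)
  ramp <- gens / 100
  mat <- rbind(m1 = ramp, m2 = 0.98 * ramp, m3 = rev(ramp))
  cl <- cluster_trajectories(long_trajs(mat, gens, c(m1 = 0.9, m2 = 0.89,
                                                     m3 = 0.1)))
  expect_length(cl, 2)
  sets <- lapply(cl, `[[`, "members")
  expect_true(any(vapply(sets, function(s) setequal(s, c("m1", "m2")),
                         logical(1))))
})

test_that("both merge thresholds are strict and jointly required", {
  gens <- 0:10
  ramp <- gens / 10
  # perfectly correlated shapes, finals exactly at the threshold: no merge
  cl <- cluster_trajectories(
    long_trajs(rbind(a = ramp, b = 0.9 * ramp), gens, c(a = 0.50, b = 0.54)),
    max_final_diff = 0.04)
  expect_length(cl, 2)
  # just inside the threshold: merge
  cl2 <- cluster_trajectories(
    long_trajs(rbind(a = ramp, b = 0.9 * ramp), gens, c(a = 0.50, b = 0.539)),
    max_final_diff = 0.04)
  expect_length(cl2, 1)
  # anticorrelated but identical finals: no merge
  cl3 <- cluster_trajectories(
    long_trajs(rbind(a = ramp, b = rev(ramp)), gens, c(a = 0.5, b = 0.5)))
  expect_length(cl3, 2)
})

test_that("no chaining: all cross pairs must satisfy the criterion", {
  gens <- 0:10
  ramp <- gens / 10
  mat <- rbind(a = ramp, b = 0.95 * ramp, c = 0.9 * ramp)
  # a-b and b-c within 4% of each other, a-c not: b joins one, never bridges
  cl <- cluster_trajectories(long_trajs(mat, gens,
                                        c(a = 0.50, b = 0.53, c = 0.56)))
  expect_length(cl, 2)
  expect_false(any(vapply(cl, function(x) length(x$members) == 3, logical(1))))
})

test_that("clustering is invariant to input row order", {
  gens <- seq(0, 100, by = 10)
  set.seed(4)
  mat <- rbind(m1 = gens / 100, m2 = 0.97 * gens / 100,
               m3 = pmin(1, gens / 50), m4 = rev(gens) / 100)
  trajs <- long_trajs(mat, gens, c(m1 = 0.8, m2 = 0.81, m3 = 0.99, m4 = 0.05))
  a <- cluster_trajectories(trajs)
  b <- cluster_trajectories(trajs[sample(nrow(trajs)), ])
  expect_identical(a, b)
})

test_that("constant-zero trajectories are excluded, constants never merged", {
  gens <- 0:10
  mat <- rbind(a = gens / 10, z = rep(0, 11), k = rep(0.5, 11),
               k2 = rep(0.5, 11))
  expect_message(
    expect_warning(
      cl <- cluster_trajectories(long_trajs(mat, gens,
                                            c(a = 0.9, z = 0, k = 0.5,
                                              k2 = 0.5))),
      "never merged"),
    "constant-zero")
  expect_length(cl, 3)
  expect_false("z" %in% unlist(lapply(cl, `[[`, "members")))
})

test_that("same-clone requirement vetoes merges across clones", {
  gens <- 0:10
  ramp <- gens / 10
  trajs <- long_trajs(rbind(a = ramp, b = 0.9 * ramp), gens,
                      c(a = 0.5, b = 0.51))
  expect_length(cluster_trajectories(trajs), 1)
  cl <- cluster_trajectories(trajs, require_same_clone = TRUE,
                             clone_memberships = list(a = "cl1", b = "cl2"))
  expect_length(cl, 2)
  cl2 <- cluster_trajectories(trajs, require_same_clone = TRUE,
                              clone_memberships = list(a = c("cl1", "cl3"),
                                                       b = "cl3"))
  expect_length(cl2, 1)
})

test_that("within-cluster order follows terminal frequency, ties flagged", {
  cluster <- list(id = "C1", members = c("m1", "m2", "m3"),
                  member_finals = c(m1 = 0.95, m2 = 0.90, m3 = 0.90))
  ord <- order_within_cluster(cluster)
  expect_equal(ord$mutation_id, c("m1", "m2", "m3"))
  expect_equal(ord$rank, c(1L, 2L, 2L))
  expect_equal(ord$tied, c(FALSE, TRUE, TRUE))
})

test_that("noiseless nested sweeps reconstruct the true genotype tree", {
  res <- simulate_chemostat_evolution(nested_sweep_config())
  trajs <- trajs_from_truth(res)
  cl <- cluster_trajectories(trajs)
  expect_length(cl, 4)  # all pairwise r < 0.97 by construction
  tree <- infer_genotype_nesting(cl)
  expect_equal(edge_recovery(tree, truth_parent_map(res)), 1)
  # depths reflect root -> A -> B -> D plus root -> C
  expect_setequal(tree$nodes$depth, c(0L, 1L, 1L, 2L, 3L))
})

test_that("noisy replicates recover most true edges", {
  res <- simulate_chemostat_evolution(nested_sweep_config())
  truth <- truth_parent_map(res)
  base <- trajs_from_truth(res)
  set.seed(31)
  rec <- vapply(1:30, function(i) {
    noisy <- base
    noisy$frequency <- pmin(1, pmax(0, base$frequency + rnorm(nrow(base),
                                                              sd = 0.02)))
    edge_recovery(infer_genotype_nesting(cluster_trajectories(noisy)), truth)
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})

test_that("a cluster above total frequency raises a hard error", {
  gens <- 0:5
  cl <- structure(list(list(id = "C1", members = "m1",
                            representative = rep(1.2, 6), final = 1.2,
                            member_finals = c(m1 = 1.2), ties = FALSE)),
                  generations = gens, class = "trajectory_clusters")
  expect_error(infer_genotype_nesting(cl), "exceeding 1")
})

test_that("introduction times use the detection floor with interpolation", {
  raw <- rbind(root = c(1, 1, 1), C1 = c(0.02, 0.08, 0.5),
               C2 = c(0.06, 0.2, 0.3), C3 = c(0.01, 0.02, 0.04))
  colnames(raw) <- c("0", "10", "20")
  tree <- structure(list(
    nodes = data.frame(id = c("root", "C1", "C2", "C3"),
                       parent = c(NA, "root", "root", "root"),
                       depth = c(0L, 1L, 1L, 1L), stringsAsFactors = FALSE),
    raw = raw, members = list(root = character(0), C1 = "m1", C2 = "m2",
                              C3 = "m3"),
    generations = c(0, 10, 20), containment_tol = 0.05),
    class = "genotype_tree")
  intro <- estimate_introduction_times(tree)
  expect_equal(intro$introduction_generation, c(10, 0, NA))
  expect_equal(intro$left_censored, c(FALSE, TRUE, FALSE))
  interp <- estimate_introduction_times(tree, interpolate = TRUE)
  expect_equal(interp$introduction_generation[1],
               (0.05 - 0.02) / (0.08 - 0.02) * 10)
})

test_that("muller table partitions the population at every generation", {
  res <- simulate_chemostat_evolution(nested_sweep_config())
  tree <- infer_genotype_nesting(cluster_trajectories(trajs_from_truth(res)))
  mt <- to_muller_table(tree)
  expect_true(all(mt$frequency >= 0))
  expect_true("ancestor" %in% mt$genotype)
  sums <- tapply(mt$frequency, mt$generation, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("muller export rejects children that exceed their parent", {
  raw <- rbind(root = c(1, 1), C1 = c(0.5, 0.5), C2 = c(0.7, 0.9))
  colnames(raw) <- c("0", "10")
  tree <- structure(list(
    nodes = data.frame(id = c("root", "C1", "C2"),
                       parent = c(NA, "root", "C1"),
                       depth = c(0L, 1L, 2L), stringsAsFactors = FALSE),
    raw = raw, members = list(root = character(0), C1 = "m1", C2 = "m2"),
    generations = c(0, 10), containment_tol = 0.05),
    class = "genotype_tree")
  expect_error(to_muller_table(tree), "negative exclusive frequency for C1")
})
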