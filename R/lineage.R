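#' Cluster allele-frequency trajectories into co-moving groups
#'
#' Mutations that hitchhike in the same genotype move together; their
#' trajectories are merged when every cross pair has Pearson correlation
#' greater than \code{r_min} (default 0.97) and terminal deep-sequencing
#' frequencies differing by less than \code{max_final_diff} (default 0.04).
#' Merging is average-linkage agglomerative under this all-pairs criterion:
#' at each step the eligible cluster pair with the highest mean cross-pair
#' correlation is merged (ties broken by lexicographic mutation id), so the
#' result is deterministic and invariant to input order, and dissimilar
#' trajectories can never chain through intermediates.
#'
#' Constant-zero trajectories are excluded before clustering (they carry no
#' signal); other constant trajectories have undefined correlation and are
#' never merged (with a warning).
#'
#' @param trajs long data.frame with columns \code{mutation_id},
#'   \code{generation}, \code{frequency}, \code{final_deepseq_freq} and
#'   optionally \code{locus}; all trajectories must share one timepoint grid.
#' @param r_min correlation threshold (strict).
#' @param max_final_diff terminal-frequency difference threshold (strict).
#'   The study's Methods use 4\%; its supplementary procedure quotes 5\%.
#' @param require_same_clone if TRUE, two mutations may merge only if they
#'   co-occur in at least one sequenced clone.
#' @param clone_memberships named list: mutation_id -> character vector of
#'   clone ids carrying the mutation.
#' @return object of class \code{trajectory_clusters}: list of clusters, each
#'   with \code{id}, \code{members} (ordered by descending terminal
#'   frequency), \code{representative} (pointwise mean trajectory),
#'   \code{final} (mean terminal frequency), \code{member_finals},
#'   \code{ties} flag; plus attributes \code{generations}.
#' @export
cluster_trajectories <- function(trajs, r_min = 0.97, max_final_diff = 0.04,
                                 require_same_clone = FALSE,
                                 clone_memberships = NULL) {
  req <- c("mutation_id", "generation", "frequency", "final_deepseq_freq")
  stopifnot(all(req %in% names(trajs)))
  if (require_same_clone && is.null(clone_memberships))
    stop("require_same_clone = TRUE needs clone_memberships")

  gens <- sort(unique(trajs$generation))
  ids <- sort(unique(trajs$mutation_id))
  mat <- matrix(NA_real_, length(ids), length(gens),
                dimnames = list(ids, as.character(gens)))
  mat[cbind(match(trajs$mutation_id, ids),
            match(trajs$generation, gens))] <- trajs$frequency
  if (anyNA(mat)) stop("trajectories do not share one timepoint grid")
  finals <- trajs$final_deepseq_freq[match(ids, trajs$mutation_id)]
  names(finals) <- ids

  allzero <- rowSums(mat != 0) == 0
  if (any(allzero)) {
    message("excluding ", sum(allzero), " constant-zero trajectories")
    mat <- mat[!allzero, , drop = FALSE]
    finals <- finals[!allzero]
    ids <- ids[!allzero]
  }
  n <- length(ids)
  if (n == 0) stop("no informative trajectories to cluster")
  constant <- apply(mat, 1, stats::sd) == 0
  if (any(constant))
    warning("constant trajectories have undefined correlation and are never merged: ",
            paste(ids[constant], collapse = ", "))

  cmat <- matrix(-Inf, n, n)
  if (n > 1 && any(!constant)) {
    ok <- which(!constant)
    cmat[ok, ok] <- suppressWarnings(stats::cor(t(mat[ok, , drop = FALSE])))
  }
  mergeable <- function(i, j) {
    !constant[i] && !constant[j] &&
      cmat[i, j] > r_min &&
      abs(finals[i] - finals[j]) < max_final_diff &&
      (!require_same_clone ||
         length(intersect(clone_memberships[[ids[i]]],
                          clone_memberships[[ids[j]]])) > 0)
  }

  clusters <- lapply(seq_len(n), function(i) i)
  repeat {
    best <- NULL; best_score <- -Inf; best_key <- NULL
    nc <- length(clusters)
    if (nc < 2) break
    for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
      mem_a <- clusters[[a]]; mem_b <- clusters[[b]]
      pairs_ok <- all(vapply(mem_a, function(i)
        all(vapply(mem_b, function(j) mergeable(i, j), logical(1))),
        logical(1)))
      if (!pairs_ok) next
      score <- mean(cmat[mem_a, mem_b])
      key <- paste(sort(ids[c(mem_a, mem_b)]), collapse = "|")
      if (score > best_score ||
          (score == best_score && !is.null(best_key) && key < best_key)) {
        best <- c(a, b); best_score <- score; best_key <- key
      }
    }
    if (is.null(best)) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }

  out <- lapply(clusters, function(mem) {
    mids <- ids[mem]
    rep_traj <- colMeans(mat[mids, , drop = FALSE])
    fin <- finals[mids]
    ord <- order(-fin, mids)
    list(members = mids[ord],
         representative = rep_traj,
         final = mean(fin),
         member_finals = fin[ord],
         ties = anyDuplicated(fin) > 0)
  })
  # deterministic output order: descending peak frequency, then first member
  peak <- vapply(out, function(cl) max(cl$representative), numeric(1))
  first <- vapply(out, function(cl) cl$members[1], character(1))
  ord <- order(-peak, first)
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- paste0("C", i)
  structure(out, generations = gens, class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(length(x), "trajectory clusters\n")
  for (cl in x)
    cat(sprintf("  %s: %s (final %.3f)\n", cl$id,
                paste(cl$members, collapse = ", "), cl$final))
  invisible(x)
}

#' Temporal order of mutations within a cluster
#'
#' Mutations that swept together in rapid succession are ordered by their
#' allele frequencies in the final evolved population (deep sequencing): in
#' an asexual lineage the earlier mutation is carried by every cell that
#' carries the later one, so it has the higher terminal frequency. Exact
#' ties are flagged as unordered.
#'
#' @param cluster one element of a [cluster_trajectories()] result.
#' @return data.frame \code{mutation_id}, \code{final_deepseq_freq},
#'   \code{rank}, \code{tied}.
#' @export
order_within_cluster <- function(cluster) {
  fin <- cluster$member_finals
  if (is.null(fin) || anyNA(fin))
    stop("terminal deep-sequencing frequencies missing for cluster members")
  ord <- order(-fin, names(fin))
  fin <- fin[ord]
  tied <- duplicated(fin) | duplicated(fin, fromLast = TRUE)
  data.frame(mutation_id = names(fin), final_deepseq_freq = unname(fin),
             rank = rank(-fin, ties.method = "min"), tied = tied,
             stringsAsFactors = FALSE)
}

#' Reconstruct the nested genotype (lineage) structure
#'
#' Greedy containment-based nesting: clusters are visited in descending order
#' of their time-averaged frequency (pointwise containment implies the
#' parent's mean dominates the child's, and unlike the peak the mean
#' accumulates the containment margin across timepoints, so the visiting
#' order is robust to measurement noise). Each cluster is attached to the
#' deepest existing node whose raw frequency dominates it at every timepoint
#' (within \code{containment_tol}) and whose existing children leave
#' headroom: the k sibling frequencies plus the candidate may not exceed the
#' parent's within \code{containment_tol * sqrt(k + 1)}, the tolerance
#' growing with the number of summed noisy frequencies. Clusters that fit
#' under no node become independent lineages under the ancestral root. Clone
#' genotypes, when supplied, veto parents whose mutations are absent from a
#' clone carrying the child's mutations.
#'
#' @param clusters a \code{trajectory_clusters} object.
#' @param containment_tol absolute frequency tolerance (default 0.05, the
#'   measurement noise floor).
#' @param clone_memberships optional named list mutation_id -> clone ids.
#' @return object of class \code{genotype_tree}: \code{nodes} data.frame
#'   (\code{id}, \code{parent}, \code{depth}), \code{raw} node x generation
#'   frequency matrix (root row = 1), \code{members} list,
#'   \code{generations}, \code{containment_tol}.
#' @export
infer_genotype_nesting <- function(clusters, containment_tol = 0.05,
                                   clone_memberships = NULL) {
  stopifnot(inherits(clusters, "trajectory_clusters"))
  gens <- attr(clusters, "generations")
  tol <- containment_tol
  n <- length(clusters)
  raw <- rbind(root = rep(1, length(gens)),
               t(vapply(clusters, function(cl) cl$representative,
                        numeric(length(gens)))))
  rownames(raw) <- c("root", vapply(clusters, `[[`, character(1), "id"))
  nodes <- data.frame(id = "root", parent = NA_character_, depth = 0L,
                      stringsAsFactors = FALSE)
  members <- list(root = character(0))
  cl_clones <- function(i) unique(unlist(clone_memberships[clusters[[i]]$members]))

  avg <- vapply(clusters, function(cl) mean(cl$representative), numeric(1))
  for (i in order(-avg, vapply(clusters, `[[`, character(1), "id"))) {
    cid <- clusters[[i]]$id
    f <- clusters[[i]]$representative
    if (any(f > 1 + tol))
      stop("cluster ", cid, " has frequency exceeding 1")
    cand <- character(0)
    for (p in nodes$id) {
      pf <- raw[p, ]
      if (any(f > pf + tol)) next              # containment
      kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == p]
      sib_sum <- if (length(kids))
        colSums(raw[kids, , drop = FALSE]) else rep(0, length(gens))
      # headroom tolerance scales with the number of summed noisy frequencies
      if (any(sib_sum + f > pf + tol * sqrt(length(kids) + 1))) next
      if (!is.null(clone_memberships) && p != "root") {
        pj <- match(p, rownames(raw)) - 1L
        child_cl <- cl_clones(i); parent_cl <- cl_clones(pj)
        if (length(child_cl) && length(parent_cl) &&
            !all(child_cl %in% parent_cl)) next  # clone genotype veto
      }
      cand <- c(cand, p)
    }
    # a cluster that fits under no node is an independent lineage from root
    if (!length(cand)) cand <- "root"
    depth <- nodes$depth[match(cand, nodes$id)]
    meanc <- rowMeans(raw[cand, , drop = FALSE])
    pick <- cand[order(-depth, meanc, cand)][1]  # deepest, then tightest
    nodes <- rbind(nodes, data.frame(
      id = cid, parent = pick,
      depth = nodes$depth[match(pick, nodes$id)] + 1L,
      stringsAsFactors = FALSE))
    members[[cid]] <- clusters[[i]]$members
  }
  raw <- raw[nodes$id, , drop = FALSE]
  colnames(raw) <- as.character(gens)
  structure(list(nodes = nodes, raw = raw, members = members,
                 generations = gens, containment_tol = tol),
            class = "genotype_tree")
}

#' @export
print.genotype_tree <- function(x, ...) {
  cat("Genotype tree with", nrow(x$nodes) - 1L, "lineages\n")
  show <- function(id, indent) {
    mem <- x$members[[id]]
    cat(strrep("  ", indent), id,
        if (length(mem)) paste0(" {", paste(mem, collapse = ","), "}") else "",
        "\n", sep = "")
    for (k in x$nodes$id[!is.na(x$nodes$parent) & x$nodes$parent == id])
      show(k, indent + 1L)
  }
  show("root", 0L)
  invisible(x)
}

#' Estimate when each lineage appeared
#'
#' Introduction generation = the earliest sampled generation at which the
#' lineage's raw frequency reaches \code{detection_floor} (default 0.05, the
#' detection limit of the frequency assay). A lineage already at or above the
#' floor at the first sample is left-censored. Optional linear interpolation
#' places the crossing between the flanking samples.
#'
#' @param tree a \code{genotype_tree}.
#' @param detection_floor frequency threshold.
#' @param interpolate if TRUE, interpolate the crossing generation.
#' @return data.frame \code{id}, \code{introduction_generation} (NA when the
#'   floor is never reached), \code{left_censored}.
#' @export
estimate_introduction_times <- function(tree, detection_floor = 0.05,
                                        interpolate = FALSE) {
  stopifnot(inherits(tree, "genotype_tree"))
  gens <- tree$generations
  ids <- setdiff(tree$nodes$id, "root")
  res <- lapply(ids, function(id) {
    f <- tree$raw[id, ]
    k <- which(f >= detection_floor)
    if (!length(k))
      return(data.frame(id = id, introduction_generation = NA_real_,
                        left_censored = FALSE))
    k <- k[1]
    gen <- gens[k]
    if (interpolate && k > 1) {
      g0 <- gens[k - 1]; f0 <- f[k - 1]; f1 <- f[k]
      gen <- g0 + (detection_floor - f0) / (f1 - f0) * (gens[k] - g0)
    }
    data.frame(id = id, introduction_generation = gen,
               left_censored = k == 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Export a genotype tree as a Muller-plot table
#'
#' Converts raw (cumulative) lineage frequencies into exclusive genotype
#' frequencies by subtracting each node's children; the ancestral residual is
#' the root's exclusive frequency. Exclusive frequencies more negative than
#' the tree's containment tolerance raise an error naming the offending node
#' and generation; small negative values (measurement noise) are clipped to 0.
#'
#' @param tree a \code{genotype_tree}.
#' @return long data.frame \code{generation}, \code{genotype},
#'   \code{frequency}, \code{parent}.
#' @export
to_muller_table <- function(tree) {
  stopifnot(inherits(tree, "genotype_tree"))
  tol <- tree$containment_tol
  gens <- tree$generations
  rows <- lapply(tree$nodes$id, function(id) {
    kids <- tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]
    child_sum <- if (length(kids))
      colSums(tree$raw[kids, , drop = FALSE]) else rep(0, length(gens))
    excl <- tree$raw[id, ] - child_sum
    bad <- which(excl < -tol)
    if (length(bad))
      stop("negative exclusive frequency for ", id, " at generation ",
           gens[bad[1]], " (", signif(excl[bad[1]], 3), ")")
    data.frame(generation = gens,
               genotype = if (id == "root") "ancestor" else id,
               frequency = pmax(excl, 0),
               parent = tree$nodes$parent[match(id, tree$nodes$id)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
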