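#' Combinatorial fitness landscape over k loci
#'
#' Holds selection-coefficient estimates (relative to a common reference,
#' normally the ancestor) for genotypes labeled by bit vectors over k named
#' loci; the wild type is all zeros. A complete landscape measures all 2^k
#' combinations, as in the backcrossed strain panel covering every
#' combination of the gat1-2, mep2-2 and lst4-2 alleles.
#'
#' @param loci character vector of locus names (order fixes bit positions).
#' @param estimates named list mapping genotype bitstrings (e.g. "101") to
#'   \code{fitness_estimate} objects, or a data.frame with columns
#'   \code{genotype}, \code{s}, \code{se}.
#' @param reference identifier of the common reference genotype.
#' @return object of class \code{fitness_landscape} with \code{loci},
#'   \code{table} (data.frame \code{genotype}, \code{s}, \code{se}),
#'   \code{reference}.
#' @export
fitness_landscape <- function(loci, estimates, reference = "ancestor") {
  k <- length(loci)
  stopifnot(k >= 1, !anyDuplicated(loci))
  if (is.data.frame(estimates)) {
    tab <- data.frame(genotype = as.character(estimates$genotype),
                      s = estimates$s, se = estimates$se,
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(genotype = names(estimates),
                      s = vapply(estimates, `[[`, numeric(1), "s"),
                      se = vapply(estimates, `[[`, numeric(1), "se"),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tab$genotype)) stop("duplicate genotype labels")
  if (any(nchar(tab$genotype) != k) || any(grepl("[^01]", tab$genotype)))
    stop("genotype labels must be bitstrings of length ", k)
  rownames(tab) <- NULL
  structure(list(loci = loci, table = tab, reference = reference),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape over {%s}, %d/%d genotypes measured\n",
              paste(x$loci, collapse = ", "), nrow(x$table),
              2^length(x$loci)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

bits_of <- function(genotype) as.integer(strsplit(genotype, "")[[1]])
genotype_of <- function(bits) paste(bits, collapse = "")

landscape_lookup <- function(landscape, genotype) {
  i <- match(genotype, landscape$table$genotype)
  if (is.na(i)) return(NULL)
  landscape$table[i, ]
}

landscape_complete <- function(landscape) {
  nrow(landscape$table) == 2^length(landscape$loci)
}

#' Additive expectation for a multi-mutant genotype
#'
#' The null of no epistasis: a genotype's selection coefficient is the sum of
#' its constituent single-mutant coefficients.
#'
#' @param landscape a \code{fitness_landscape}.
#' @param genotype bitstring label.
#' @return expected s under additivity.
#' @export
additive_expectation <- function(landscape, genotype) {
  bits <- bits_of(genotype)
  k <- length(landscape$loci)
  stopifnot(length(bits) == k)
  total <- 0
  for (i in which(bits == 1L)) {
    single <- genotype_of(replace(integer(k), i, 1L))
    row <- landscape_lookup(landscape, single)
    if (is.null(row))
      stop("single mutant ", landscape$loci[i], " (", single,
           ") not measured")
    total <- total + row$s
  }
  total
}

#' Epistasis decomposition of a complete landscape
#'
#' Inclusion-exclusion (Moebius) transform on the selection-coefficient scale:
#' for each locus subset S, \eqn{\epsilon_S = \sum_{T \subseteq S} (-1)^{|S|-|T|} s_T}
#' with \eqn{s_\emptyset = 0}. Singleton terms are the single-mutant effects;
#' higher-order terms are interaction coefficients, zero everywhere iff the
#' landscape is additive. The inverse transform
#' (\eqn{s_S = \sum_{T \subseteq S} \epsilon_T}) reconstructs every measured
#' value exactly. Standard errors are propagated as the root-sum-square over
#' the contributing measurements.
#'
#' @param landscape a complete \code{fitness_landscape}.
#' @return data.frame \code{subset} (comma-joined locus names),
#'   \code{genotype}, \code{order}, \code{epsilon}, \code{se}.
#' @export
epistasis_terms <- function(landscape) {
  k <- length(landscape$loci)
  all_g <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE], 1,
                 paste, collapse = "")
  missing <- setdiff(all_g, landscape$table$genotype)
  if (length(missing))
    stop("incomplete landscape; missing genotypes: ",
         paste(missing, collapse = ", "))
  s <- landscape$table$s[match(all_g, landscape$table$genotype)]
  se <- landscape$table$se[match(all_g, landscape$table$genotype)]
  names(s) <- names(se) <- all_g
  res <- lapply(all_g, function(g) {
    bits <- bits_of(g)
    S <- which(bits == 1L)
    subsets <- expand.grid(rep(list(0:1), length(S)))
    eps <- 0; var_sum <- 0
    for (r in seq_len(nrow(subsets))) {
      sel <- S[unlist(subsets[r, ]) == 1L]
      tg <- genotype_of(replace(integer(k), sel, 1L))
      sign <- (-1)^(length(S) - length(sel))
      val <- if (length(sel) == 0) 0 else s[tg]
      eps <- eps + sign * val
      if (length(sel) > 0) var_sum <- var_sum + se[tg]^2
    }
    data.frame(subset = paste(landscape$loci[S], collapse = ","),
               genotype = g, order = length(S), epsilon = eps,
               se = sqrt(var_sum), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$order, out$genotype), , drop = FALSE]
}

#' Reconstruct genotype fitness values from epistasis terms
#'
#' Inverse of [epistasis_terms()]; used to verify the decomposition is
#' exactly invertible.
#'
#' @param terms output of [epistasis_terms()].
#' @return named numeric vector of s per genotype bitstring.
#' @export
epistasis_to_fitness <- function(terms) {
  gts <- terms$genotype
  eps <- stats::setNames(terms$epsilon, gts)
  vapply(gts, function(g) {
    bits <- bits_of(g)
    S <- which(bits == 1L)
    if (!length(S)) return(0)
    subsets <- expand.grid(rep(list(0:1), length(S)))
    total <- 0
    for (r in seq_len(nrow(subsets))) {
      sel <- S[unlist(subsets[r, ]) == 1L]
      tg <- genotype_of(replace(integer(length(bits)), sel, 1L))
      total <- total + eps[tg]
    }
    unname(total)
  }, numeric(1))
}

delta_with_se <- function(landscape, g_to, g_from) {
  a <- landscape_lookup(landscape, g_to)
  b <- landscape_lookup(landscape, g_from)
  if (is.null(a) || is.null(b))
    stop("missing genotype: ", if (is.null(a)) g_to else g_from)
  list(delta = a$s - b$s, se = sqrt(a$se^2 + b$se^2))
}

#' Classify pairwise epistasis between two loci
#'
#' Computes the fitness effect of each mutation of the pair in both
#' backgrounds (with and without the partner, on top of a fixed background of
#' other loci), with z-tests on propagated standard errors. Sign epistasis:
#' some mutation's effect is significantly positive in one background and
#' significantly negative in the other; reciprocal when this holds for both
#' loci; magnitude epistasis: effects share sign but differ significantly;
#' none otherwise.
#'
#' @param landscape a \code{fitness_landscape}.
#' @param locus_pair two locus names.
#' @param background bitstring over the remaining loci held fixed (default
#'   all ancestral).
#' @param alpha significance level (two-sided threshold \code{qnorm(1-alpha/2)}).
#' @return list with \code{class} in \{"none","magnitude","sign",
#'   "reciprocal_sign"\} and \code{effects}, a data.frame of the four
#'   background-specific effects with z statistics.
#' @export
classify_pairwise_epistasis <- function(landscape, locus_pair,
                                        background = NULL, alpha = 0.05) {
  k <- length(landscape$loci)
  ij <- match(locus_pair, landscape$loci)
  if (anyNA(ij)) stop("unknown loci: ",
                      paste(locus_pair[is.na(ij)], collapse = ", "))
  base <- integer(k)
  if (!is.null(background)) {
    bb <- bits_of(background)
    stopifnot(length(bb) == k - 2)
    base[-ij] <- bb
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  gt <- function(b1, b2) genotype_of(replace(replace(base, ij[1], b1),
                                             ij[2], b2))
  eff <- do.call(rbind, lapply(1:2, function(which_locus) {
    other <- 3 - which_locus
    do.call(rbind, lapply(0:1, function(ob) {
      gfrom <- if (which_locus == 1) gt(0, ob) else gt(ob, 0)
      gto <- if (which_locus == 1) gt(1, ob) else gt(ob, 1)
      d <- delta_with_se(landscape, gto, gfrom)
      data.frame(locus = locus_pair[which_locus],
                 partner_present = ob == 1,
                 delta_s = d$delta, se = d$se,
                 z = if (d$se > 0) d$delta / d$se else
                   ifelse(d$delta == 0, 0, sign(d$delta) * Inf),
                 stringsAsFactors = FALSE)
    }))
  }))
  sig_pos <- eff$z > zcrit
  sig_neg <- eff$z < -zcrit
  per_locus_sign <- vapply(locus_pair, function(l) {
    e <- eff[eff$locus == l, ]
    (any(sig_pos[eff$locus == l]) && any(sig_neg[eff$locus == l]))
  }, logical(1))
  cls <- if (all(per_locus_sign)) "reciprocal_sign"
  else if (any(per_locus_sign)) "sign"
  else {
    # same-sign effects differing significantly for either locus?
    mag <- any(vapply(locus_pair, function(l) {
      e <- eff[eff$locus == l, ]
      d <- e$delta_s[e$partner_present] - e$delta_s[!e$partner_present]
      se <- sqrt(sum(e$se^2))
      se > 0 && abs(d / se) > zcrit
    }, logical(1)))
    if (mag) "magnitude" else "none"
  }
  list(class = cls, effects = eff)
}

#' Enumerate selectively accessible mutational paths
#'
#' Enumerates all k! orderings in which the k mutations can be acquired. A
#' step is favored when the fitness difference along the corresponding
#' hypercube edge is positive -- significantly so at level \code{alpha} on
#' propagated standard errors, or by point estimate when \code{alpha} is NA.
#' A path is accessible when every step is favored; blocked paths report
#' their first blocking step. Orders that place a conditionally beneficial
#' mutation (such as the LST4-like allele, neutral alone and deleterious on
#' the double-mutant background) in the wrong position are blocked.
#'
#' @param landscape a complete \code{fitness_landscape}.
#' @param alpha significance level, or NA to use point estimates.
#' @return data.frame \code{path} (locus order, "+"-joined),
#'   \code{accessible}, \code{first_blocked_step} (NA when accessible).
#' @export
accessible_paths <- function(landscape, alpha = 0.05) {
  k <- length(landscape$loci)
  if (k > 12) stop("k > 12: ", factorial(k),
                   " orderings; restrict to the loci of interest")
  if (!landscape_complete(landscape))
    stop("accessible_paths requires a complete hypercube")
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))))
  }
  zcrit <- if (is.na(alpha)) NA_real_ else stats::qnorm(1 - alpha / 2)
  res <- lapply(perm(seq_len(k)), function(ord) {
    cur <- integer(k)
    blocked_at <- NA_integer_
    for (step in seq_len(k)) {
      nxt <- replace(cur, ord[step], 1L)
      d <- delta_with_se(landscape, genotype_of(nxt), genotype_of(cur))
      favored <- if (is.na(zcrit)) d$delta > 0
      else d$se > 0 && d$delta / d$se > zcrit || (d$se == 0 && d$delta > 0)
      if (!favored) { blocked_at <- step; break }
      cur <- nxt
    }
    data.frame(path = paste(landscape$loci[ord], collapse = "+"),
               accessible = is.na(blocked_at),
               first_blocked_step = blocked_at,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build the hypercube fitness graph
#'
#' Directed edges between Hamming-distance-1 genotypes (toward the genotype
#' with one more mutation), annotated with the fitness difference, a z-test
#' on propagated standard errors, a favored flag (significant increase;
#' exactly zero differences are neutral, not favored), and edge weight
#' |delta s| for display.
#'
#' @param landscape a \code{fitness_landscape}.
#' @param alpha significance level, or NA for point estimates.
#' @return object of class \code{fitness_graph}: data.frame \code{from},
#'   \code{to}, \code{locus}, \code{delta_s}, \code{se}, \code{z}, \code{p},
#'   \code{favored}, \code{weight}.
#' @export
build_fitness_graph <- function(landscape, alpha = 0.05) {
  k <- length(landscape$loci)
  gts <- landscape$table$genotype
  zcrit <- if (is.na(alpha)) NA_real_ else stats::qnorm(1 - alpha / 2)
  edges <- list()
  for (g in gts) {
    bits <- bits_of(g)
    for (i in which(bits == 0L)) {
      h <- genotype_of(replace(bits, i, 1L))
      if (!h %in% gts) next
      d <- delta_with_se(landscape, h, g)
      z <- if (d$se > 0) d$delta / d$se else
        ifelse(d$delta == 0, 0, sign(d$delta) * Inf)
      favored <- if (is.na(zcrit)) d$delta > 0 else
        (d$delta > 0 && (d$se == 0 || z > zcrit))
      edges[[length(edges) + 1L]] <- data.frame(
        from = g, to = h, locus = landscape$loci[i],
        delta_s = d$delta, se = d$se, z = z,
        p = 2 * stats::pnorm(-abs(z)), favored = favored,
        weight = abs(d$delta), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  structure(list(edges = out, loci = landscape$loci,
                 landscape = landscape),
            class = "fitness_graph")
}

#' @export
print.fitness_graph <- function(x, ...) {
  cat("Fitness graph:", nrow(x$edges), "edges over",
      length(x$loci), "loci\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Export a fitness graph as DOT text
#'
#' Solid edges are favored paths, dashed edges disfavored; line width is
#' proportional to the fitness difference across the edge.
#'
#' @param graph a \code{fitness_graph}.
#' @param path output file; NULL returns the DOT string.
#' @export
export_dot <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "fitness_graph"))
  e <- graph$edges
  wmax <- max(e$weight, 1e-12)
  lines <- c("digraph fitness_landscape {",
             "  rankdir=BT;",
             sprintf("  \"%s\" -> \"%s\" [label=\"%s\", penwidth=%.2f, style=%s];",
                     e$from, e$to, e$locus,
                     0.5 + 4 * e$weight / wmax,
                     ifelse(e$favored, "solid", "dashed")),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Re-base fitness estimates measured against a non-ancestral reference
#'
#' When genotypes were competed directly against a mutant reference (as the
#' double mutants were against the triple mutant), their s values are
#' expressed relative to that reference; adding the reference's own s
#' (measured against the ancestor) re-bases them to the ancestral scale, with
#' standard errors combined root-sum-square.
#'
#' @param landscape landscape whose s values are relative to the reference.
#' @param reference_estimate \code{fitness_estimate} of the reference vs the
#'   ancestor.
#' @return a new \code{fitness_landscape} on the ancestral scale, flagged via
#'   attribute \code{rebased}.
#' @export
rebase_landscape <- function(landscape, reference_estimate) {
  stopifnot(inherits(reference_estimate, "fitness_estimate"))
  tab <- landscape$table
  tab$s <- tab$s + reference_estimate$s
  tab$se <- sqrt(tab$se^2 + reference_estimate$se^2)
  out <- fitness_landscape(landscape$loci, tab, reference = "ancestor")
  attr(out, "rebased") <- TRUE
  out
}
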