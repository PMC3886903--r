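#' Competition assay time course
#'
#' A two-strain competition between an evolved clone and a fluorescently
#' labeled reference, recorded either as abundance ratios or as per-strain
#' cell counts (ratio derived). Points where the rarer strain falls below
#' \code{count_floor} cells are flagged unreliable but never dropped.
#'
#' @param generations sampling times in generations (strictly increasing,
#'   at least 3 points).
#' @param ratio evolved/reference abundance ratio per point; omit if counts
#'   are given.
#' @param count_evolved,count_reference per-strain counts (optional).
#' @param label assay identifier.
#' @param reference_genotype identity of the reference strain (ancestor, or
#'   another mutant for direct genotype-vs-genotype competitions).
#' @param count_floor reliability floor on the rarer strain's count.
#' @return object of class \code{competition_series}.
#' @export
competition_series <- function(generations, ratio = NULL,
                               count_evolved = NULL, count_reference = NULL,
                               label = "assay",
                               reference_genotype = "ancestor",
                               count_floor = 100) {
  if (is.null(ratio)) {
    if (is.null(count_evolved) || is.null(count_reference))
      stop("supply either ratio or both count_evolved and count_reference")
    if (any(count_reference <= 0))
      stop("reference counts must be positive to form a ratio")
    ratio <- count_evolved / count_reference
  }
  if (length(generations) != length(ratio))
    stop("generations and ratio differ in length")
  if (length(generations) < 3)
    stop("a competition series needs at least 3 points")
  if (any(diff(generations) <= 0))
    stop("generations must be strictly increasing")
  if (any(ratio <= 0))
    stop("all ratios must be positive (ln transform required)")
  unreliable <- if (!is.null(count_evolved) && !is.null(count_reference))
    pmin(count_evolved, count_reference) < count_floor
  else rep(FALSE, length(ratio))
  structure(list(generations = as.numeric(generations),
                 ratio = as.numeric(ratio), label = label,
                 reference_genotype = reference_genotype,
                 unreliable = unreliable),
            class = "competition_series")
}

#' Estimate a selection coefficient from a competition assay
#'
#' Ordinary least squares of the natural-log abundance ratio on time in
#' generations. The slope is the selection coefficient s per generation, with
#' its standard error and Student-t 95% confidence interval (n - 2 df);
#' relative fitness normalized to the reference is 1 + s. All points are used
#' (no weighting, no exclusion).
#'
#' @param series a [competition_series()].
#' @return object of class \code{fitness_estimate} with fields \code{s},
#'   \code{se}, \code{ci95}, \code{n_points}, \code{df},
#'   \code{relative_fitness}, \code{intercept}, \code{label},
#'   \code{reference_genotype}.
#' @export
estimate_selection_coefficient <- function(series) {
  stopifnot(inherits(series, "competition_series"))
  t <- series$generations
  if (stats::var(t) == 0) stop("zero variance in time points")
  fit <- stats::lm(log(series$ratio) ~ t)
  # noiseless series fit perfectly; the zero-residual warning is benign
  sm <- suppressWarnings(summary(fit))$coefficients
  s <- unname(sm["t", "Estimate"])
  se <- unname(sm["t", "Std. Error"])
  if (!is.finite(se)) se <- 0  # perfect fit: zero residual variance
  df <- length(t) - 2L
  half <- stats::qt(0.975, df) * se
  structure(list(s = s, se = se, ci95 = c(s - half, s + half),
                 n_points = length(t), df = df,
                 relative_fitness = 1 + s,
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 label = series$label,
                 reference_genotype = series$reference_genotype),
            class = "fitness_estimate")
}

#' Construct a fitness estimate directly
#'
#' For landscapes assembled from published or externally computed values.
#' @param s selection coefficient; @param se its standard error;
#' @param df residual degrees of freedom for the CI (default large: normal).
#' @export
fitness_estimate <- function(s, se, df = Inf) {
  half <- stats::qt(0.975, df) * se
  structure(list(s = s, se = se, ci95 = c(s - half, s + half),
                 n_points = NA_integer_, df = df, relative_fitness = 1 + s,
                 intercept = NA_real_, label = NA_character_,
                 reference_genotype = NA_character_),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("s = %.4f (se %.4f), 95%% CI [%.4f, %.4f], relative fitness %.4f\n",
              x$s, x$se, x$ci95[1], x$ci95[2], x$relative_fitness))
  invisible(x)
}

#' @export
coef.fitness_estimate <- function(object, ...) {
  c(s = object$s, intercept = object$intercept)
}

#' @export
confint.fitness_estimate <- function(object, parm = "s", level = 0.95, ...) {
  half <- stats::qt(1 - (1 - level) / 2, object$df) * object$se
  c(object$s - half, object$s + half)
}

#' Compare two fitness estimates
#'
#' Two-sided z-test on the difference of selection coefficients with
#' propagated standard errors.
#'
#' @param a,b \code{fitness_estimate} objects.
#' @return list with \code{delta_s}, \code{z}, \code{p}, and
#'   \code{degenerate} flag (TRUE when both se are 0 and the estimates
#'   differ, reported as infinite z with p = 0).
#' @export
compare_fitness <- function(a, b) {
  stopifnot(inherits(a, "fitness_estimate"), inherits(b, "fitness_estimate"))
  delta <- a$s - b$s
  pooled <- sqrt(a$se^2 + b$se^2)
  if (pooled == 0) {
    if (delta == 0) return(list(delta_s = 0, z = 0, p = 1, degenerate = FALSE))
    return(list(delta_s = delta, z = sign(delta) * Inf, p = 0,
                degenerate = TRUE))
  }
  z <- delta / pooled
  list(delta_s = delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Chemostat doubling time
#'
#' ln2 / D: at the study's dilution rate D = 0.12/hr the population doubling
#' time is 5.8 hours.
#' @param dilution_rate dilution rate in 1/hr.
#' @return doubling time in hours.
#' @export
doubling_time <- function(dilution_rate) {
  if (any(dilution_rate <= 0)) stop("dilution_rate must be positive")
  log(2) / dilution_rate
}

#' Wall-clock duration of a selection experiment
#'
#' @param n_generations number of generations.
#' @param dilution_rate dilution rate in 1/hr.
#' @return duration in days (250 generations at D = 0.12/hr is ~60 days,
#'   i.e. about two months).
#' @export
selection_duration_days <- function(n_generations, dilution_rate) {
  n_generations * doubling_time(dilution_rate) / 24
}

#' Estimate selection coefficients for a table of assays
#'
#' Convenience wrapper over [estimate_selection_coefficient()] for a long
#' table of one or more assays (columns \code{assay_id}, \code{generation},
#' and either \code{ratio} or \code{count_evolved}/\code{count_reference}).
#'
#' @param assays data.frame as above.
#' @return data.frame with one row per assay: \code{assay_id}, \code{s},
#'   \code{se}, \code{ci_lower}, \code{ci_upper}, \code{n_points},
#'   \code{relative_fitness}.
#' @export
estimate_fitness_table <- function(assays) {
  stopifnot(all(c("assay_id", "generation") %in% names(assays)))
  out <- lapply(split(assays, assays$assay_id), function(d) {
    d <- d[order(d$generation), ]
    ser <- if ("ratio" %in% names(d))
      competition_series(d$generation, ratio = d$ratio,
                         label = d$assay_id[1])
    else competition_series(d$generation,
                            count_evolved = d$count_evolved,
                            count_reference = d$count_reference,
                            label = d$assay_id[1])
    est <- estimate_selection_coefficient(ser)
    data.frame(assay_id = d$assay_id[1], s = est$s, se = est$se,
               ci_lower = est$ci95[1], ci_upper = est$ci95[2],
               n_points = est$n_points,
               relative_fitness = est$relative_fitness,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
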