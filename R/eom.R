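# Ensemble optimization: genetic-algorithm selection of a sub-ensemble of
# conformers (with repetition) whose average scattering best fits the data,
# the approach used to detect reduced flexibility of the full-length dimer
# (selected-ensemble Rg below the pool average).

#' Precompute pool scattering curves on a data grid
#'
#' @param pool a `conformer_pool`.
#' @param s_grid momentum transfer grid (1/nm).
#' @param method Debye evaluation method (see [debye_intensity()]).
#' @return matrix: one row per conformer, one column per s point.
#' @export
pool_curves <- function(pool, s_grid, method = "histogram") {
  t(vapply(pool$conformers,
           function(m) debye_intensity(m, s_grid, method = method)$I,
           numeric(length(s_grid))))
}

#' @keywords internal
ensemble_chi2 <- function(avg, I, sig) {
  # optimal multiplicative scale, then reduced chi2
  c0 <- sum(I * avg / sig^2) / sum(avg^2 / sig^2)
  sum(((c0 * avg - I) / sig)^2) / max(1, length(I) - 1)
}

#' Genetic-algorithm ensemble selection against scattering data
#'
#' Selects `ensemble_size` conformers (repetition allowed) from a pool so that
#' the unweighted average of their curves, after an optimal multiplicative
#' scale, minimizes the reduced chi-squared against the data. Chromosomes are
#' index multisets evolved by single-point crossover, per-gene mutation and
#' elitism.
#'
#' @param curves matrix from [pool_curves()] (pool x s points), on the data's
#'   s grid.
#' @param data a [scattering_curve()]; when uncertainties are absent, 1% of I
#'   is assumed and flagged.
#' @param ensemble_size number of selected conformers (study-scale default 50).
#' @param ga list of GA settings: `population` (100), `generations` (200),
#'   `mutation` (0.05), `elitism` (10).
#' @param rng_seed integer seed.
#' @param pool_rg optional per-conformer Rg (nm) for the pool-vs-selected
#'   summary.
#' @return object of class `ensemble_fit`: `indices`, `chi2`, `avg_curve`,
#'   `scale`, `rg_pool`, `rg_selected`, `improved`, `ga`, `seed`.
#' @export
eom_select <- function(curves, data, ensemble_size = 50,
                       ga = list(), rng_seed = 1, pool_rg = NULL) {
  stopifnot(nrow(curves) >= 1)
  if (ensemble_size > nrow(curves) && nrow(curves) == 0) stop("empty pool")
  ga <- utils::modifyList(
    list(population = 100, generations = 200, mutation = 0.05, elitism = 10),
    ga)
  I <- data$I
  sigma_assumed <- is.null(data$sigma)
  sig <- data$sigma %||% (0.01 * (abs(I) + 0.01 * max(abs(I))))
  stopifnot(ncol(curves) == length(I))
  set.seed(rng_seed)
  npool <- nrow(curves)
  npop <- ga$population
  pop <- matrix(sample.int(npool, npop * ensemble_size, replace = TRUE),
                nrow = npop)
  fitness <- function(idx) ensemble_chi2(colMeans(curves[idx, , drop = FALSE]),
                                         I, sig)
  fit <- apply(pop, 1, fitness)
  best0 <- min(fit)
  for (gen in seq_len(ga$generations)) {
    o <- order(fit)
    elite <- pop[o[seq_len(ga$elitism)], , drop = FALSE]
    # tournament-free rank selection of parents
    probs <- (npop - rank(fit, ties.method = "first") + 1)
    probs <- probs / sum(probs)
    n_children <- npop - ga$elitism
    parents <- matrix(sample.int(npop, 2 * n_children, replace = TRUE,
                                 prob = probs), ncol = 2)
    children <- matrix(0L, n_children, ensemble_size)
    for (k in seq_len(n_children)) {
      cut <- sample.int(ensemble_size, 1)
      child <- c(pop[parents[k, 1], seq_len(cut)],
                 pop[parents[k, 2], -seq_len(cut)])[seq_len(ensemble_size)]
      mut <- stats::runif(ensemble_size) < ga$mutation
      child[mut] <- sample.int(npool, sum(mut), replace = TRUE)
      children[k, ] <- child
    }
    pop <- rbind(elite, children)
    fit <- apply(pop, 1, fitness)
  }
  bi <- which.min(fit)
  idx <- sort(pop[bi, ])
  avg <- colMeans(curves[idx, , drop = FALSE])
  c0 <- sum(I * avg / sig^2) / sum(avg^2 / sig^2)
  structure(list(
    indices = idx, chi2 = fit[bi],
    avg_curve = scattering_curve(data$s, c0 * avg), scale = c0,
    rg_pool = pool_rg, rg_selected = if (!is.null(pool_rg)) pool_rg[idx],
    improved = fit[bi] < best0, sigma_assumed = sigma_assumed,
    ga = ga, seed = rng_seed
  ), class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("Ensemble fit: %d members, chi2 = %.4g%s\n",
              length(x$indices), x$chi2,
              if (!is.null(x$rg_selected))
                sprintf(", Rg selected %.2f vs pool %.2f nm",
                        mean(x$rg_selected), mean(x$rg_pool)) else ""))
  if (!x$improved) cat("note: GA did not improve on the initial population\n")
  invisible(x)
}
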