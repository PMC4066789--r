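#' Validated rate parameters for the collisional model
#'
#' The model evolves the copy number of one gene family across `N` species
#' genomes through pairwise "collisions". In a collision each partner gains
#' copies from the other by Bernoulli trials of probability `p_h` per donor
#' gene (horizontal transfer), and each of its own copies is independently
#' lost with probability `p_l` or duplicated with probability `p_d`
#' (mutually exclusive outcomes, so `p_d + p_l <= 1`). Stationarity of the
#' total abundance requires the balance condition `p_h + p_d = p_l`; when
#' `p_l` is omitted it is filled in as `p_h + p_d`.
#'
#' @param p_h probability per donor gene of horizontal gain during a collision.
#' @param p_d probability per own gene of duplication.
#' @param p_l probability per own gene of loss; defaults to `p_h + p_d`.
#' @param N number of species genomes (>= 2).
#' @return An object of class `collision_params`.
#' @examples
#' collision_params(p_h = 0.01, p_d = 0, N = 1000)        # transfer/loss only
#' collision_params(p_h = 0.001, p_d = 0.009, N = 1000)   # duplication-dominated
#' @export
collision_params <- function(p_h, p_d, p_l = NULL, N) {
  stopifnot(is.numeric(p_h), is.numeric(p_d), length(p_h) == 1L, length(p_d) == 1L)
  if (is.null(p_l)) p_l <- p_h + p_d
  stopifnot(is.numeric(p_l), length(p_l) == 1L)
  if (anyNA(c(p_h, p_d, p_l))) stop("rates must not be NA")
  if (p_h < 0 || p_h > 1 || p_d < 0 || p_d > 1 || p_l < 0)
    stop("rates must lie in [0, 1]")
  if (abs(p_h + p_d - p_l) > 1e-12)
    stop("non-stationary parameterization: p_h + p_d = p_l is required ",
         "(got p_h + p_d = ", p_h + p_d, ", p_l = ", p_l, ")")
  # p_d + p_l <= 1 also bounds p_l itself
  if (p_d + p_l > 1)
    stop("p_d + p_l = ", p_d + p_l, " > 1: loss and duplication are exclusive ",
         "per-gene outcomes")
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  structure(list(p_h = p_h, p_d = p_d, p_l = p_l, N = N),
            class = "collision_params")
}

#' @export
print.collision_params <- function(x, ...) {
  cat("Collisional model parameters\n")
  cat(sprintf("  N   = %d species\n", x$N))
  cat(sprintf("  p_h = %g (horizontal gain)\n", x$p_h))
  cat(sprintf("  p_d = %g (duplication)\n", x$p_d))
  cat(sprintf("  p_l = %g (loss; balances p_h + p_d)\n", x$p_l))
  invisible(x)
}

#' Initial abundance state
#'
#' @param N number of species.
#' @param init non-negative integer scalar (broadcast) or length-`N` vector of
#'   initial copy numbers.
#' @return An `abundance_state`: list with integer vector `V` and time `t = 0`
#'   (in sweeps; one sweep is `N` collisions).
#' @examples
#' init_abundance(5, 30)
#' init_abundance(5, c(0, 1, 2, 3, 4))
#' @export
init_abundance <- function(N, init) {
  N <- as.integer(N)
  stopifnot(N >= 1L, is.numeric(init))
  if (anyNA(init) || any(init < 0)) stop("initial abundances must be >= 0")
  if (any(init != floor(init))) stop("initial abundances must be integers")
  if (length(init) == 1L) init <- rep(init, N)
  if (length(init) != N) stop("init must have length 1 or N = ", N)
  structure(list(V = as.integer(init), t = 0), class = "abundance_state")
}

#' @export
print.abundance_state <- function(x, ...) {
  cat(sprintf("Abundance state: %d species at t = %g sweeps; mean V = %.3f\n",
              length(x$V), x$t, mean(x$V)))
  invisible(x)
}

#' Perform one collision between two species
#'
#' Applies one exchange event to species `i` and `j`: simultaneous Bernoulli
#' gains from the partner's pre-collision genome (probability `p_h` per gene)
#' and multinomial loss/duplication of own genes (probabilities `p_l`, `p_d`).
#' Uses R's random number stream.
#'
#' @param state an `abundance_state`.
#' @param i,j distinct species indices (1-based).
#' @param params a [collision_params()] object.
#' @return The updated `abundance_state` (time unchanged; a single collision is
#'   1/N of a sweep and is tracked by [simulate_family()]).
#' @export
collide_pair <- function(state, i, j, params) {
  stopifnot(inherits(state, "abundance_state"), inherits(params, "collision_params"))
  i <- as.integer(i); j <- as.integer(j)
  N <- length(state$V)
  if (i < 1L || i > N || j < 1L || j > N) stop("species index out of range")
  if (i == j) stop("a species cannot collide with itself (i == j)")
  state$V <- cpp_collide_pair(state$V, i, j, params$p_h, params$p_d, params$p_l)
  state
}

#' Phylogeny-biased collision kernel from a distance matrix
#'
#' Builds the symmetric pair-weight matrix `W_ij = exp(-d_ij / d0)` used to
#' bias collision partner choice towards phylogenetically close genomes.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param d0 positive decay scale, in the units of `D`.
#' @return A weight matrix with zero diagonal, suitable for the `kernel`
#'   argument of [simulate_family()].
#' @export
distance_kernel <- function(D, d0) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D), d0 > 0)
  if (any(D < 0) || anyNA(D)) stop("distances must be non-negative and non-missing")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  W <- exp(-D / d0)
  diag(W) <- 0
  W
}

check_kernel <- function(W, N) {
  W <- as.matrix(W)
  if (nrow(W) != N || ncol(W) != N)
    stop("kernel dimension ", nrow(W), " does not match N = ", N)
  if (max(abs(W - t(W))) > 1e-8) stop("kernel must be symmetric")
  if (any(W < 0) || anyNA(W)) stop("kernel weights must be non-negative")
  diag(W) <- 0
  if (all(W == 0)) stop("kernel needs at least one positive off-diagonal weight")
  W
}

#' Simulate the collisional dynamics of one gene family
#'
#' Runs `n_sweeps * N` collisions (one sweep = `N` collisions, the natural
#' time unit of the model's relaxation). Without a kernel each collision picks
#' an unordered pair of species uniformly at random; with a kernel, pair
#' `(i, j)` is chosen with probability proportional to `W[i, j]`. Ensemble
#' moments of the abundance are recorded every `record_interval` sweeps.
#'
#' @param params a [collision_params()] object.
#' @param init initial abundance: scalar, length-`N` vector, or an
#'   `abundance_state`.
#' @param n_sweeps number of sweeps to run (>= 1).
#' @param record_interval record moments every this many sweeps.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   trajectories.
#' @param kernel optional `N x N` symmetric pair-weight matrix (for instance
#'   from [distance_kernel()]).
#' @return A `family_trajectory`: list with `times` (sweeps), `mean`,
#'   `variance` (sample variance), `skewness`, `final_state`, and `params`.
#' @examples
#' p <- collision_params(p_h = 0.05, p_d = 0, N = 200)
#' tr <- simulate_family(p, init = 10, n_sweeps = 50, seed = 1)
#' tail(tr$mean, 1)  # conserved near 10
#' @export
simulate_family <- function(params, init = 30, n_sweeps, record_interval = 1L,
                            seed = NULL, kernel = NULL) {
  stopifnot(inherits(params, "collision_params"))
  n_sweeps <- as.integer(n_sweeps)
  record_interval <- as.integer(record_interval)
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1")
  if (record_interval < 1L) stop("record_interval must be >= 1")
  state <- if (inherits(init, "abundance_state")) init
           else init_abundance(params$N, init)
  if (length(state$V) != params$N) stop("state length does not match params$N")
  if (!is.null(kernel)) kernel <- check_kernel(kernel, params$N)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_simulation(state$V, params$p_h, params$p_d, params$p_l,
                            n_sweeps, record_interval, kernel)
  structure(list(times = res$times, mean = res$means, variance = res$variances,
                 skewness = res$skewnesses,
                 final_state = structure(list(V = res$final_V, t = n_sweeps),
                                         class = "abundance_state"),
                 params = params),
            class = "family_trajectory")
}

#' Convenience `simulate` method for collisional model parameters
#'
#' Thin wrapper around [simulate_family()] so that model parameters can be
#' used with the standard `simulate()` generic; returns a list of `nsim`
#' trajectories.
#'
#' @param object a [collision_params()] object.
#' @param nsim number of replicate trajectories.
#' @param seed optional integer seed applied once before the replicates.
#' @param ... passed on to [simulate_family()] (e.g. `init`, `n_sweeps`).
#' @importFrom stats simulate
#' @export
simulate.collision_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(k) simulate_family(object, seed = NULL, ...))
}

#' @export
print.family_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Collisional trajectory: N = %d, %g sweeps, %d records\n",
              x$params$N, x$times[n], n))
  cat(sprintf("  final mean = %.3f, variance = %.3f, Fano = %.3f\n",
              x$mean[n], x$variance[n], x$variance[n] / x$mean[n]))
  invisible(x)
}

#' @export
plot.family_trajectory <- function(x, which = c("variance", "mean", "skewness"),
                                   ...) {
  which <- match.arg(which)
  graphics::plot(x$times, x[[which]], type = "l", xlab = "time (sweeps)",
                 ylab = which, ...)
  invisible(x)
}

#' Empirical abundance histogram of a state
#'
#' @param state an `abundance_state` or a non-negative integer vector.
#' @return A data frame with columns `v` (0 up to the observed maximum) and
#'   `probability` (summing to 1).
#' @examples
#' abundance_histogram(c(0, 1, 1, 2))
#' @export
abundance_histogram <- function(state) {
  V <- if (inherits(state, "abundance_state")) state$V else state
  stopifnot(is.numeric(V), length(V) > 0)
  if (anyNA(V) || any(V < 0) || any(V != floor(V)))
    stop("abundances must be non-negative integers")
  counts <- tabulate(V + 1L, nbins = max(V) + 1L)
  data.frame(v = seq_along(counts) - 1L, probability = counts / length(V))
}

#' Pooled stationary ensemble of the collisional model
#'
#' Runs `n_reps` replicate simulations and pools the abundance vectors of
#' snapshots taken every `snapshot_every` sweeps from `burn_in` to
#' `n_sweeps`. Ergodic averaging over post-burn-in snapshots and replicates
#' gives stable estimates of the stationary mean, Fano factor and abundance
#' histogram; snapshots about one relaxation time apart are close to
#' independent.
#'
#' @inheritParams simulate_family
#' @param burn_in sweeps discarded before the first snapshot (a common
#'   choice is 5-10 relaxation times, see [relaxation_time_sweeps()]).
#' @param snapshot_every sweeps between pooled snapshots.
#' @param n_reps number of replicate runs.
#' @return List with the pooled `values`, their `mean`, `fano`
#'   (variance/mean) and the per-snapshot ensemble means `snapshot_means`.
#' @export
stationary_ensemble <- function(params, init = 30, n_sweeps, burn_in,
                                snapshot_every, n_reps = 1, seed = NULL,
                                kernel = NULL) {
  stopifnot(burn_in >= 1, burn_in <= n_sweeps, snapshot_every >= 1,
            n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  vals <- list(); means <- numeric(0)
  for (r in seq_len(n_reps)) {
    tr <- simulate_family(params, init = init, n_sweeps = burn_in,
                          record_interval = burn_in, kernel = kernel)
    state <- tr$final_state
    t <- burn_in
    vals[[length(vals) + 1L]] <- state$V
    means <- c(means, mean(state$V))
    while (t < n_sweeps) {
      step <- min(snapshot_every, n_sweeps - t)
      tr <- simulate_family(params, init = state, n_sweeps = step,
                            record_interval = step, kernel = kernel)
      state <- tr$final_state
      t <- t + step
      vals[[length(vals) + 1L]] <- state$V
      means <- c(means, mean(state$V))
    }
  }
  values <- unlist(vals)
  list(values = values, mean = mean(values),
       fano = stats::var(values) / mean(values), snapshot_means = means)
}

#' Half L1 distance between an empirical sample and an analytic profile
#'
#' `0.5 * sum_v |p_hat(v) - pmf(v)|` over `v = 0..v_max` of the profile;
#' sample values beyond the truncation fall outside the sum.
#'
#' @param values non-negative integer sample (e.g. pooled abundances).
#' @param profile an `analytic_profile` from [poisson_profile()] or
#'   [grazing_limit_profile()].
#' @return The half L1 distance, in [0, 1].
#' @export
l1_to_profile <- function(values, profile) {
  stopifnot(inherits(profile, "analytic_profile"))
  v_max <- profile$v_max
  p <- tabulate(pmin(values, v_max + 1L) + 1L, nbins = v_max + 1L) /
    length(values)
  0.5 * sum(abs(p - profile$pmf))
}
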