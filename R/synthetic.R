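# Synthetic family-by-genome ensembles with planted abundance classes.
#
# The generator emulates the statistical structure the analysis assumes:
# Poisson, overdispersed (negative-binomial) and peaked (constant +/- 1
# noise) family profiles, multiplicative genome-size heterogeneity, genome
# clades with clade-structured presence of peaked families (the planted
# phylogenetic signal), class-correlated transfer counts, and
# class-correlated functional categories.

#' Specification of a synthetic ensemble
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 500 genomes in 4 clades, 100 families per class, mean copy numbers
#' uniform in [5, 50], variance/mean 10 for overdispersed families, peaked
#' copy number k in {3..8} with symmetric +/-1 noise at rate 0.1, log-uniform
#' genome-size factors in [0.7, 1.4], full occurrence, and a 10% dropout of
#' each peaked family inside one designated clade (the planted clade signal).
#'
#' @param n_genomes number of genomes.
#' @param n_poisson,n_overdispersed,n_peaked families per planted class.
#' @param lambda_range range of mean copy numbers for Poisson/overdispersed
#'   families.
#' @param dispersion variance/mean ratio of overdispersed families
#'   (equivalently `1 + p_d/p_h` of the collisional model; > 1).
#' @param k_range integer range of peaked copy numbers.
#' @param epsilon rate of the symmetric +/-1 noise on peaked families: each
#'   direction occurs with probability `epsilon` (noise variance
#'   `2 * epsilon`; in [0, 0.5]).
#' @param occurrence per-family fraction of genomes carrying the family
#'   (class-independent random dropout; in (0, 1]).
#' @param size_range genome-size factors are log-uniform over this range.
#' @param n_clades number of genome clades.
#' @param clade_dropout probability that a genome of a peaked family's
#'   designated clade lacks the family.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_genomes = 500, n_poisson = 100,
                          n_overdispersed = 100, n_peaked = 100,
                          lambda_range = c(5, 50), dispersion = 10,
                          k_range = c(3L, 8L), epsilon = 0.1,
                          occurrence = 1, size_range = c(0.7, 1.4),
                          n_clades = 4, clade_dropout = 0.1) {
  stopifnot(n_genomes >= 2, dispersion > 1, epsilon >= 0, epsilon <= 0.5,
            occurrence > 0, occurrence <= 1, lambda_range[1] > 0,
            k_range[1] >= 1, size_range[1] > 0, n_clades >= 1,
            clade_dropout >= 0, clade_dropout <= 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 n_poisson = as.integer(n_poisson),
                 n_overdispersed = as.integer(n_overdispersed),
                 n_peaked = as.integer(n_peaked),
                 lambda_range = lambda_range, dispersion = dispersion,
                 k_range = as.integer(k_range), epsilon = epsilon,
                 occurrence = occurrence, size_range = size_range,
                 n_clades = as.integer(n_clades),
                 clade_dropout = clade_dropout),
            class = "ensemble_spec")
}

#' Generate a synthetic family-by-genome ensemble
#'
#' Per family f and genome g with size factor `s_g`: Poisson families draw
#' `Poisson(lambda_f * s_g)`; overdispersed families draw a negative binomial
#' with mean `lambda_f * s_g` and the spec'd variance/mean; peaked families
#' take `round(k_f * s_g)` shifted by -1 or +1, each with probability
#' `epsilon` (clamped at 0). A random `1 - occurrence` fraction of
#' genomes is then zeroed per family, and each peaked family is additionally
#' dropped with probability `clade_dropout` from genomes of its designated
#' clade, planting a clade-correlated presence pattern that only the peaked
#' class carries.
#'
#' @param spec an [ensemble_spec()].
#' @param seed integer seed; identical spec and seed give bit-identical
#'   output.
#' @return List with `counts` (families x genomes integer matrix) and `truth`
#'   (list of `families` and `genomes` data frames with the planted
#'   parameters).
#' @examples
#' sim <- generate_ensemble(ensemble_spec(n_genomes = 50, n_poisson = 5,
#'                                        n_overdispersed = 5, n_peaked = 5),
#'                          seed = 1)
#' dim(sim$counts)
#' @export
generate_ensemble <- function(spec = ensemble_spec(), seed = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (!is.null(seed)) set.seed(seed)
  G <- spec$n_genomes
  s_g <- exp(runif(G, log(spec$size_range[1]), log(spec$size_range[2])))
  clade <- rep_len(seq_len(spec$n_clades), G)

  classes <- rep(c("poisson", "overdispersed", "peaked"),
                 c(spec$n_poisson, spec$n_overdispersed, spec$n_peaked))
  F <- length(classes)
  lambda <- runif(F, spec$lambda_range[1], spec$lambda_range[2])
  k <- spec$k_range[1] +
    sample.int(spec$k_range[2] - spec$k_range[1] + 1L, F, replace = TRUE) - 1L
  is_peak <- classes == "peaked"
  lambda[is_peak] <- NA_real_
  k[!is_peak] <- NA_integer_
  fam_clade <- ifelse(is_peak,
                      sample.int(spec$n_clades, F, replace = TRUE),
                      NA_integer_)
  if (any(is_peak) && any(round(k[is_peak] * min(s_g)) < 1))
    stop("infeasible spec: round(k * s_g) < 1 for some peaked family")

  counts <- matrix(0L, F, G,
                   dimnames = list(sprintf("F%04d", seq_len(F)),
                                   sprintf("G%04d", seq_len(G))))
  for (f in seq_len(F)) {
    counts[f, ] <- switch(classes[f],
      poisson = rpois(G, lambda[f] * s_g),
      overdispersed = {
        mu <- lambda[f] * s_g
        rnbinom(G, mu = mu, size = mu / (spec$dispersion - 1))
      },
      peaked = {
        base <- as.integer(round(k[f] * s_g))
        # -1 and +1 each with probability epsilon (noise variance 2 * epsilon)
        u <- runif(G)
        shift <- integer(G)
        shift[u < spec$epsilon] <- -1L
        shift[u >= spec$epsilon & u < 2 * spec$epsilon] <- 1L
        pmax(base + shift, 0L)
      })
    if (spec$occurrence < 1) {
      absent <- runif(G) > spec$occurrence
      counts[f, absent] <- 0L
    }
    if (is_peak[f] && spec$clade_dropout > 0) {
      in_clade <- clade == fam_clade[f]
      drop <- in_clade & runif(G) < spec$clade_dropout
      counts[f, drop] <- 0L
    }
  }
  storage.mode(counts) <- "integer"
  truth <- list(
    families = data.frame(family_id = rownames(counts), class = classes,
                          lambda = lambda, dispersion = ifelse(
                            classes == "overdispersed", spec$dispersion, NA),
                          k = k, epsilon = ifelse(is_peak, spec$epsilon, NA),
                          clade = fam_clade, stringsAsFactors = FALSE),
    genomes = data.frame(genome_id = colnames(counts), size_factor = s_g,
                         clade = clade, stringsAsFactors = FALSE),
    spec = spec)
  list(counts = counts, truth = truth)
}

#' Generate class-correlated transfer counts
#'
#' Scored transfers per family/genome are `Binomial(V_{f,g}, h_class)`: by
#' default transfer-dominated Poisson families carry the highest per-copy
#' transfer rate (0.4), overdispersed families an intermediate one (0.3), and
#' peaked families almost none (0.02).
#'
#' @param counts abundance matrix from [generate_ensemble()].
#' @param truth matching ground truth.
#' @param h_by_class named per-copy transfer rates in [0, 1].
#' @param seed optional integer seed.
#' @return Integer transfer matrix aligned to `counts`.
#' @export
generate_transfer_table <- function(counts, truth,
                                    h_by_class = c(poisson = 0.4,
                                                   overdispersed = 0.3,
                                                   peaked = 0.02),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(h_by_class >= 0), all(h_by_class <= 1))
  cls <- truth$families$class
  if (!all(cls %in% names(h_by_class)))
    stop("h_by_class must name every planted class")
  H <- counts
  H[] <- rbinom(length(counts), size = as.vector(counts),
                prob = h_by_class[cls][row(counts)])
  storage.mode(H) <- "integer"
  H
}

#' Generate class-correlated functional-category annotations
#'
#' Each family draws one category with probability proportional to a uniform
#' base weight times the relative risk for its planted class. The default
#' plants a 3x enrichment of "metabolism" in the Poisson class; passing an
#' empty `assoc` list gives the null (no association).
#'
#' @param truth ground truth from [generate_ensemble()].
#' @param categories category names.
#' @param assoc named list: `assoc$category` is a named vector of relative
#'   risks per class (classes not named have risk 1).
#' @param seed optional integer seed.
#' @return Data frame with `family_id` and `category`.
#' @export
generate_category_annotations <- function(truth,
                                          categories = c("metabolism",
                                                         "information",
                                                         "regulation",
                                                         "intracellular",
                                                         "extracellular",
                                                         "general", "other"),
                                          assoc = list(
                                            metabolism = c(poisson = 3)),
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(categories) < 1) stop("need at least one category")
  fam <- truth$families
  cat_out <- character(nrow(fam))
  for (f in seq_len(nrow(fam))) {
    w <- rep(1, length(categories))
    names(w) <- categories
    for (ct in names(assoc)) {
      rr <- assoc[[ct]][fam$class[f]]
      if (!is.na(rr)) {
        if (rr < 0) stop("relative risks must be >= 0")
        w[ct] <- w[ct] * rr
      }
    }
    if (sum(w) == 0) stop("degenerate category weights for family ",
                          fam$family_id[f])
    cat_out[f] <- sample(categories, 1, prob = w)
  }
  data.frame(family_id = fam$family_id, category = cat_out,
             stringsAsFactors = FALSE)
}

#' Generate a clade-block reference distance matrix
#'
#' An ultrametric-style stand-in for a 16S rRNA phylogenetic distance:
#' constant small distance within planted clades and a larger constant
#' between clades.
#'
#' @param truth ground truth from [generate_ensemble()].
#' @param d_within,d_between within- and between-clade distances.
#' @return Symmetric genome-by-genome matrix with zero diagonal.
#' @export
generate_reference_distances <- function(truth, d_within = 0.1,
                                         d_between = 1) {
  clade <- truth$genomes$clade
  D <- ifelse(outer(clade, clade, `==`), d_within, d_between)
  diag(D) <- 0
  dimnames(D) <- list(truth$genomes$genome_id, truth$genomes$genome_id)
  D
}
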