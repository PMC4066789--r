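#' Classify families by their abundance-fluctuation index
#'
#' Families with sampling weight below `w_min` are too poorly sampled to
#' classify ("undersampled"); the rest are split on `Q_f`: overdispersed
#' (`Q_f < q_low`), peaked (`Q_f > q_high`), Poisson-like otherwise.
#' Boundary equality goes to Poisson-like (the thresholds are strict
#' inequalities). Families with missing `Q_f` are undersampled, with a
#' warning.
#'
#' @param stats a [family_stats()] object or a data frame with columns
#'   `family_id`, `Q`, `w`.
#' @param q_low,q_high `Q_f` thresholds (defaults -0.43 and 1).
#' @param w_min sampling-noise threshold on `w_f` (default 0.38); families at
#'   or above it are retained.
#' @return Data frame with `family_id` and factor `class` with levels
#'   overdispersed, poisson_like, peaked, undersampled.
#' @examples
#' df <- data.frame(family_id = c("a", "b", "c"), Q = c(-1, 0, 2),
#'                  w = c(0.9, 0.9, 0.1))
#' classify_families(df)
#' @export
classify_families <- function(stats, q_low = -0.43, q_high = 1, w_min = 0.38) {
  if (inherits(stats, "family_stats")) stats <- stats$stats
  stopifnot(is.data.frame(stats), all(c("family_id", "Q", "w") %in% names(stats)),
            q_low < q_high)
  Q <- stats$Q; w <- stats$w
  if (anyNA(Q[w >= w_min]))
    warning("families with missing Q_f assigned to the undersampled class")
  cls <- rep("poisson_like", nrow(stats))
  cls[Q < q_low] <- "overdispersed"
  cls[Q > q_high] <- "peaked"
  cls[is.na(Q) | is.na(w) | w < w_min] <- "undersampled"
  data.frame(family_id = stats$family_id,
             class = factor(cls, levels = c("overdispersed", "poisson_like",
                                            "peaked", "undersampled")),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' The two-sided p-value sums the probabilities of all tables with the
#' observed margins that are no more probable than the observed one, under
#' the hypergeometric null; probabilities are evaluated with `lchoose`. The
#' odds ratio is the sample estimate `a*d / (b*c)` (0 or Inf at zero cells,
#' NaN when both products vanish).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`a` = category & class, `b` = category & not class, etc.); alternatively
#'   `a` may be a 2x2 matrix.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # p = 1
#' fisher_exact_2x2(10, 0, 0, 10) # p ~ 1.08e-5
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  or <- (a * d) / (b * c)  # 0, Inf or NaN at degenerate cells
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n)
    return(list(odds_ratio = or, p_value = 1))
  x <- max(0, k - n):min(k, m)
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  lp_obs <- lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k)
  # relative tolerance guards floating-point ties among equal-probability tables
  p <- sum(exp(lp)[lp <= lp_obs + log(1 + 1e-7)])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Functional-category enrichment of abundance classes
#'
#' Runs one two-sided Fisher exact test per (category, class) pair on the
#' contingency of category membership versus class membership, among the
#' classified (non-undersampled) families by default. Raw p-values are
#' reported (significance at `alpha` without correction), with a
#' Benjamini-Hochberg adjusted column alongside.
#'
#' @param labels data frame from [classify_families()].
#' @param categories data frame with columns `family_id` and `category`.
#' @param alpha significance level on the raw p-value (default 0.01).
#' @param include_undersampled also test undersampled families as a class
#'   (default FALSE drops them).
#' @return Data frame with one row per (category, class): cell counts `a`-`d`,
#'   `odds_ratio`, `p_value`, `p_adjust` (BH), `direction` (over/under/none)
#'   and `significant`.
#' @export
category_enrichment <- function(labels, categories, alpha = 0.01,
                                include_undersampled = FALSE) {
  stopifnot(is.data.frame(labels), is.data.frame(categories),
            all(c("family_id", "category") %in% names(categories)))
  df <- merge(labels, categories, by = "family_id")
  if (!include_undersampled) df <- df[df$class != "undersampled", ]
  df$class <- droplevels(df$class)
  if (nrow(df) == 0) stop("no classified, annotated families to test")
  cats <- sort(unique(df$category))
  classes <- levels(df$class)
  out <- list()
  for (cat_i in cats) {
    in_cat <- df$category == cat_i
    if (!any(in_cat)) {
      warning("category ", cat_i, " has no families; skipped")
      next
    }
    for (cls in classes) {
      in_cls <- df$class == cls
      a <- sum(in_cat & in_cls); b <- sum(in_cat & !in_cls)
      cc <- sum(!in_cat & in_cls); d <- sum(!in_cat & !in_cls)
      ft <- fisher_exact_2x2(a, b, cc, d)
      direction <- if (is.nan(ft$odds_ratio) || ft$odds_ratio == 1) "none"
                   else if (ft$odds_ratio > 1) "over" else "under"
      out[[length(out) + 1L]] <-
        data.frame(category = cat_i, class = cls, a = a, b = b, c = cc, d = d,
                   odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                   direction = direction, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_adjust <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < alpha
  res
}

#' Plasmid enrichment log-ratio score
#'
#' Compares a family's share of all plasmid-borne domains with its share of
#' the genomic background:
#' `score_f = log((plasmid_f + pc) / sum(plasmid + pc)) -
#'            log((background_f + pc) / sum(background + pc))`.
#' Positive scores mark families enriched on mobile elements.
#'
#' @param plasmid_counts,background_counts aligned non-negative per-family
#'   domain counts.
#' @param pseudocount added to every count before forming percentages
#'   (default 0.5; guards log(0)).
#' @return Named vector of log-ratio scores.
#' @export
plasmid_enrichment_score <- function(plasmid_counts, background_counts,
                                     pseudocount = 0.5) {
  stopifnot(length(plasmid_counts) == length(background_counts),
            pseudocount >= 0)
  if (any(plasmid_counts < 0) || any(background_counts < 0))
    stop("counts must be non-negative")
  if (sum(plasmid_counts) + pseudocount * length(plasmid_counts) == 0 ||
      sum(background_counts) + pseudocount * length(background_counts) == 0)
    stop("all-zero counts with zero pseudocount")
  p <- (plasmid_counts + pseudocount) /
    sum(plasmid_counts + pseudocount)
  q <- (background_counts + pseudocount) /
    sum(background_counts + pseudocount)
  score <- log(p) - log(q)
  names(score) <- names(plasmid_counts)
  score
}

#' Genome-genome distance restricted to one abundance class
#'
#' Computes pairwise genome distances from family usage restricted to the
#' families carrying a given class label: Jaccard distance on
#' presence/absence (default) or Bray-Curtis on counts, via
#' \code{vegan::vegdist}. Restricting to peaked families tracks vertical
#' descent, while transfer-dominated (Poisson-like, overdispersed) families
#' scramble the phylogenetic signal.
#'
#' @param counts family-by-genome matrix.
#' @param labels data frame from [classify_families()].
#' @param cls class label to restrict to.
#' @param metric `"jaccard"` (presence/absence) or `"braycurtis"` (counts).
#' @return Symmetric genome-by-genome distance matrix.
#' @export
class_restricted_distance <- function(counts, labels,
                                      cls = c("peaked", "poisson_like",
                                              "overdispersed"),
                                      metric = c("jaccard", "braycurtis")) {
  counts <- as_abundance_matrix(counts)
  cls <- match.arg(cls)
  metric <- match.arg(metric)
  keep <- labels$family_id[labels$class == cls]
  if (length(keep) < 2)
    stop("need at least 2 families labeled ", cls)
  sub <- counts[rownames(counts) %in% keep, , drop = FALSE]
  X <- t(sub)  # vegan wants samples (genomes) in rows
  d <- if (metric == "jaccard")
    suppressWarnings(vegan::vegdist(X, method = "jaccard", binary = TRUE))
  else
    suppressWarnings(vegan::vegdist(X, method = "bray"))
  D <- as.matrix(d)
  # genomes with an empty restricted profile: maximally distant from any
  # non-empty genome, at distance 0 from one another
  empty <- colSums(sub) == 0
  if (any(empty)) {
    D[empty, ] <- 1
    D[, empty] <- 1
    D[empty, empty] <- 0
  }
  diag(D) <- 0
  dimnames(D) <- list(colnames(counts), colnames(counts))
  D
}

#' Spearman correlation between two distance matrices
#'
#' Rank correlation over the strict upper triangles (average ranks on ties).
#' A constant matrix (e.g. a single-clade reference) has no ranking and
#' returns NA with a warning.
#'
#' @param D,D_ref symmetric matrices of identical dimension.
#' @return Spearman rho.
#' @export
spearman_distance_correlation <- function(D, D_ref) {
  D <- as.matrix(D); D_ref <- as.matrix(D_ref)
  if (!all(dim(D) == dim(D_ref)))
    stop("distance matrices must have identical dimensions")
  ut <- upper.tri(D)
  x <- D[ut]; y <- D_ref[ut]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant distance matrix: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
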