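# Cross-species abundance-fluctuation statistics.
#
# All statistics are computed inside sliding bins of genomes with similar
# size (total assigned domains), which removes the trivial scaling of family
# abundance with genome size before fluctuations are measured.

as_abundance_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("abundance matrix must be numeric")
  if (anyNA(counts)) stop("abundance matrix must not contain NA")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("abundances must be non-negative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("F%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%04d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("family ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("genome ids must be unique")
  storage.mode(counts) <- "integer"
  counts
}

#' Genome sizes in domains
#'
#' @param counts family-by-genome integer matrix (families in rows).
#' @return Named vector of per-genome sizes (column sums, in domains).
#' @export
genome_sizes <- function(counts) {
  counts <- as_abundance_matrix(counts)
  colSums(counts)
}

#' Sliding genome-size bins
#'
#' Genomes are grouped into half-open size intervals `[x, x + width)` whose
#' left edges advance by `step` from the smallest observed size; with
#' `step < width` the bins overlap and a genome belongs to several bins.
#' Bins with fewer than `min_bin` genomes are dropped.
#'
#' @param sizes per-genome sizes (domains), e.g. from [genome_sizes()].
#' @param width bin width in domains (default 390).
#' @param step bin step in domains (default 100; equal to `width` gives a
#'   disjoint partition).
#' @param min_bin minimum genomes per retained bin (default 10).
#' @return A `genome_bins` object: list of bins, each with `lower`, `upper`,
#'   `members` (genome indices) and `n`.
#' @export
build_bins <- function(sizes, width = 390, step = 100, min_bin = 10) {
  stopifnot(width > 0, step > 0, min_bin >= 1)
  if (length(sizes) == 0) stop("empty size vector")
  starts <- seq(min(sizes), max(sizes), by = step)
  bins <- lapply(starts, function(lo) {
    members <- which(sizes >= lo & sizes < lo + width)
    list(lower = lo, upper = lo + width, members = members,
         n = length(members))
  })
  # the half-open interval misses nothing because every start <= max(sizes),
  # but a genome at exactly max(sizes) needs the last bin to reach it
  keep <- vapply(bins, function(b) b$n >= min_bin, logical(1))
  if (!any(keep))
    stop("no bin reaches min_bin = ", min_bin, " genomes; widen the bins")
  structure(list(bins = bins[keep], width = width, step = step,
                 min_bin = min_bin, n_dropped = sum(!keep)),
            class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  n <- vapply(x$bins, `[[`, integer(1), "n")
  cat(sprintf("%d genome-size bins (width %g, step %g), %g-%g genomes each; %d dropped (< %d)\n",
              length(x$bins), x$width, x$step, min(n), max(n), x$n_dropped,
              x$min_bin))
  invisible(x)
}

# per-bin presence counts n_b^+ (families x bins) and occupancies n_b
bin_presence <- function(counts, bins) {
  nb <- vapply(bins$bins, `[[`, integer(1), "n")
  nplus <- vapply(bins$bins, function(b)
    as.integer(rowSums(counts[, b$members, drop = FALSE] > 0)),
    integer(nrow(counts)))
  if (is.null(dim(nplus))) nplus <- matrix(nplus, nrow = nrow(counts))
  list(nb = nb, nplus = nplus)
}

#' Per-family sampling weights
#'
#' The sampling weight of family `f` in bin `b` is
#' `w_{f,b} = n_b * n_b^+ / sum_b(n_b^2)`, where `n_b` is the bin occupancy
#' and `n_b^+` the number of genomes in the bin carrying the family; the
#' family weight is `w_f = sum_b w_{f,b}`, which lies in `[0, 1]` and reaches
#' 1 only for families present in every genome of every bin. Low `w_f` marks
#' poorly sampled abundance histograms.
#'
#' @param counts family-by-genome matrix.
#' @param bins a [build_bins()] object.
#' @return List with `w_fb` (families x bins matrix) and `w_f` (vector).
#' @export
sampling_weights <- function(counts, bins) {
  counts <- as_abundance_matrix(counts)
  stopifnot(inherits(bins, "genome_bins"))
  bp <- bin_presence(counts, bins)
  denom <- sum(bp$nb^2)
  w_fb <- sweep(bp$nplus, 2, bp$nb, `*`) / denom
  rownames(w_fb) <- rownames(counts)
  list(w_fb = w_fb, w_f = rowSums(w_fb))
}

# per-bin mean and variance of family abundance; values include v = 0 entries
# for genomes lacking the family when include_zeros, else only positive entries
bin_moments <- function(sub, include_zeros, var_type) {
  n <- ncol(sub)
  if (include_zeros) {
    m <- rowMeans(sub)
    m2 <- rowMeans(sub^2)
    used <- rep(n, nrow(sub))
  } else {
    np <- rowSums(sub > 0)
    m <- ifelse(np > 0, rowSums(sub) / np, NA_real_)
    m2 <- ifelse(np > 0, rowSums(sub^2) / np, NA_real_)
    used <- np
  }
  v <- pmax(m2 - m^2, 0)
  if (var_type == "sample") v <- ifelse(used > 1, v * used / (used - 1), 0)
  list(mean = m, var = v, used = used)
}

#' L1 distance of the abundance histogram from Poisson
#'
#' For each bin the empirical histogram of family abundance `p_{f,b}(v)` is
#' compared to the Poisson pmf with the same bin mean,
#' `L_{f,b} = 0.5 * sum_v |p_{f,b}(v) - Poiss(v)|`, summing over
#' `v = 0..v_max`. The aggregate is weighted by the bin presence counts:
#' `L_f = sum_b L_{f,b} n_b^+ / sum_b n_b^+`.
#'
#' @inheritParams sampling_weights
#' @param v_max truncation of the sums over `v` (default 450).
#' @param include_zeros include `v = 0` entries of genomes lacking the family
#'   (default TRUE); FALSE restricts histograms to genomes where the family is
#'   present.
#' @return List with `L_fb` (families x bins, NA where the family is absent
#'   from the bin) and `L_f`.
#' @export
l1_statistic <- function(counts, bins, v_max = 450, include_zeros = TRUE) {
  counts <- as_abundance_matrix(counts)
  stopifnot(inherits(bins, "genome_bins"), v_max >= 0)
  v_max <- as.integer(v_max)
  bp <- bin_presence(counts, bins)
  F <- nrow(counts); B <- length(bins$bins)
  L_fb <- matrix(NA_real_, F, B, dimnames = list(rownames(counts), NULL))
  for (b in seq_len(B)) {
    sub <- counts[, bins$bins[[b]]$members, drop = FALSE]
    for (f in seq_len(F)) {
      if (bp$nplus[f, b] == 0L) next
      vals <- sub[f, ]
      if (!include_zeros) vals <- vals[vals > 0]
      m <- mean(vals)
      # values beyond v_max fall outside the truncated sum over v
      p <- tabulate(pmin(vals, v_max + 1L) + 1L, nbins = v_max + 1L) /
        length(vals)
      L_fb[f, b] <- 0.5 * sum(abs(p - dpois(0:v_max, m)))
    }
  }
  wts <- bp$nplus
  tot <- rowSums(wts)
  L_f <- ifelse(tot > 0, rowSums(L_fb * wts, na.rm = TRUE) / tot, NA_real_)
  list(L_fb = L_fb, L_f = L_f)
}

#' Log inverse Fano factor statistic Q
#'
#' For each bin with positive abundance variance,
#' `Q_{f,b} = log(mean_b(v_f) / Var_b(v_f))`; a Poisson-compatible family has
#' `Q ~ 0`, overdispersed families `Q < 0`, and sub-Poissonian ("peaked")
#' families `Q > 0`. Bins where the family is present with exactly equal
#' abundance everywhere (zero variance) inherit the family's maximum
#' positive-variance `Q_{f,b}`, or the cap `q_cap` if no bin has positive
#' variance (flagged). The aggregate is the weighted sum
#' `Q_f = sum_b Q_{f,b} * w_{f,b}` with the sampling weights of
#' [sampling_weights()].
#'
#' @inheritParams l1_statistic
#' @param q_cap value assigned when every bin of a family has zero variance
#'   (default 5).
#' @param var_type `"population"` (divide by n, default) or `"sample"`.
#' @param normalize divide `Q_f` by `w_f` (default FALSE, i.e. the plain
#'   weighted sum).
#' @return List with `Q_fb`, `Q_f`, and logical `zero_var` flagging families
#'   that hit the cap.
#' @export
q_statistic <- function(counts, bins, include_zeros = TRUE, q_cap = 5,
                        var_type = c("population", "sample"),
                        normalize = FALSE) {
  counts <- as_abundance_matrix(counts)
  stopifnot(inherits(bins, "genome_bins"))
  var_type <- match.arg(var_type)
  bp <- bin_presence(counts, bins)
  F <- nrow(counts); B <- length(bins$bins)
  Q_fb <- matrix(NA_real_, F, B, dimnames = list(rownames(counts), NULL))
  zero_fb <- matrix(FALSE, F, B)
  for (b in seq_len(B)) {
    sub <- counts[, bins$bins[[b]]$members, drop = FALSE]
    mo <- bin_moments(sub, include_zeros, var_type)
    present <- bp$nplus[, b] > 0L
    pos <- present & !is.na(mo$var) & mo$var > 0
    Q_fb[pos, b] <- log(mo$mean[pos] / mo$var[pos])
    zero_fb[, b] <- present & !is.na(mo$var) & mo$var == 0
  }
  zero_var <- logical(F)
  for (f in which(rowSums(zero_fb) > 0)) {
    finite_q <- Q_fb[f, is.finite(Q_fb[f, ])]
    if (length(finite_q)) {
      Q_fb[f, zero_fb[f, ]] <- max(finite_q)
    } else {
      Q_fb[f, zero_fb[f, ]] <- q_cap
      zero_var[f] <- TRUE
    }
  }
  sw <- sampling_weights(counts, bins)
  contrib <- Q_fb * sw$w_fb
  Q_f <- rowSums(contrib, na.rm = TRUE)
  Q_f[rowSums(bp$nplus) == 0] <- NA_real_  # family absent everywhere
  if (normalize) Q_f <- Q_f / sw$w_f
  list(Q_fb = Q_fb, Q_f = Q_f, zero_var = zero_var)
}

#' Family occurrence across genomes
#'
#' @inheritParams sampling_weights
#' @return List with `O_f` (fraction of genomes with at least one member) and
#'   `O_count` (number of such genomes).
#' @export
occurrence <- function(counts) {
  counts <- as_abundance_matrix(counts)
  cnt <- rowSums(counts > 0)
  list(O_f = cnt / ncol(counts), O_count = as.integer(cnt))
}

#' Mean horizontal-transfer fraction H
#'
#' `H_f` averages `H_{f,g} / V_{f,g}` over the genomes where family `f` is
#' present, where `H_{f,g}` is the number of family members scored as
#' horizontal transfers and `V_{f,g}` the abundance. `H_f` approaches 1 when
#' most members are putative transfers and 0 when transfers are rare.
#' Ratios above 1 (possible with independent transfer annotations) are
#' clipped to 1 with a warning; families never present give NA.
#'
#' @inheritParams sampling_weights
#' @param transfers integer matrix of scored transfers, aligned to `counts`.
#' @return Named vector `H_f`.
#' @export
h_index <- function(counts, transfers) {
  counts <- as_abundance_matrix(counts)
  transfers <- as.matrix(transfers)
  if (!all(dim(transfers) == dim(counts)))
    stop("transfer table dimensions must match the abundance matrix")
  if (anyNA(transfers) || any(transfers < 0))
    stop("transfer counts must be non-negative")
  ratio <- ifelse(counts > 0, transfers / counts, NA_real_)
  n_clip <- sum(ratio > 1, na.rm = TRUE)
  if (n_clip > 0) {
    warning(n_clip, " transfer count(s) exceed the family abundance; ",
            "ratios clipped to 1")
    ratio <- pmin(ratio, 1)
  }
  H <- rowMeans(ratio, na.rm = TRUE)
  H[rowSums(counts > 0) == 0] <- NA_real_
  names(H) <- rownames(counts)
  H
}

#' Mean of y in equal-width bins of x
#'
#' @param x,y equal-length numeric vectors; pairs with missing values are
#'   dropped.
#' @param n_bins number of equal-width bins over the range of `x`.
#' @return Data frame with `lower`, `upper`, `mid`, `mean_y`, `n` per bin
#'   (`mean_y` NA for empty bins).
#' @export
binned_trend <- function(x, y, n_bins) {
  stopifnot(length(x) == length(y))
  if (n_bins < 1) stop("n_bins must be >= 1")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no finite (x, y) pairs")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mean_y <- n <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    n[b] <- sum(sel)
    if (n[b] > 0) mean_y[b] <- mean(y[sel])
  }
  data.frame(lower = breaks[-(n_bins + 1)], upper = breaks[-1],
             mid = (breaks[-(n_bins + 1)] + breaks[-1]) / 2,
             mean_y = mean_y, n = n)
}

#' Abundance-fluctuation statistics for every family
#'
#' The main data-analysis entry point: builds sliding genome-size bins and
#' computes, per family, the sampling weight `w_f`, the L1 distance to the
#' Poisson expectation `L_f`, the log inverse Fano factor `Q_f`, the
#' occurrence `O_f`, and (when a transfer table is supplied) the mean
#' transfer fraction `H_f`.
#'
#' @inheritParams l1_statistic
#' @param transfers optional transfer-count matrix aligned to `counts`.
#' @param bin_width,bin_step,min_bin passed to [build_bins()].
#' @param q_cap,var_type,normalize_q passed to [q_statistic()].
#' @return A `family_stats` object: list with `stats` (one row per family),
#'   `bins`, and the effective parameters. Methods: `print`, `summary`,
#'   `plot` (the L vs Q classification plane), `as.data.frame`.
#' @examples
#' sim <- generate_ensemble(ensemble_spec(n_genomes = 120, n_poisson = 10,
#'                                        n_overdispersed = 10, n_peaked = 10),
#'                          seed = 1)
#' fs <- family_stats(sim$counts)
#' head(as.data.frame(fs))
#' @export
family_stats <- function(counts, transfers = NULL, bin_width = 390,
                         bin_step = 100, v_max = 450, include_zeros = TRUE,
                         min_bin = 10, q_cap = 5,
                         var_type = c("population", "sample"),
                         normalize_q = FALSE) {
  counts <- as_abundance_matrix(counts)
  var_type <- match.arg(var_type)
  sizes <- genome_sizes(counts)
  bins <- build_bins(sizes, width = bin_width, step = bin_step,
                     min_bin = min_bin)
  sw <- sampling_weights(counts, bins)
  l1 <- l1_statistic(counts, bins, v_max = v_max,
                     include_zeros = include_zeros)
  qs <- q_statistic(counts, bins, include_zeros = include_zeros,
                    q_cap = q_cap, var_type = var_type,
                    normalize = normalize_q)
  occ <- occurrence(counts)
  H <- if (!is.null(transfers)) h_index(counts, transfers)
       else rep(NA_real_, nrow(counts))
  stats <- data.frame(family_id = rownames(counts), w = sw$w_f, L = l1$L_f,
                      Q = qs$Q_f, O = occ$O_f, O_count = occ$O_count, H = H,
                      zero_var = qs$zero_var, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(stats = stats, bins = bins,
                 params = list(bin_width = bin_width, bin_step = bin_step,
                               v_max = v_max, include_zeros = include_zeros,
                               min_bin = min_bin, q_cap = q_cap,
                               var_type = var_type,
                               normalize_q = normalize_q),
                 n_genomes = ncol(counts), n_families = nrow(counts)),
            class = "family_stats")
}

#' @export
as.data.frame.family_stats <- function(x, ...) x$stats

#' @export
print.family_stats <- function(x, ...) {
  cat(sprintf("Family abundance-fluctuation statistics: %d families x %d genomes\n",
              x$n_families, x$n_genomes))
  print(x$bins)
  cat("First families:\n")
  print(head(x$stats, 5), digits = 3)
  invisible(x)
}

#' @export
summary.family_stats <- function(object, q_low = -0.43, q_high = 1,
                                 w_min = 0.38, ...) {
  cls <- classify_families(object, q_low = q_low, q_high = q_high,
                           w_min = w_min)
  out <- list(n_families = object$n_families, n_genomes = object$n_genomes,
              class_counts = table(cls$class),
              w = quantile(object$stats$w, na.rm = TRUE),
              Q = quantile(object$stats$Q, na.rm = TRUE),
              L = quantile(object$stats$L, na.rm = TRUE))
  class(out) <- "summary.family_stats"
  out
}

#' @export
print.summary.family_stats <- function(x, ...) {
  cat(sprintf("%d families x %d genomes\n", x$n_families, x$n_genomes))
  cat("Class counts (default thresholds):\n")
  print(x$class_counts)
  cat("Quantiles of w_f:\n"); print(x$w, digits = 3)
  cat("Quantiles of Q_f:\n"); print(x$Q, digits = 3)
  cat("Quantiles of L_f:\n"); print(x$L, digits = 3)
  invisible(x)
}

#' @export
plot.family_stats <- function(x, ...) {
  s <- x$stats
  ok <- is.finite(s$Q) & is.finite(s$L)
  graphics::plot(s$Q[ok], s$L[ok], cex = 0.5 + 1.5 * s$w[ok],
                 xlab = expression(Q[f]), ylab = expression(L[f]),
                 main = "Abundance-fluctuation classification plane", ...)
  graphics::abline(v = c(-0.43, 1), lty = 2, col = "grey40")
  invisible(x)
}
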