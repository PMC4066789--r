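# Independent brute-force oracles, written as plain loops over raw counts so
# they share no code path with the package implementation.

# w_f, L_f, Q_f recomputed from first principles
naive_family_stats <- function(counts, width, step, min_bin, v_max = 450,
                               include_zeros = TRUE, q_cap = 5) {
  sizes <- colSums(counts)
  starts <- seq(min(sizes), max(sizes), by = step)
  members <- list()
  for (lo in starts) {
    mem <- which(sizes >= lo & sizes < lo + width)
    if (length(mem) >= min_bin) members[[length(members) + 1L]] <- mem
  }
  nb <- vapply(members, length, integer(1))
  S <- sum(nb^2)
  F <- nrow(counts)
  w <- L <- Q <- rep(NA_real_, F)
  for (f in seq_len(F)) {
    w_sum <- 0; L_num <- 0; L_den <- 0
    q_terms <- numeric(0); w_terms <- numeric(0); zero_bin <- logical(0)
    for (b in seq_along(members)) {
      vals <- counts[f, members[[b]]]
      npl <- sum(vals > 0)
      w_fb <- nb[b] * npl / S
      w_sum <- w_sum + w_fb
      if (npl == 0) next
      use <- if (include_zeros) vals else vals[vals > 0]
      m <- mean(use)
      p <- rep(0, v_max + 1)
      for (x in use) if (x <= v_max) p[x + 1] <- p[x + 1] + 1 / length(use)
      L_fb <- 0.5 * sum(abs(p - dpois(0:v_max, m)))
      L_num <- L_num + L_fb * npl
      L_den <- L_den + npl
      v <- mean((use - m)^2)
      if (v > 0) {
        q_terms <- c(q_terms, log(m / v)); zero_bin <- c(zero_bin, FALSE)
      } else {
        q_terms <- c(q_terms, NA_real_); zero_bin <- c(zero_bin, TRUE)
      }
      w_terms <- c(w_terms, w_fb)
    }
    w[f] <- w_sum
    if (L_den > 0) {
      L[f] <- L_num / L_den
      fallback <- if (any(!zero_bin)) max(q_terms[!zero_bin]) else q_cap
      q_terms[zero_bin] <- fallback
      Q[f] <- sum(q_terms * w_terms)
    }
  }
  list(w = w, L = L, Q = Q)
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration (dhyper)
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# maps planted generator classes to the classifier's label set
planted_label <- function(class) {
  c(poisson = "poisson_like", overdispersed = "overdispersed",
    peaked = "peaked")[class]
}
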