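test_that("genome sizes are column sums in domains", {
  m <- matrix(c(1, 0, 2, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("g1", "g2")))
  expect_equal(unname(genome_sizes(m)), c(3, 3))
  m2 <- cbind(m, g3 = c(0, 0))
  expect_equal(unname(genome_sizes(m2))[3], 0)
})

test_that("sliding bins cover the size range with the stated overlap", {
  # all genomes equal in size: exactly one retained bin holding everything
  b <- build_bins(rep(1500, 20), width = 390, step = 100, min_bin = 10)
  expect_length(b$bins, 1)
  expect_length(b$bins[[1]]$members, 20)

  # step = width gives a disjoint partition
  sizes <- c(100, 200, 500, 550, 900, 905)
  b <- build_bins(sizes, width = 390, step = 390, min_bin = 1)
  membership <- rowSums(vapply(b$bins, function(bb) seq_along(sizes) %in%
                                 bb$members, logical(length(sizes))))
  expect_true(all(membership == 1))

  # width 390, step 100: a genome of size s lies in every bin starting in
  # (s - 390, s], i.e. ceiling(390/100) = 4 overlapping bins (3 at phases
  # where a bin start falls just above s - 390); checked against direct
  # interval arithmetic
  sizes <- seq(1000, 3000, by = 10)
  b <- build_bins(sizes, width = 390, step = 100, min_bin = 1)
  membership <- rowSums(vapply(b$bins, function(bb) seq_along(sizes) %in%
                                 bb$members, logical(length(sizes))))
  starts <- seq(1000, 3000, by = 100)
  expected <- vapply(sizes, function(s) sum(starts > s - 390 & starts <= s),
                     numeric(1))
  expect_equal(membership, expected)
  interior <- sizes >= 1390
  expect_true(all(membership[interior] %in% c(3, 4)))
  expect_true(max(membership) == 4)

  expect_error(build_bins(numeric(0)), "empty")
  expect_error(build_bins(rep(1, 5), min_bin = 10), "min_bin")
})

test_that("sampling weights implement w_fb = n_b n_b^+ / sum(n_b^2)", {
  # one bin, full presence: w = 1; absent family: w = 0
  m <- rbind(full = rep(2L, 12), none = rep(0L, 12))
  colnames(m) <- paste0("g", 1:12)
  b <- build_bins(genome_sizes(m), width = 390, step = 100, min_bin = 10)
  sw <- sampling_weights(m, b)
  expect_equal(unname(sw$w_f), c(1, 0))

  # two disjoint bins (n=10, n+=5) and (n=20, n+=20): w = 450/500 = 0.9
  m <- matrix(0L, 2, 30)
  m[1, ] <- c(rep(100L, 10), rep(600L, 20))      # dummy filler family sets sizes
  m[2, c(1:5, 11:30)] <- 1L                      # family under test
  sizes <- genome_sizes(m)
  b <- build_bins(sizes, width = 390, step = 500, min_bin = 5)
  expect_length(b$bins, 2)
  sw <- sampling_weights(m, b)
  expect_equal(unname(sw$w_f[2]), 0.9)
})

test_that("the L1 statistic matches its closed-form point-mass value", {
  # every genome carries exactly 30 copies: L = 1 - Poiss(30; 30) ~ 0.9274
  m <- matrix(30L, 1, 50, dimnames = list("f", paste0("g", 1:50)))
  b <- build_bins(genome_sizes(m))
  l1 <- l1_statistic(m, b, v_max = 450)
  expect_equal(unname(l1$L_f), 1 - dpois(30, 30), tolerance = 1e-12)
  expect_true(all(l1$L_fb >= 0 & l1$L_fb <= 1, na.rm = TRUE))

  # an empirical sample far from the reference support approaches L = 1
  vals <- rep(400L, 100)
  expect_gt(l1_to_profile(vals, poisson_profile(2, 450)), 0.99)
})

test_that("the Q statistic matches direct arithmetic and caps zero variance", {
  # one bin, abundances {2,4,4,6}: mean 4, population variance 2 -> Q = ln 2
  m <- matrix(c(2L, 4L, 4L, 6L), 1, 4, dimnames = list("f", paste0("g", 1:4)))
  b <- build_bins(genome_sizes(m), width = 10, step = 10, min_bin = 2)
  expect_length(b$bins, 1)
  qs <- q_statistic(m, b)
  expect_equal(unname(qs$Q_f), log(2), tolerance = 1e-12)

  # constant positive abundance in every bin: capped and flagged
  m <- matrix(3L, 1, 20, dimnames = list("f", paste0("g", 1:20)))
  b <- build_bins(genome_sizes(m))
  qs <- q_statistic(m, b, q_cap = 5)
  expect_equal(unname(qs$Q_f), 5)
  expect_true(qs$zero_var)

  # a zero-variance bin inherits the family's max positive-variance Q
  m <- matrix(0L, 2, 24)
  m[1, ] <- c(rep(10L, 12), rep(500L, 12))       # filler family splits sizes
  m[2, ] <- c(rep(2L, 12), c(rep(3L, 6), rep(5L, 6)))
  colnames(m) <- paste0("g", 1:24); rownames(m) <- c("filler", "f")
  b <- build_bins(genome_sizes(m), width = 100, step = 480, min_bin = 5)
  expect_length(b$bins, 2)
  qs <- q_statistic(m, b)
  expect_false(qs$zero_var[2])
  # bin 2 has mean 4, pop var 1 -> Q = ln 4; the constant bin 1 inherits ln 4
  expect_equal(unname(qs$Q_fb[2, ]), rep(log(4), 2), tolerance = 1e-12)
})

test_that("occurrence counts genomes carrying the family", {
  m <- rbind(all = rep(1L, 4), none = rep(0L, 4), some = c(1L, 2L, 3L, 0L))
  occ <- occurrence(m)
  expect_equal(unname(occ$O_f), c(1, 0, 0.75))
  expect_equal(unname(occ$O_count), c(4L, 0L, 3L))
})

test_that("the transfer fraction averages H/V over genomes where present", {
  V <- rbind(a = c(2L, 4L), b = c(3L, 3L), c = c(0L, 0L), d = c(2L, 2L))
  H <- rbind(a = c(1L, 1L), b = c(0L, 0L), c = c(0L, 0L), d = c(2L, 2L))
  hf <- h_index(V, H)
  expect_equal(unname(hf["a"]), 0.375)   # (1/2)(0.5 + 0.25)
  expect_equal(unname(hf["b"]), 0)
  expect_true(is.na(hf["c"]))            # never present
  expect_equal(unname(hf["d"]), 1)
  expect_warning(h_index(rbind(x = c(1L, 2L)), rbind(x = c(3L, 1L))),
                 "clipped")
})

test_that("binned trends average y inside equal-width x bins", {
  tr <- binned_trend(c(0.5, 1.5), c(0.5, 1.5), 2)
  expect_equal(tr$mean_y, c(0.5, 1.5))
  tr <- binned_trend(runif(50), rep(7, 50), 5)
  expect_true(all(tr$mean_y[tr$n > 0] == 7))
  x <- c(0, 0.1, 3)                      # middle bin empty
  tr <- binned_trend(x, x, 3)
  expect_true(is.na(tr$mean_y[2]))
  expect_error(binned_trend(1:3, 1:3, 0), "n_bins")
})

test_that("L and Q agree with brute-force recomputation on random instances", {
  set.seed(77)
  for (rep in 1:20) {
    F <- 6; G <- 20
    m <- matrix(rpois(F * G, lambda = sample(2:15, 1)), F, G)
    mode(m) <- "integer"
    rownames(m) <- paste0("f", 1:F); colnames(m) <- paste0("g", 1:G)
    inc <- rep %% 2 == 0
    fs <- family_stats(m, bin_width = 8, bin_step = 3, min_bin = 4,
                       v_max = 100, include_zeros = inc)
    ref <- naive_family_stats(m, width = 8, step = 3, min_bin = 4,
                              v_max = 100, include_zeros = inc)
    expect_equal(fs$stats$w, ref$w, tolerance = 1e-12)
    expect_equal(fs$stats$L, ref$L, tolerance = 1e-12)
    expect_equal(fs$stats$Q, ref$Q, tolerance = 1e-12)
  }
})

test_that("planted profile classes produce the expected Q and L signatures", {
  set.seed(88)
  G <- 800
  lam <- runif(8, 5, 50)
  pois <- t(vapply(lam, function(l) rpois(G, l), numeric(G)))
  disp <- 4  # = 1 + p_d/p_h
  nb <- t(vapply(lam, function(l)
    rnbinom(G, mu = l, size = l / (disp - 1)), numeric(G)))
  k <- sample(3:8, 8, replace = TRUE)
  peak <- t(vapply(k, function(kk) {
    shift <- sample(c(-1L, 0L, 1L), G, replace = TRUE,
                    prob = c(0.1, 0.8, 0.1))
    pmax(kk + shift, 0L)
  }, numeric(G)))
  m <- rbind(pois, nb, peak)
  mode(m) <- "integer"
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  colnames(m) <- paste0("g", seq_len(G))
  fs <- family_stats(m)$stats
  grp <- rep(c("pois", "nb", "peak"), each = 8)
  expect_true(all(abs(fs$Q[grp == "pois"]) < 0.15))
  expect_true(all(fs$L[grp == "pois"] < 0.1))
  expect_true(all(abs(fs$Q[grp == "nb"] - (-log(disp))) < 0.15))
  expect_true(all(fs$Q[grp == "peak"] > 1))
})

test_that("w tracks occurrence while Q stays independent of it", {
  set.seed(99)
  G <- 400
  nf <- 100
  O <- runif(nf, 0.3, 1)
  lam <- runif(nf, 5, 50)
  cls <- sample(c("pois", "nb", "peak"), nf, replace = TRUE)
  m <- t(vapply(seq_len(nf), function(f) {
    v <- switch(cls[f],
                pois = rpois(G, lam[f]),
                nb = rnbinom(G, mu = lam[f], size = lam[f] / 9),
                peak = pmax(5L + sample(c(-1L, 0L, 1L), G, replace = TRUE,
                                        prob = c(0.1, 0.8, 0.1)), 0L))
    v[runif(G) > O[f]] <- 0L
    v
  }, numeric(G)))
  mode(m) <- "integer"
  rownames(m) <- paste0("f", seq_len(nf)); colnames(m) <- paste0("g", 1:G)
  occ <- occurrence(m)$O_f
  sizes <- genome_sizes(m)
  bins <- build_bins(sizes, width = 390, step = 100)
  w <- sampling_weights(m, bins)$w_f
  expect_gt(cor(w, occ), 0.9)
  expect_true(all(w >= 0 & w <= 1))
  # presence-only Q is not driven by occurrence when classes are independent
  Q <- q_statistic(m, bins, include_zeros = FALSE)$Q_f
  expect_lt(abs(cor(Q, occ)), 0.2)
})
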