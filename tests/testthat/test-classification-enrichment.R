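test_that("classification applies the Q and w thresholds with strict inequalities", {
  df <- data.frame(family_id = letters[1:7],
                   Q = c(-1, 0, 2, -0.43, 1, NA, 2),
                   w = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.1))
  lab <- suppressWarnings(classify_families(df))
  expect_equal(as.character(lab$class),
               c("overdispersed", "poisson_like", "peaked",
                 "poisson_like",    # boundary Q = q_low stays poisson_like
                 "poisson_like",    # boundary Q = q_high stays poisson_like
                 "undersampled",    # missing Q
                 "undersampled"))   # w below the noise threshold
  expect_warning(classify_families(df), "missing Q")
  expect_equal(sum(table(lab$class)), nrow(df))  # labels partition families
})

test_that("the Fisher exact test matches closed forms and the enumeration oracle", {
  res <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  res <- fisher_exact_2x2(10, 0, 0, 10)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)

  res <- fisher_exact_2x2(3, 1, 1, 3)   # margins (4,4,4,4): p = 34/70
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)

  expect_equal(fisher_exact_2x2(0, 3, 2, 0)$odds_ratio, 0)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")

  # exhaustive check against the hypergeometric enumeration, margins <= 8
  for (a in 0:8) for (b in 0:(8 - a)) for (cc in 0:(8 - a)) {
    for (d in 0:min(8 - cc, 8 - b)) {
      expect_equal(fisher_exact_2x2(a, b, cc, d)$p_value,
                   enum_fisher_p(a, b, cc, d), tolerance = 1e-10)
    }
  }

  # independent cross-check against stats::fisher.test on random tables
  set.seed(10)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_exact_2x2(tb)$p_value, fisher.test(tb)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("category enrichment detects planted associations and degrades gracefully", {
  sim <- generate_ensemble(ensemble_spec(n_genomes = 300), seed = 3)
  lab <- data.frame(family_id = sim$truth$families$family_id,
                    class = factor(planted_label(sim$truth$families$class),
                                   levels = c("overdispersed", "poisson_like",
                                              "peaked", "undersampled")))
  ann <- generate_category_annotations(sim$truth,
                                       assoc = list(metabolism = c(poisson = 3)),
                                       seed = 4)
  enr <- category_enrichment(lab, ann, alpha = 0.01)
  hit <- enr[enr$category == "metabolism" & enr$class == "poisson_like", ]
  expect_lt(hit$p_value, 0.01)
  expect_equal(hit$direction, "over")
  expect_equal(unique(enr$a + enr$b + enr$c + enr$d), 300)

  # single-class labels make every test degenerate (p = 1)
  lab1 <- lab; lab1$class[] <- "poisson_like"
  enr1 <- category_enrichment(lab1, ann)
  expect_true(all(enr1$p_value == 1))
})

test_that("null annotations stay near the nominal false-positive rate", {
  set.seed(6)
  n_sig <- 0; n_tot <- 0
  for (r in 1:8) {
    sim <- generate_ensemble(ensemble_spec(n_genomes = 60, n_poisson = 40,
                                           n_overdispersed = 40,
                                           n_peaked = 40), seed = 100 + r)
    lab <- data.frame(family_id = sim$truth$families$family_id,
                      class = factor(planted_label(sim$truth$families$class),
                                     levels = c("overdispersed",
                                                "poisson_like", "peaked",
                                                "undersampled")))
    ann <- generate_category_annotations(sim$truth, assoc = list(),
                                         seed = 200 + r)
    enr <- category_enrichment(lab, ann, alpha = 0.01)
    n_sig <- n_sig + sum(enr$significant)
    n_tot <- n_tot + nrow(enr)
  }
  expect_lt(n_sig / n_tot, 0.05)  # nominal rate 0.01
})

test_that("plasmid log-ratio scores behave like share ratios", {
  # identical composition: all scores zero
  x <- c(4, 6, 10)
  expect_equal(unname(plasmid_enrichment_score(x, 3 * x, pseudocount = 0)),
               rep(0, 3))
  # a family with double its background share scores ln 2
  sc <- plasmid_enrichment_score(c(2, 2), c(1, 3), pseudocount = 0)
  expect_equal(unname(sc[1]), log(2))
  # pseudocount keeps absent families finite and negative
  sc <- plasmid_enrichment_score(c(0, 10), c(5, 5), pseudocount = 0.5)
  expect_true(is.finite(sc[1]) && sc[1] < 0)
  # invariance under a common scale factor
  expect_equal(plasmid_enrichment_score(7 * c(2, 2), 7 * c(1, 3),
                                        pseudocount = 0),
               plasmid_enrichment_score(c(2, 2), c(1, 3), pseudocount = 0))
})

test_that("class-restricted distances follow presence geometry", {
  m <- rbind(p1 = c(1L, 1L, 0L), p2 = c(2L, 3L, 0L),
             q1 = c(0L, 1L, 1L), q2 = c(0L, 2L, 1L))
  colnames(m) <- c("gA", "gB", "gC")
  lab <- data.frame(family_id = rownames(m),
                    class = factor(c("peaked", "peaked", "poisson_like",
                                     "poisson_like")))
  D <- class_restricted_distance(m, lab, "peaked")
  expect_equal(D["gA", "gB"], 0)        # identical restricted presence
  expect_equal(D["gA", "gC"], 1)        # disjoint presence sets
  expect_true(isSymmetric(D))

  Dbc <- class_restricted_distance(m, lab, "poisson_like",
                                   metric = "braycurtis")
  # genomes B (1,2) vs C (1,1): sum|x-y| / sum(x+y) = 1/5
  expect_equal(Dbc["gB", "gC"], 0.2)

  lab$class[1] <- "poisson_like"
  expect_error(class_restricted_distance(m, lab, "peaked"), "at least 2")
})

test_that("Spearman distance correlation is a rank statistic on upper triangles", {
  set.seed(12)
  D <- as.matrix(dist(matrix(runif(40), 20, 2)))
  expect_equal(spearman_distance_correlation(D, D), 1)
  expect_equal(spearman_distance_correlation(D, sqrt(D) + 2), 1)

  sh <- D
  ut <- upper.tri(sh)
  sh[ut] <- sample(sh[ut])
  sh[lower.tri(sh)] <- t(sh)[lower.tri(sh)]
  rho <- spearman_distance_correlation(D, sh)
  expect_lt(abs(rho), 3 / sqrt(sum(ut)))

  expect_error(spearman_distance_correlation(D, D[1:5, 1:5]), "dimensions")
  expect_warning(spearman_distance_correlation(D, matrix(1, 20, 20)),
                 "constant")
})
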