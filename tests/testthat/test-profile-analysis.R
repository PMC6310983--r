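test_that("Spearman implementation matches the rank-then-Pearson oracle", {
  set.seed(421)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties on purpose
    y <- x + rnorm(n, sd = 2)
    expect_equal(spearman_correlation(x, y)$rho, spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_correlation(1:3, 1:4), "equal length")
})

test_that("divergence-frequency correlation is -1 on a perfect gradient", {
  # three observed combos at distances 1,2,3 with monotone counts
  p <- profile_from_counts(c(GAAG = 30, CAAG = 20, CAAC = 10))
  combos <- c("GAAG", "CAAG", "CAAC")
  expect_equal(combo_hamming(combos, "GTAG"), c(1L, 2L, 3L))
  r <- spearman_correlation(combo_hamming(combos, "GTAG"),
                            p$counts[combos])
  expect_equal(r$rho, -1)

  # full-profile version over 256 combinations: counts decreasing with
  # distance give a strongly negative coefficient
  d <- combo_hamming(all_splice_combos(), "GTAG")
  full <- profile_from_counts(stats::setNames(1000 %/% 10^d,
                                              all_splice_combos()))
  rf <- divergence_frequency_correlation(full)
  expect_lt(rf$rho, -0.9)
  expect_equal(rf$n, 256L)
})

test_that("divergence-frequency correlation is rank (scale) invariant", {
  gen_prof <- simulate_species_profiles(
    n_species = 3, total_range = c(5000, 20000),
    config = generator_config(seed = 8, minor_mode = "distance"))
  r1 <- divergence_frequency_correlation(gen_prof)
  scaled <- lapply(gen_prof, function(p) {
    p$counts <- p$counts * 7L
    p
  })
  r2 <- divergence_frequency_correlation(scaled)
  expect_equal(r1$rho, r2$rho)
  expect_error(
    divergence_frequency_correlation(profile_from_counts(integer(0))),
    "zero")
})

test_that("profile similarity matrix is symmetric with unit diagonal", {
  prof <- simulate_species_profiles(
    n_species = 3, total_range = c(5000, 20000),
    config = generator_config(seed = 17))
  m <- profile_similarity_matrix(prof)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))

  # identical profiles correlate perfectly
  m2 <- profile_similarity_matrix(list(prof[[1]], prof[[1]]))
  expect_equal(unname(m2[1, 2]), 1)

  # hand-built small profiles match the brute-force oracle
  a <- profile_from_counts(c(GTAG = 100, GCAG = 10, ATAC = 5, CAGG = 2))
  b <- profile_from_counts(c(GTAG = 80, GCAG = 20, ATAC = 1, AATA = 3))
  m3 <- profile_similarity_matrix(list(a, b))
  expect_equal(unname(m3[1, 2]),
               spearman_oracle(a$counts[all_splice_combos()],
                               b$counts[all_splice_combos()]),
               tolerance = 1e-12)

  # zero-variance profile is reported as missing
  flat <- profile_from_counts(stats::setNames(rep(1, 256),
                                              all_splice_combos()))
  m4 <- profile_similarity_matrix(list(a, flat))
  expect_true(is.na(m4[1, 2]))
})

test_that("correlate_counts recovers monotone relations", {
  expect_equal(correlate_counts(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(correlate_counts(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_error(correlate_counts(1:4, 1:3), "equal length")
})

test_that("intron length comparison behaves under null and shift, deterministically", {
  set.seed(31)
  background <- round(rlnorm(500, log(200), 0.6))
  focal_null <- sample(background, 40)
  r_null <- compare_intron_lengths(focal_null, background, reps = 100,
                                   seed = 7)
  expect_gt(r_null$median_p, 0.05)

  r_shift <- compare_intron_lengths(focal_null + 1000, background,
                                    reps = 100, seed = 7)
  expect_lt(r_shift$median_p, 0.01)

  r_again <- compare_intron_lengths(focal_null, background, reps = 100,
                                    seed = 7)
  expect_identical(r_null, r_again)
  expect_equal(r_null$reps, 100L)
  expect_error(compare_intron_lengths(1:10, 1:5), "smaller")
})

test_that("long-intron enrichment ranks over-represented combos first", {
  mk <- function(combo, length, n) {
    data.frame(combo = rep(combo, n), length = rep(length, n),
               class = classify_combo(rep(combo, n)),
               stringsAsFactors = FALSE)
  }
  intr <- rbind(mk("AATA", 6000, 2), mk("AATA", 100, 1),
                mk("CAGG", 6000, 1), mk("CAGG", 100, 500),
                mk("TTTT", 100, 499))
  enr <- long_intron_enrichment(intr, threshold = 5000)
  expect_equal(enr$table$combo[1], "AATA")
  expect_false(enr$no_long_introns)
  expect_equal(sum(enr$table$count_long), 3L)
  # base counts per combo are consistent
  aata <- enr$table[enr$table$combo == "AATA", ]
  expect_equal(unlist(aata[, c("n_A", "n_C", "n_G", "n_T")],
                      use.names = FALSE),
               c(3L, 0L, 0L, 1L))

  # all-equal ratios -> lexicographic order among observed ties
  flat <- rbind(mk("AAAA", 6000, 1), mk("CCCC", 6000, 1),
                mk("AAAA", 100, 1), mk("CCCC", 100, 1))
  enr2 <- long_intron_enrichment(flat, threshold = 5000)
  top <- enr2$table[enr2$table$count_long > 0, ]
  expect_equal(top$combo, sort(top$combo))

  # threshold above every intron -> warning flag
  expect_warning(enr3 <- long_intron_enrichment(mk("AATA", 100, 5),
                                                threshold = 5000),
                 "no minor")
  expect_true(enr3$no_long_introns)
})

test_that("noncanonical-by-intron-count follows the independence model", {
  # q = 0 and q = 1 degenerate cases
  g0 <- data.frame(intron_count = rep(1:5, each = 10),
                   has_noncanonical = FALSE)
  expect_true(all(noncanonical_by_intron_count(g0)$median == 0))
  g1 <- data.frame(intron_count = rep(1:5, each = 10),
                   has_noncanonical = TRUE)
  expect_true(all(noncanonical_by_intron_count(g1)$median == 1))

  # per-intron probability q: P(gene has one) = 1 - (1-q)^n
  q <- 0.02
  set.seed(90)
  counts <- rep(1:20, each = 2000)
  has <- rbinom(length(counts), counts, q) > 0
  tab <- noncanonical_by_intron_count(
    data.frame(intron_count = counts, has_noncanonical = has))
  expected <- 1 - (1 - q)^(1:20)
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_true(all(abs(tab$median - expected) <= 3 * se))
  expect_error(noncanonical_by_intron_count(
    data.frame(intron_count = 0, has_noncanonical = TRUE)), ">= 1")
})

test_that("gene-set comparison reports Mann-Whitney p and means", {
  same <- data.frame(proportion_in_set = seq(0.05, 0.15, length.out = 30),
                     proportion_overall = seq(0.05, 0.15, length.out = 30))
  r <- compare_gene_sets(same)
  expect_gt(r$p_value, 0.9)
  expect_equal(r$mean_in_set, r$mean_overall)

  shifted <- same
  shifted$proportion_in_set <- shifted$proportion_in_set + 0.05
  r2 <- compare_gene_sets(shifted)
  expect_lt(r2$p_value, 0.05)
  expect_equal(r2$mean_in_set, mean(shifted$proportion_in_set))
  expect_error(compare_gene_sets(same[1:2, ]), "3 species")
})
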