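test_that("chi-square goodness of fit reproduces the survey's sex-ratio values", {
  r1 <- chisq_uniform(c(177, 164))
  expect_equal(r1$statistic, 0.4956, tolerance = 1e-4)
  expect_equal(r1$df, 1)
  expect_gt(r1$p_value, 0.05)
  r2 <- chisq_uniform(c(39, 22), yates = TRUE)
  expect_equal(r2$statistic, 4.7377, tolerance = 1e-4)
  expect_equal(r2$corrected_statistic, 4.1967, tolerance = 1e-4)
  expect_lt(r2$p_value, 0.05)
  r3 <- chisq_uniform(c(10, 10))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(chisq_uniform(c(5, 5, 5), yates = TRUE), "two classes")
})

test_that("chi-square statistic matches the brute-force oracle and chisq.test", {
  set.seed(12)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    counts <- rpois(k, sample(5:500, 1)) + 1
    res <- chisq_uniform(counts)
    expect_equal(res$statistic, oracle_chisq(counts), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(counts, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, unname(ref$p.value))
    if (k == 2) {
      ry <- chisq_uniform(counts, yates = TRUE)
      expect_lte(ry$corrected_statistic, ry$statistic)
    }
  }
})

test_that("sex-ratio test excludes undetermined specimens", {
  sp <- tiny_specimens()
  r <- sex_ratio_test(sp, "S. rhombeus")
  # b2 is undetermined, so only the single female counts -> (0 male, 1 female)
  expect_equal(r$statistic, 1)
  r_all <- sex_ratio_test(sp)
  expect_equal(r_all$statistic, oracle_chisq(c(1, 3)))
})

test_that("day/night test is exposure-weighted and label-invariant", {
  sim_profile <- function(counts) {
    sp <- data.frame(interval = rep(net_checks, counts))
    sp$species <- "x"; sp$season <- "flood"
    structure(list(group = group_key(),
                   counts = setNames(as.integer(counts), net_checks),
                   rel_freq = counts / sum(counts),
                   night_count = sum(counts[net_checks %in% nocturnal_checks]),
                   day_count = sum(counts[!net_checks %in% nocturnal_checks])),
              class = "activity_profile")
  }
  # equal effort per interval: 10 everywhere -> exposure-weighted chi2 = 0
  flat <- sim_profile(rep(10, 8))
  expect_equal(day_night_test(flat)$statistic, 0)
  # a 50/50 expectation would call that nocturnal preference
  expect_gt(day_night_test(flat, expectation = "equal")$statistic, 0)
  # all captures nocturnal -> large and significant
  allnight <- sim_profile(c(20, 20, 20, 20, 20, 0, 0, 0))
  expect_lt(day_night_test(allnight)$p_value, 0.05)
  # invariant to which intervals hold the counts, given the same 5/3 split
  p1 <- sim_profile(c(30, 5, 5, 5, 5, 4, 3, 3))
  p2 <- sim_profile(c(5, 5, 30, 5, 5, 3, 3, 4))
  expect_equal(day_night_test(p1)$statistic, day_night_test(p2)$statistic)
})

test_that("activity profile splits 8 intervals into night and day counts", {
  sim <- generate(preset_paper_like(seed = 2))
  ap <- activity_profile(sim$specimens, group_key("S. rhombeus"))
  expect_length(ap$counts, 8)
  expect_equal(sum(ap$counts), ap$night_count + ap$day_count)
  expect_equal(sum(ap$rel_freq), 1)
  het <- interval_heterogeneity_test(ap)
  expect_equal(het$df, 7)
})

test_that("G-test matches the hand oracle, including the 2x2 and null cases", {
  expect_equal(g_test(rbind(c(10, 0), c(0, 10)))$statistic, 27.72589,
               tolerance = 1e-5)
  even <- rbind(c(10, 20), c(10, 20))  # O = E everywhere
  expect_equal(g_test(even)$statistic, 0)
  set.seed(33)
  for (i in 1:50) {
    tab <- matrix(rpois(6, 20) + 1, nrow = 2)
    res <- g_test(tab)
    expect_equal(res$statistic, oracle_g(tab), tolerance = 1e-12)
    expect_equal(res$df, 2)
    resw <- g_test(tab, williams = TRUE)
    expect_lte(resw$corrected_statistic, resw$statistic)
  }
  expect_error(g_test(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("G under independent sampling behaves like its chi-square reference", {
  set.seed(44)
  pvals <- replicate(400, {
    tab <- matrix(rmultinom(1, 200, rep(1 / 6, 6)), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    g_test(tab)$p_value
  })
  pvals <- pvals[!is.na(pvals)]
  # asymptotically uniform p-values; generous band for a discrete statistic
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("seasonal occurrence G-test builds the present/absent by season table", {
  sim <- generate(preset_paper_like(seed = 8))
  res <- seasonal_fo_gtest(sim$items, sim$specimens, "S. gibbus", "plant")
  tab <- attr(res, "table")
  expect_equal(dim(tab), c(2, 2))
  expect_equal(rownames(tab), c("flood", "dry"))
  # margins are the per-season content-stomach counts
  N_flood <- occurrence_counts(sim$items, sim$specimens,
                               group_key("S. gibbus", "flood"))$N
  expect_equal(sum(tab["flood", ]), N_flood)
})

test_that("size-structure battery runs pre-checks then Student's t", {
  a <- c(10, 12, 14, 16, 18)
  res <- size_structure_compare(a, a)
  expect_equal(res$t$statistic, 0)
  expect_false(res$variance_flag)
  set.seed(55)
  het <- size_structure_compare(rnorm(40, 100, 1), rnorm(40, 100, 8))
  expect_true(het$variance_flag)
  expect_error(size_structure_compare(rep(5, 10), rnorm(10)), "zero-variance")
  expect_error(size_structure_compare(c(1, 2), rnorm(10)), "n >= 3")
})

test_that("shifted normal samples are reliably detected by the t-test", {
  set.seed(66)
  hits <- replicate(200, {
    a <- rnorm(50, 100, 10)
    b <- rnorm(50, 120, 10)  # shift of 2 sd
    size_structure_compare(a, b)$t$p_value < 0.05
  })
  expect_gte(mean(hits), 0.99)
})

test_that("class histograms use half-open classes and conserve the sample", {
  h <- class_histogram(c(1, 1.5, 2), 1)
  expect_equal(unname(h), c(2, 1))
  expect_equal(names(h), c("[1,2)", "[2,3)"))
  set.seed(77)
  v <- rnorm(500, 120, 25)
  h2 <- class_histogram(v, 10)
  expect_equal(sum(h2), 500)
  expect_length(class_histogram(numeric(0), 5), 0)
  expect_error(class_histogram(1:3, -1), "class_width")
})

test_that("uniform-null type-I error of the 8-interval test is calibrated", {
  set.seed(88)
  sims <- rmultinom(2000, 341, rep(1 / 8, 8))
  rej <- mean(apply(sims, 2, function(cnt) chisq_uniform(cnt)$p_value < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
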