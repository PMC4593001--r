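test_that("allele-frequency histograms use half-open bins, closed at 1", {
  d <- af_distribution(c(0.05, 0.05, 0.95))
  expect_equal(d$counts, c(2L, rep(0L, 8), 1L))
  expect_equal(d$n_sites, 3L)
  empty <- af_distribution(numeric(0))
  expect_equal(empty$counts, rep(0L, 10))
  expect_equal(empty$n_sites, 0L)
  # boundary: p = 1 lands in the last bin, p = 0.9 also (right-closed end)
  expect_equal(af_distribution(c(0.9, 1.0))$counts[10], 2L)
  expect_equal(sum(af_distribution(runif(100))$counts), 100L)
})

test_that("a neutral allele pair yields the symmetric U-shaped distribution", {
  # for two alleles neutral to each other, either member of the pair may
  # be the derived one: symmetrize the derived-allele spectrum
  set.seed(41)
  daf <- sample_allele_count(0, 200, 10000) / 200
  p <- ifelse(runif(10000) < 0.5, daf, 1 - daf)
  d <- af_distribution(p)
  expect_true(all(d$counts[1] > d$counts[2:9]))
  expect_true(all(d$counts[10] > d$counts[2:9]))
})

test_that("avoidance is a log2 count ratio, antisymmetric, NA when empty", {
  mat <- c(rep(0.05, 8), 0.5)
  zyg <- c(rep(0.05, 2), 0.5)
  av <- target_avoidance(mat, zyg)
  expect_equal(av$n_low_maternal, 8)
  expect_equal(av$n_low_zygotic, 2)
  expect_equal(av$avoidance, 2)
  expect_false(av$continuity)
  # symmetry and antisymmetry
  expect_equal(target_avoidance(zyg, zyg)$avoidance, 0)
  expect_equal(target_avoidance(zyg, mat)$avoidance, -av$avoidance)
  # one empty side: +0.5 continuity, flagged
  av0 <- target_avoidance(c(0.5, 0.5), c(0.05, 0.5))
  expect_true(av0$continuity)
  expect_equal(av0$avoidance, log2(0.5 / 1.5))
  # both sides empty: undefined
  expect_true(is.na(target_avoidance(c(0.5), c(0.5))$avoidance))
})

test_that("conservation mirrors avoidance at the high-frequency tail", {
  expect_equal(target_conservation(c(0.95, 0.95, 0.95, 0.95, 0.5),
                                   c(rep(0.95, 4)))$conservation, 0)
  expect_equal(target_conservation(rep(0.95, 6),
                                   rep(0.95, 3))$conservation, 1)
  expect_true(is.na(target_conservation(c(0.5), c(0.5))$conservation))
})

test_that("the one-sided KS left-shift test matches its closed form", {
  r <- ks_left_shift(rep(0.05, 20), rep(0.95, 20))
  expect_equal(r$d_plus, 1)
  expect_equal(r$p_value, exp(-20))
  same <- ks_left_shift(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(same$d_plus, 0)
  expect_equal(same$p_value, 1)
  expect_error(ks_left_shift(numeric(0), 0.5), "non-empty")
  # maternal stochastically larger: no left shift, p ~ 1
  set.seed(5)
  big <- ks_left_shift(runif(300, 0.5, 1), runif(300, 0, 0.5))
  expect_gt(big$p_value, 0.9)
})

test_that("the D+ statistic agrees with the stats::ks.test oracle", {
  set.seed(13)
  for (i in 1:50) {
    x <- runif(sample(5:60, 1))
    y <- runif(sample(5:60, 1))
    expect_equal(
      ks_left_shift(x, y)$d_plus,
      unname(suppressWarnings(
        stats::ks.test(x, y, alternative = "greater")$statistic)))
  }
})

test_that("class summaries give means, SEMs and Welch t-tests", {
  s <- summarize_by_class(c(1, 1, 1), rep("HIGH", 3))
  expect_equal(s$summary$mean, 1)
  expect_equal(s$summary$sem, 0)
  # two identical non-constant classes: t = 0, p = 1
  s2 <- summarize_by_class(c(1, 2, 3, 1, 2, 3),
                           rep(c("LOW", "HIGH"), each = 3))
  expect_equal(unname(s2$welch_p["LOW", "HIGH"]), 1)
  # classes are reported in abundance order
  expect_equal(s2$summary$class, c("LOW", "HIGH"))
})

test_that("selected vs neutral classes separate in the class summary", {
  set.seed(17)
  vals <- c(
    HIGH = replicate(20, {
      m <- sample_allele_count(-5, 200, 200) / 200
      z <- sample_allele_count(0, 200, 200) / 200
      target_avoidance(m, z)$avoidance
    }),
    NULLC = replicate(20, {
      m <- sample_allele_count(0, 200, 200) / 200
      z <- sample_allele_count(0, 200, 200) / 200
      target_avoidance(m, z)$avoidance
    })
  )
  cls <- rep(c("HIGH", "NULL"), each = 20)
  s <- summarize_by_class(vals, cls)
  expect_gt(s$summary$mean[s$summary$class == "HIGH"],
            s$summary$mean[s$summary$class == "NULL"])
  expect_lt(s$welch_p["HIGH", "NULL"], 0.01)
})

test_that("polarization keeps only ancestrally non-target sites", {
  sites <- data.frame(
    chrom = "2L", pos = c(100L, 200L, 300L),
    target_allele = "T", nontarget_allele = "C",
    n_target = c(3L, 5L, 7L), n_nontarget = c(27L, 25L, 23L),
    p = c(0.1, 1 / 6, 7 / 30), maternal = TRUE,
    stringsAsFactors = FALSE
  )
  outgroup <- data.frame(chrom = "2L", pos = c(100L, 200L, 300L),
                         base = c("C", "T", "G"),
                         stringsAsFactors = FALSE)
  expect_message(kept <- polarize(sites, outgroup), "neither allele")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pos, 100L)
  expect_equal(kept$daf, 0.1)
  expect_equal(kept$ancestral_state, "nontarget")
  expect_equal(attr(kept, "excluded"),
               c(target = 1L, other = 1L, missing = 0L))
})

test_that("the singleton chi-squared test reproduces the printed statistic", {
  r <- singleton_chisq(67, 236, 44, 223)
  expect_equal(round(r$chi2, 2), 4.69)
  expect_equal(round(r$p_value, 4), 0.0304)
  # equal proportions: chi2 = 0, p = 1
  expect_equal(singleton_chisq(10, 20, 10, 20)$p_value, 1)
  expect_equal(singleton_chisq(5, 25, 5, 25)$chi2, 0)
  # degenerate margins are rejected
  expect_error(singleton_chisq(0, 10, 0, 10), "margin")
})

test_that("singleton_excess counts derived alleles seen exactly once", {
  mk <- function(n_target) data.frame(n_target = n_target)
  r <- singleton_excess(mk(c(1, 1, 2, 5)), mk(c(1, 3, 4, 6, 7)))
  expect_equal(r$singletons_maternal, 2L)
  expect_equal(r$n_maternal, 4L)
  expect_equal(r$singletons_nonmaternal, 1L)
  expect_equal(r$n_nonmaternal, 5L)
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("the Monte-Carlo permutation matches exact enumeration on small tables", {
  set.seed(23)
  for (cc in list(c(8, 30, 3, 28), c(12, 40, 6, 45))) {
    pex <- exact_perm_chisq_p(cc[1], cc[2], cc[3], cc[4])
    pmc <- mc_perm_chisq_p(cc[1], cc[2], cc[3], cc[4], n_shuffles = 1e5)
    expect_lt(abs(pmc - pex), 3 * sqrt(pex * (1 - pex) / 1e5))
  }
})

test_that("DAF comparison detects disjoint and identical distributions", {
  expect_equal(daf_compare(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_lt(daf_compare(rep(0.05, 50), rep(0.95, 50)), 1e-10)
  expect_error(daf_compare(numeric(0), 0.5), "non-empty")
})

test_that("selected maternal DAFs separate from neutral in most replicates", {
  set.seed(29)
  hits <- replicate(100, {
    m <- sample_allele_count(-5, 200, 250) / 200
    z <- sample_allele_count(0, 200, 250) / 200
    daf_compare(m, z) < 1e-4
  })
  expect_gte(mean(hits), 0.9)
})
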