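#' Binned allele-frequency distribution
#'
#' Histogram of target-allele frequencies over `[0, 1]`. All bins are
#' half-open `[a, b)` except the final bin, which is closed at 1. Under
#' neutrality the distribution of two alleles in a finite population is
#' symmetric and U-shaped; selection against the target allele shifts it to
#' the left.
#'
#' @param p numeric vector of target-allele frequencies in `[0, 1]`.
#' @param n_bins number of equal-width bins (default 10).
#' @return list of class `af_distribution`: `bin_edges` (length
#'   `n_bins + 1`), `counts`, `n_sites`.
#' @export
af_distribution <- function(p, n_bins = 10) {
  stopifnot(all(p >= 0 & p <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- if (length(p) == 0) {
    integer(n_bins)
  } else {
    graphics::hist(p, breaks = edges, right = FALSE, include.lowest = TRUE,
                   plot = FALSE)$counts
  }
  structure(list(bin_edges = edges, counts = as.integer(counts),
                 n_sites = length(p)),
            class = "af_distribution")
}

# shared log2-ratio core for avoidance / conservation
log2_count_ratio <- function(n_mat, n_zyg) {
  if (n_mat == 0 && n_zyg == 0) {
    return(list(value = NA_real_, continuity = FALSE))
  }
  continuity <- n_mat == 0 || n_zyg == 0
  if (continuity) {
    n_mat <- n_mat + 0.5
    n_zyg <- n_zyg + 0.5
  }
  list(value = log2(n_mat / n_zyg), continuity = continuity)
}

#' Target avoidance: log2 ratio of low-frequency target sites
#'
#' Avoidance for one seed target is the log2 ratio of the number of
#' polymorphic target sites with target-allele frequency below `low_thr` in
#' maternal versus zygotic transcripts. Positive values mean maternal
#' transcripts carry the non-target allele more often than zygotic ones,
#' i.e. the target is avoided.
#'
#' When exactly one of the two counts is zero, 0.5 is added to both before
#' the ratio and the result is flagged (`continuity = TRUE`); when both are
#' zero the statistic is undefined (`NA`).
#'
#' @param maternal_p,zygotic_p target-allele frequencies of sites in
#'   maternal and zygotic transcripts for one seed target.
#' @param low_thr frequency threshold (default 0.1, strict `<`).
#' @return list: `n_low_maternal`, `n_low_zygotic`, `avoidance`,
#'   `continuity`.
#' @export
target_avoidance <- function(maternal_p, zygotic_p, low_thr = 0.1) {
  n_mat <- sum(maternal_p < low_thr)
  n_zyg <- sum(zygotic_p < low_thr)
  r <- log2_count_ratio(n_mat, n_zyg)
  list(n_low_maternal = n_mat, n_low_zygotic = n_zyg,
       avoidance = r$value, continuity = r$continuity)
}

#' Target conservation: log2 ratio of high-frequency target sites
#'
#' The mirror statistic of [target_avoidance()]: log2 ratio of the number of
#' sites with target-allele frequency above `high_thr` (default 0.9, strict
#' `>`) in maternal versus zygotic transcripts. Positive values mean target
#' sites are preferentially conserved in maternal transcripts.
#'
#' @inheritParams target_avoidance
#' @param high_thr frequency threshold (default 0.9).
#' @return list: `n_high_maternal`, `n_high_zygotic`, `conservation`,
#'   `continuity`.
#' @export
target_conservation <- function(maternal_p, zygotic_p, high_thr = 0.9) {
  n_mat <- sum(maternal_p > high_thr)
  n_zyg <- sum(zygotic_p > high_thr)
  r <- log2_count_ratio(n_mat, n_zyg)
  list(n_high_maternal = n_mat, n_high_zygotic = n_zyg,
       conservation = r$value, continuity = r$continuity)
}

#' One-sided Kolmogorov-Smirnov test for a left shift
#'
#' Tests whether the maternal allele-frequency distribution is shifted to
#' the left of the zygotic one. The statistic is
#' \eqn{D^+ = \sup_x [\hat F_{mat}(x) - \hat F_{zyg}(x)]} and the one-sided
#' asymptotic p-value is \eqn{\exp(-2 D^{+2} mn/(m+n))}, clamped to (0, 1].
#'
#' @param maternal_p,zygotic_p non-empty numeric vectors of frequencies.
#' @return list of class `ks_shift`: `d_plus`, `p_value`, `n_maternal`,
#'   `n_zygotic`.
#' @export
ks_left_shift <- function(maternal_p, zygotic_p) {
  m <- length(maternal_p)
  n <- length(zygotic_p)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  w <- c(maternal_p, zygotic_p)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= m, 1 / m, -1 / n))
  ws <- w[ord]
  # with ties, the CDF difference is defined only after the whole tie group
  last_of_group <- c(diff(ws) != 0, TRUE)
  d_plus <- max(0, steps[last_of_group])
  p <- exp(-2 * d_plus^2 * m * n / (m + n))
  structure(list(d_plus = d_plus, p_value = min(1, p),
                 n_maternal = m, n_zygotic = n),
            class = "ks_shift")
}

#' Per-abundance-class summary of avoidance/conservation values
#'
#' Unweighted mean and SEM of a per-miRNA statistic within each egg
#' abundance class, plus pairwise Welch (unequal-variance) two-sample
#' t-tests between classes. `NA` values are dropped.
#'
#' @param values numeric vector (one value per miRNA/seed).
#' @param classes character vector of abundance classes, same length.
#' @return list: `summary` (data.frame class/n/mean/sem) and `welch_p`
#'   (symmetric matrix of pairwise Welch t-test p-values; `NA` when a class
#'   has fewer than 2 values).
#' @export
summarize_by_class <- function(values,
                               classes = rep("ALL", length(values))) {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values)
  values <- values[keep]
  classes <- as.character(classes[keep])
  lev <- intersect(c("NULL", "LOW", "MID", "HIGH"), unique(classes))
  if (length(lev) == 0) lev <- sort(unique(classes))
  groups <- split(values, factor(classes, levels = lev))
  summ <- data.frame(
    class = lev,
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, function(x) mean(x), numeric(1)),
    sem = vapply(groups, function(x) {
      if (length(x) < 2) return(NA_real_)
      stats::sd(x) / sqrt(length(x))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  k <- length(lev)
  welch <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      x <- groups[[i]]; y <- groups[[j]]
      if (length(x) >= 2 && length(y) >= 2 &&
          (stats::sd(x) > 0 || stats::sd(y) > 0)) {
        welch[i, j] <- welch[j, i] <-
          stats::t.test(x, y, var.equal = FALSE)$p.value
      } else if (length(x) >= 2 && length(y) >= 2) {
        welch[i, j] <- welch[j, i] <- 1  # both constant and equal-variance
      }
    }
  }
  list(summary = summ, welch_p = welch)
}

#' Polarize polymorphic target sites against an outgroup
#'
#' Keeps the sites whose outgroup base equals the non-target allele; under
#' the assumption that the outgroup carries the ancestral state, the target
#' allele is then derived and its frequency `p` is the derived allele
#' frequency (DAF). Sites where the outgroup carries the target allele or a
#' third base are excluded.
#'
#' @param sites site table from [build_site_table()].
#' @param outgroup data.frame with columns `chrom`, `pos`, `base`; bases
#'   must be in the same sense orientation as the site table alleles.
#' @return the subset of `sites` with added columns `ancestral_state`
#'   (`"nontarget"`) and `daf` (= `p`); attribute `excluded` holds the
#'   counts of sites dropped because the outgroup matched the target allele
#'   or neither allele, or was absent.
#' @export
polarize <- function(sites, outgroup) {
  key <- paste(outgroup$chrom, outgroup$pos)
  base <- outgroup$base[match(paste(sites$chrom, sites$pos), key)]
  state <- ifelse(is.na(base), "missing",
                  ifelse(base == sites$nontarget_allele, "nontarget",
                         ifelse(base == sites$target_allele, "target",
                                "other")))
  kept <- sites[state == "nontarget", , drop = FALSE]
  if (nrow(kept) > 0) {
    kept$ancestral_state <- "nontarget"
    kept$daf <- kept$p
  } else {
    kept$ancestral_state <- character(0)
    kept$daf <- numeric(0)
  }
  row.names(kept) <- NULL
  excl <- c(target = sum(state == "target"),
            other = sum(state == "other"),
            missing = sum(state == "missing"))
  if (excl[["other"]] > 0) {
    message(excl[["other"]],
            " site(s) excluded: outgroup base matches neither allele")
  }
  attr(kept, "excluded") <- excl
  kept
}

#' Pearson chi-squared test on a 2x2 singleton table
#'
#' @param k1,n1 singleton count and total sites in group 1 (maternal).
#' @param k2,n2 singleton count and total sites in group 2 (nonmaternal).
#' @return list: `chi2`, `p_value`, `table` (the 2x2 matrix of singleton vs
#'   non-singleton counts). 1 df, no continuity correction. Errors if any
#'   table margin is zero.
#' @export
singleton_chisq <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE,
                dimnames = list(c("maternal", "nonmaternal"),
                                c("singleton", "non_singleton")))
  if (any(tab < 0)) stop("singleton counts exceed totals")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: a table margin is zero")
  }
  # small-expected-count warnings are expected on small tables; the
  # permutation cross-check in the test suite covers that regime
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Singleton excess between maternal and nonmaternal derived target alleles
#'
#' A singleton is a derived (target) allele observed in exactly one sampled
#' line (`n_target == 1`). Compares singleton proportions between maternal
#' and nonmaternal site sets with a Pearson chi-squared test (1 df, no
#' continuity correction).
#'
#' @param maternal_sites,nonmaternal_sites polarized site tables from
#'   [polarize()] (need column `n_target`).
#' @return list: `singletons_maternal`, `n_maternal`,
#'   `singletons_nonmaternal`, `n_nonmaternal`, `chi2`, `p_value`.
#' @export
singleton_excess <- function(maternal_sites, nonmaternal_sites) {
  k1 <- sum(maternal_sites$n_target == 1L)
  n1 <- nrow(maternal_sites)
  k2 <- sum(nonmaternal_sites$n_target == 1L)
  n2 <- nrow(nonmaternal_sites)
  ct <- singleton_chisq(k1, n1, k2, n2)
  list(singletons_maternal = k1, n_maternal = n1,
       singletons_nonmaternal = k2, n_nonmaternal = n2,
       chi2 = ct$chi2, p_value = ct$p_value)
}

#' Compare two derived-allele-frequency distributions
#'
#' Two-sample Kolmogorov-Smirnov test: two-sided by default (via
#' [stats::ks.test()]), or the one-sided left-shift variant of
#' [ks_left_shift()] testing whether the maternal DAF distribution lies to
#' the left of the nonmaternal one.
#'
#' @param maternal_dafs,nonmaternal_dafs non-empty numeric vectors.
#' @param alternative `"two.sided"` (default) or `"left_shift"`.
#' @return the p-value.
#' @export
daf_compare <- function(maternal_dafs, nonmaternal_dafs,
                        alternative = c("two.sided", "left_shift")) {
  alternative <- match.arg(alternative)
  if (length(maternal_dafs) == 0 || length(nonmaternal_dafs) == 0) {
    stop("both samples must be non-empty")
  }
  if (alternative == "left_shift") {
    return(ks_left_shift(maternal_dafs, nonmaternal_dafs)$p_value)
  }
  suppressWarnings(
    stats::ks.test(maternal_dafs, nonmaternal_dafs)$p.value
  )
}
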