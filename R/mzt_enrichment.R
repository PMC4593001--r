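#' Count targeted unstable/stable maternal transcripts for one seed
#'
#' A transcript is targeted when its 3' UTR contains at least one exact
#' occurrence of the target sixmer. Counting is per transcript and
#' restricted to maternal transcripts carrying a stability label.
#'
#' @param target DNA target sixmer.
#' @param utr_sequences named character vector of maternal 3' UTR sense
#'   sequences (names = transcript ids).
#' @param stability data.frame with columns `transcript_id` and `unstable`
#'   (0/1 or logical): transcripts destabilized across the
#'   maternal-to-zygotic transition.
#' @return integer vector `c(n_unstable, n_stable)` over labeled, targeted
#'   transcripts.
#' @export
count_targeted <- function(target, utr_sequences, stability) {
  lab <- stability[stability$transcript_id %in% names(utr_sequences), ,
                   drop = FALSE]
  seqs <- utr_sequences[lab$transcript_id]
  # presence only: a fixed-string match is equivalent to >= 1 scan hit
  targeted <- grepl(target, seqs, fixed = TRUE)
  unstable <- as.logical(lab$unstable)
  c(n_unstable = sum(targeted & unstable),
    n_stable = sum(targeted & !unstable))
}

#' Proportion of unstable transcripts among targeted transcripts
#'
#' @param n_unstable,n_stable non-negative counts; their sum must be > 0.
#' @return `n_unstable / (n_unstable + n_stable)` rounded half away from
#'   zero to 3 decimals (the reporting precision of the enrichment table).
#' @export
proportion_unstable <- function(n_unstable, n_stable) {
  if (any(n_unstable + n_stable <= 0)) stop("no targeted transcripts")
  round_half_away(n_unstable / (n_unstable + n_stable), 3)
}

#' Upper-tail cumulative binomial enrichment test
#'
#' Exact upper-tail probability P(X >= k | n, p0) that at least `k` of `n`
#' targeted transcripts are unstable when the genome-wide unstable
#' proportion is `p0`.
#'
#' @param k observed unstable count.
#' @param n total targeted (labeled) transcripts.
#' @param p0 expected unstable proportion (default 0.146).
#' @return the p-value; 1 when `k == 0`.
#' @export
binomial_enrichment <- function(k, n, p0 = 0.146) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up q-values by default; Storey's estimator (with
#' a fixed lambda) optionally rescales them by the estimated null proportion
#' pi0.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda tuning parameter of Storey's pi0 estimate (default 0.5).
#' @return q-values, same order as `p`.
#' @export
fdr_qvalues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Binomial test for maternal deposition of microRNA host genes
#'
#' Upper-tail probability that at least `k_maternal` of `n_informative` host
#' genes produce maternally deposited transcripts when the genome-wide
#' background proportion is `background`.
#'
#' @param k_maternal maternally deposited host genes.
#' @param n_informative host genes with expression information.
#' @param background genome-wide maternal-deposition proportion.
#' @return p-value P(X >= k | n, background).
#' @export
host_gene_binomial <- function(k_maternal, n_informative, background) {
  binomial_enrichment(k_maternal, n_informative, p0 = background)
}

#' Expected unstable proportion from a label table
#'
#' @param stability data.frame with an `unstable` column (0/1 or logical).
#' @return fraction of unstable transcripts among all labeled transcripts;
#'   warns when degenerate (0 or 1).
#' @export
expected_proportion <- function(stability) {
  if (nrow(stability) == 0) stop("label table is empty")
  p0 <- mean(as.logical(stability$unstable))
  if (p0 == 0 || p0 == 1) {
    warning("degenerate null: all transcripts are ",
            if (p0 == 0) "stable" else "unstable")
  }
  p0
}

#' Per-seed-family enrichment of MZT-destabilized targets
#'
#' For every seed family, counts targeted unstable/stable maternal
#' transcripts, tests enrichment of unstable targets against `p0` with the
#' upper-tail binomial test, and controls the FDR across families.
#'
#' @param families data.frame from [collapse_seed_families()] (columns
#'   `target`, `members`).
#' @param utr_sequences named character vector of maternal 3' UTR sequences.
#' @param stability stability label table (see [count_targeted()]).
#' @param p0 expected unstable proportion; `NULL` (default) estimates it
#'   from the label table with [expected_proportion()].
#' @param fdr_method passed to [fdr_qvalues()].
#' @return data.frame with one row per seed family: `seed_group`, `target`,
#'   `n_unstable`, `n_stable`, `proportion_unstable`, `p0`, `p_value`,
#'   `q_value`. Families with no targeted labeled transcript get
#'   `p_value = 1` and `NA` proportion.
#' @export
mzt_enrichment_table <- function(families, utr_sequences, stability,
                                 p0 = NULL, fdr_method = "BH") {
  if (is.null(p0)) p0 <- expected_proportion(stability)
  res <- lapply(seq_len(nrow(families)), function(i) {
    cnt <- count_targeted(families$target[i], utr_sequences, stability)
    n <- sum(cnt)
    data.frame(
      seed_group = families$members[i],
      target = families$target[i],
      n_unstable = unname(cnt[1]), n_stable = unname(cnt[2]),
      proportion_unstable = if (n > 0) proportion_unstable(cnt[1], cnt[2])
                            else NA_real_,
      p0 = p0,
      p_value = if (n > 0) binomial_enrichment(cnt[1], n, p0) else 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q_value <- fdr_qvalues(out$p_value, method = fdr_method)
  out <- out[order(out$p_value), , drop = FALSE]
  row.names(out) <- NULL
  out
}
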