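# Fixture builders: everything is generated in code at test time.

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

write_labels <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal VCF v4.2 with haploid GT columns; gt is a sites x lines matrix
# of "0"/"1"/"." characters
write_vcf_text <- function(fix, gt, path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT",
            sprintf("l%02d", seq_len(ncol(gt)))), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(fix)), function(i) {
    paste(c(fix$chrom[i], fix$pos[i], ".", fix$ref[i], fix$alt[i], ".",
            "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  path
}

# small simulated dataset shared by round-trip tests
small_sim <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_lines = 50, n_mirs = 4, n_utrs = 20, utr_length = 400,
         sites_per_class = 6, rng_seed = seed),
    list(...)
  )
  simulate_dataset(do.call(sim_config, args))
}

# exact conditional (label-permutation) p-value of the 2x2 chi-squared
# statistic, by full hypergeometric enumeration; mid-p optional
exact_perm_chisq_p <- function(k1, n1, k2, n2, mid = FALSE) {
  K <- k1 + k2
  N <- n1 + n2
  ks <- max(0, K - n2):min(K, n1)
  a <- ks; b <- n1 - a; cc <- K - a; d <- n2 - cc
  stat <- N * (a * d - b * cc)^2 / (n1 * n2 * K * (N - K))
  obs <- stat[ks == k1]
  pr <- dhyper(ks, n1, n2, K)
  if (mid) {
    sum(pr[stat > obs + 1e-9]) + 0.5 * sum(pr[abs(stat - obs) <= 1e-9])
  } else {
    sum(pr[stat >= obs - 1e-9])
  }
}

# Monte-Carlo label-permutation p for the same statistic; a permutation of
# group labels induces a hypergeometric count, sampled via rhyper
mc_perm_chisq_p <- function(k1, n1, k2, n2, n_shuffles = 1e5,
                            mid = FALSE) {
  K <- k1 + k2
  N <- n1 + n2
  stat_of <- function(a) {
    b <- n1 - a; cc <- K - a; d <- n2 - cc
    N * (a * d - b * cc)^2 / (n1 * n2 * K * (N - K))
  }
  obs <- stat_of(k1)
  perm <- stat_of(rhyper(n_shuffles, n1, n2, K))
  if (mid) {
    mean(perm > obs + 1e-9) + 0.5 * mean(abs(perm - obs) <= 1e-9)
  } else {
    mean(perm >= obs - 1e-9)
  }
}

# egg read-count fixture: the printed profiling counts, 13,114 mapped
# reads in total, plus precursor loci for cluster aggregation
egg_counts_fixture <- function(dir) {
  counts <- data.frame(
    name = c("mir-310", "mir-311", "mir-312", "mir-313",
             "mir-92a", "mir-92b", "mir-184", "bantam", "other"),
    read_count = c(356L, 2012L, 1661L, 82L, 172L, 2109L, 1377L, 1204L,
                   13114L - 8973L)
  )
  stopifnot(sum(counts$read_count) == 13114L)
  cpath <- write_labels(counts, file.path(dir, "counts.tsv"))
  loci <- data.frame(
    chrom = c(rep("2R", 4), "3R", "3R", "2R", "3L", "X"),
    start = c(1e6, 1e6 + 2e3, 1e6 + 4e3, 1e6 + 6e3,
              5e6, 5e6 + 3e3, 8e6, 2e6, 3e6),
    end = c(1e6 + 100, 1e6 + 2100, 1e6 + 4100, 1e6 + 6100,
            5e6 + 100, 5e6 + 3100, 8e6 + 100, 2e6 + 100, 3e6 + 100),
    name = counts$name, score = 0L, strand = "+"
  )
  lpath <- write_bed(loci, file.path(dir, "loci.bed"))
  list(counts = cpath, loci = lpath)
}
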