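#' Site-frequency-spectrum sampling weights for a segregating allele
#'
#' Discretized stationary density of the frequency of an allele under
#' genic selection in the Poisson-random-field / diffusion approximation:
#' \deqn{f(x) = \frac{1 - e^{-2\gamma(1-x)}}{(1 - e^{-2\gamma})\, x (1-x)}}
#' evaluated at `x = i / n_lines`, `i = 1, ..., n_lines - 1`, where
#' `gamma = 2Ns` is the scaled selection coefficient acting on the allele.
#' The neutral limit `gamma = 0` is the classical `1/i` spectrum. Negative
#' `gamma` (selection against the allele) shifts mass toward low
#' frequencies.
#'
#' @param gamma scaled selection coefficient (0 = neutral).
#' @param n_lines number of sampled lines (>= 2).
#' @return numeric vector of unnormalized weights for counts
#'   `1 .. n_lines - 1`.
#' @export
sfs_weights <- function(gamma, n_lines) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  i <- seq_len(n_lines - 1)
  x <- i / n_lines
  if (gamma == 0) {
    w <- 1 / x
  } else {
    w <- (1 - exp(-2 * gamma * (1 - x))) /
      ((1 - exp(-2 * gamma)) * x * (1 - x))
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("SFS weights under/overflow at gamma = ", gamma,
         "; use a smaller |gamma| (|gamma| < ~350 is safe)")
  }
  w
}

#' Draw segregating target-allele counts from the SFS
#'
#' @param gamma scaled selection coefficient on the target allele.
#' @param n_lines number of sampled lines.
#' @param n number of draws.
#' @return integer vector of counts in `[1, n_lines - 1]`.
#' @export
sample_allele_count <- function(gamma, n_lines, n = 1) {
  sample.int(n_lines - 1L, size = n, replace = TRUE,
             prob = sfs_weights(gamma, n_lines))
}

#' Configuration of the synthetic population-data generator
#'
#' Defaults emulate the study conditions: ~200 sequenced inbred lines, a
#' genome-wide unstable-transcript proportion of 0.146, neutral evolution
#' of both site classes unless a selection coefficient is set, and perfect
#' outgroup polarization.
#'
#' @param n_lines sampled inbred lines (default 200).
#' @param gamma_maternal,gamma_zygotic scaled selection coefficients
#'   `2Ns` acting on the target allele at sites in maternal / zygotic
#'   transcripts (default 0 = neutral).
#' @param n_mirs number of microRNAs (default 10).
#' @param n_utrs number of single-exon 3' UTRs, half maternal (default 60).
#' @param utr_length UTR length in bp (default 800).
#' @param gc_content background GC fraction of UTR sequence (default 0.38,
#'   typical of *Drosophila* 3' UTRs).
#' @param sites_per_class polymorphic target sites planted per microRNA in
#'   each transcript class (default 20).
#' @param unstable_rate baseline probability that a maternal transcript is
#'   MZT-destabilized (default 0.146).
#' @param enriched_seeds named numeric vector: target sixmer ->
#'   unstable-rate multiplier for transcripts targeted by that seed
#'   (default none).
#' @param mispolarization_rate probability that the emitted outgroup base
#'   wrongly shows the (derived) target allele (default 0).
#' @param rng_seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200, gamma_maternal = 0,
                       gamma_zygotic = 0, n_mirs = 10, n_utrs = 60,
                       utr_length = 800, gc_content = 0.38,
                       sites_per_class = 20, unstable_rate = 0.146,
                       enriched_seeds = numeric(0),
                       mispolarization_rate = 0, rng_seed = 1) {
  stopifnot(n_lines >= 2, n_mirs >= 1, n_utrs >= 2, utr_length >= 50,
            gc_content > 0, gc_content < 1,
            sites_per_class >= 0,
            unstable_rate >= 0, unstable_rate <= 1,
            mispolarization_rate >= 0, mispolarization_rate < 1)
  structure(list(
    n_lines = as.integer(n_lines), gamma_maternal = gamma_maternal,
    gamma_zygotic = gamma_zygotic, n_mirs = as.integer(n_mirs),
    n_utrs = as.integer(n_utrs), utr_length = as.integer(utr_length),
    gc_content = gc_content, sites_per_class = as.integer(sites_per_class),
    unstable_rate = unstable_rate, enriched_seeds = enriched_seeds,
    mispolarization_rate = mispolarization_rate,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# random DNA at a given GC content
random_dna <- function(len, gc) {
  paste(sample(DNA_BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# enumerate qualifying (window, alleles) pairs for one SNP and one target;
# independent of classify_site (used for generator bookkeeping)
truth_classify <- function(seq, offset, a1, a2, target) {
  len <- nchar(seq)
  ws <- seq.int(max(0L, offset - 5L), min(offset, len - 6L))
  ws <- ws[ws >= 0 & ws <= len - 6L]
  for (w in ws) {
    left <- substr(seq, w + 1L, offset)
    right <- substr(seq, offset + 2L, w + 6L)
    v1 <- paste0(left, a1, right)
    v2 <- paste0(left, a2, right)
    if (xor(v1 == target, v2 == target)) {
      if (v1 == target) {
        return(list(window_offset = w, target_allele = a1,
                    nontarget_allele = a2))
      }
      return(list(window_offset = w, target_allele = a2,
                  nontarget_allele = a1))
    }
  }
  NULL
}

#' Simulate a complete synthetic dataset
#'
#' Generates microRNAs, single-exon 3' UTRs (each on its own chromosome,
#' half on the minus strand), and for every microRNA plants
#' `sites_per_class` biallelic SNPs in maternal and in zygotic UTRs such
#' that one allele completes the target sixmer and the other a random
#' one-nucleotide neighbor. Target-allele counts are drawn from the SFS
#' with the class's selection coefficient; the non-target allele is
#' ancestral (it is the allele the outgroup carries, except with
#' probability `mispolarization_rate`). Maternal transcripts receive
#' Bernoulli stability labels at `unstable_rate`, optionally multiplied for
#' transcripts targeted by enriched seeds. Planted windows are
#' non-overlapping (>= 12 bp apart) so ground truth is unambiguous.
#'
#' The ground-truth site table is computed by enumerating every planted SNP
#' against every seed over the final reference sequences, so it also
#' captures sites that background sequence context happens to create for a
#' non-focal seed.
#'
#' @param config a [sim_config()] list.
#' @return list of class `sim_dataset` with elements `config`, `mirs`,
#'   `seeds`, `utrs` (same shape as [load_utrs()] output), `snps`, `gt`
#'   (line x site genotype matrix, "0"/"1"), `outgroup`,
#'   `maternal_labels`, `stability`, `truth_sites` (same shape as
#'   [build_site_table()] output) and `truth_daf`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  cf <- config

  # --- microRNAs with distinct target sixmers ---------------------------
  mature <- character(cf$n_mirs)
  targets <- character(cf$n_mirs)
  for (k in seq_len(cf$n_mirs)) {
    repeat {
      s <- chartr("T", "U", random_dna(22, 0.5))
      tg <- dna_revcomp(chartr("U", "T", substr(s, 2, 7)))
      if (!tg %in% targets) break
    }
    mature[k] <- s
    targets[k] <- tg
  }
  mir_names <- sprintf("mir-s%02d-3p", seq_len(cf$n_mirs))
  read_count <- as.integer(round(stats::rlnorm(cf$n_mirs,
                                               meanlog = log(50),
                                               sdlog = 2)))
  read_count[stats::runif(cf$n_mirs) < 0.15] <- 0L
  mirs <- data.frame(name = mir_names, sequence = mature,
                     chrom = "chrMIR",
                     start = 20000L * seq_len(cf$n_mirs),
                     strand = "+", read_count = read_count,
                     stringsAsFactors = FALSE)
  seeds <- extract_seed(mir_names, mature)

  # --- UTRs -------------------------------------------------------------
  n_mat <- ceiling(cf$n_utrs / 2)
  utrs <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(cf$n_utrs)),
    gene_id = sprintf("g%04d", seq_len(cf$n_utrs)),
    chrom = sprintf("chr%04d", seq_len(cf$n_utrs)),
    start = 50L, end = 50L + cf$utr_length,
    strand = rep_len(c("+", "-"), cf$n_utrs),
    exon_count = 1L,
    stringsAsFactors = FALSE
  )
  utrs$maternal <- seq_len(cf$n_utrs) <= n_mat
  sense_seq <- vapply(seq_len(cf$n_utrs),
                      function(i) random_dna(cf$utr_length, cf$gc_content),
                      character(1))

  # --- plant polymorphic target sites -----------------------------------
  planted_w <- vector("list", cf$n_utrs)  # window starts used per UTR
  plant <- list()
  for (k in seq_len(cf$n_mirs)) {
    tg <- targets[k]
    tg_bases <- strsplit(tg, "")[[1]]
    for (maternal_class in c(TRUE, FALSE)) {
      class_utrs <- which(utrs$maternal == maternal_class)
      gamma <- if (maternal_class) cf$gamma_maternal else cf$gamma_zygotic
      for (r in seq_len(cf$sites_per_class)) {
        placed <- FALSE
        for (try in seq_len(500)) {
          u <- class_utrs[sample.int(length(class_utrs), 1)]
          w <- sample.int(cf$utr_length - 5L, 1) - 1L
          if (all(abs(w - planted_w[[u]]) >= 12L)) { placed <- TRUE; break }
        }
        if (!placed) {  # exhaustive fallback before giving up
          for (u in class_utrs[sample.int(length(class_utrs))]) {
            free <- setdiff(0:(cf$utr_length - 6L),
                            unlist(lapply(planted_w[[u]],
                                          function(x) (x - 11L):(x + 11L))))
            if (length(free) > 0) {
              w <- free[sample.int(length(free), 1)]
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          stop("requested sites exceed available non-overlapping windows; ",
               "increase n_utrs or utr_length, or lower sites_per_class")
        }
        planted_w[[u]] <- c(planted_w[[u]], w)
        j <- sample.int(6L, 1)
        nb_base <- sample(setdiff(DNA_BASES, tg_bases[j]), 1)
        ref_is_target <- stats::runif(1) < 0.5
        s <- sense_seq[u]
        substr(s, w + 1L, w + 6L) <- tg
        if (!ref_is_target) {
          substr(s, w + j, w + j) <- nb_base
        }
        sense_seq[u] <- s
        cnt <- sample_allele_count(gamma, cf$n_lines)
        mispol <- stats::runif(1) < cf$mispolarization_rate
        plant[[length(plant) + 1L]] <- data.frame(
          utr = u, window = w, snp_offset = w + j - 1L,
          target_allele = tg_bases[j], nontarget_allele = nb_base,
          ref_is_target = ref_is_target, mir = k,
          n_target = cnt, mispolarized = mispol,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  plant <- if (length(plant)) do.call(rbind, plant) else
    data.frame(utr = integer(0), window = integer(0),
               snp_offset = integer(0), target_allele = character(0),
               nontarget_allele = character(0), ref_is_target = logical(0),
               mir = integer(0), n_target = integer(0),
               mispolarized = logical(0))
  utrs$sequence <- sense_seq

  # --- genomic SNP table + genotypes ------------------------------------
  n_snp <- nrow(plant)
  snp <- data.frame(chrom = character(n_snp), pos = integer(n_snp),
                    ref = character(n_snp), alt = character(n_snp),
                    count_ref = integer(n_snp), count_alt = integer(n_snp),
                    n_lines = rep(cf$n_lines, n_snp),
                    stringsAsFactors = FALSE)
  gt <- matrix("0", nrow = n_snp, ncol = cf$n_lines)
  outgroup <- data.frame(chrom = character(n_snp), pos = integer(n_snp),
                         base = character(n_snp), stringsAsFactors = FALSE)
  for (i in seq_len(n_snp)) {
    u <- plant$utr[i]
    utr <- utrs[u, ]
    off <- plant$snp_offset[i]
    if (utr$strand == "+") {
      pos <- utr$start + off + 1L
      g_tar <- plant$target_allele[i]
      g_non <- plant$nontarget_allele[i]
    } else {
      pos <- utr$end - off
      g_tar <- dna_complement(plant$target_allele[i])
      g_non <- dna_complement(plant$nontarget_allele[i])
    }
    ref <- if (plant$ref_is_target[i]) g_tar else g_non
    alt <- if (plant$ref_is_target[i]) g_non else g_tar
    cnt <- plant$n_target[i]
    carriers <- sample.int(cf$n_lines, cnt)
    tar_code <- if (plant$ref_is_target[i]) "0" else "1"
    # default is the non-target allele code, carriers get the target code
    gt[i, ] <- if (tar_code == "1") "0" else "1"
    gt[i, carriers] <- tar_code
    snp$chrom[i] <- utr$chrom
    snp$pos[i] <- pos
    snp$ref[i] <- ref
    snp$alt[i] <- alt
    snp$count_ref[i] <- if (plant$ref_is_target[i]) cnt else
      cf$n_lines - cnt
    snp$count_alt[i] <- cf$n_lines - snp$count_ref[i]
    outgroup$chrom[i] <- utr$chrom
    outgroup$pos[i] <- pos
    outgroup$base[i] <- if (plant$mispolarized[i])
      plant$target_allele[i] else plant$nontarget_allele[i]
  }
  ord <- order(snp$chrom, snp$pos)
  plant <- plant[ord, , drop = FALSE]
  snp <- snp[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  outgroup <- outgroup[ord, , drop = FALSE]
  row.names(plant) <- row.names(snp) <- row.names(outgroup) <- NULL

  # --- ground-truth site table (full enumeration) -----------------------
  truth <- list()
  for (i in seq_len(n_snp)) {
    u <- plant$utr[i]
    utr <- utrs[u, ]
    off <- plant$snp_offset[i]
    a_ref <- if (plant$ref_is_target[i]) plant$target_allele[i] else
      plant$nontarget_allele[i]
    a_alt <- if (plant$ref_is_target[i]) plant$nontarget_allele[i] else
      plant$target_allele[i]
    for (k in seq_len(cf$n_mirs)) {
      cls <- truth_classify(utr$sequence, off, a_ref, a_alt, targets[k])
      if (is.null(cls)) next
      n_tar <- if (cls$target_allele == a_ref) snp$count_ref[i] else
        snp$count_alt[i]
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = utr$transcript_id, gene_id = utr$gene_id,
        chrom = snp$chrom[i], pos = snp$pos[i], strand = utr$strand,
        seed_target = targets[k], window_offset = cls$window_offset,
        target_allele = cls$target_allele,
        nontarget_allele = cls$nontarget_allele,
        n_target = n_tar, n_nontarget = cf$n_lines - n_tar,
        p = n_tar / cf$n_lines, maternal = utr$maternal,
        stringsAsFactors = FALSE
      )
    }
  }
  truth_sites <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(transcript_id = character(0), gene_id = character(0),
               chrom = character(0), pos = integer(0),
               strand = character(0), seed_target = character(0),
               window_offset = integer(0), target_allele = character(0),
               nontarget_allele = character(0), n_target = integer(0),
               n_nontarget = integer(0), p = numeric(0),
               maternal = logical(0), stringsAsFactors = FALSE)
  }
  truth_sites <- truth_sites[order(truth_sites$chrom, truth_sites$pos,
                                   truth_sites$seed_target), ,
                             drop = FALSE]
  row.names(truth_sites) <- NULL

  # true derived (target) allele frequencies of the focal planted sites
  truth_daf <- data.frame(
    chrom = snp$chrom, pos = snp$pos,
    seed_target = targets[plant$mir],
    maternal = utrs$maternal[plant$utr],
    daf = plant$n_target / cf$n_lines,
    stringsAsFactors = FALSE
  )

  # --- labels -----------------------------------------------------------
  maternal_labels <- data.frame(transcript_id = utrs$transcript_id,
                                maternal = as.integer(utrs$maternal),
                                stringsAsFactors = FALSE)
  mat_idx <- which(utrs$maternal)
  rate <- rep(cf$unstable_rate, length(mat_idx))
  if (length(cf$enriched_seeds) > 0) {
    for (tg in names(cf$enriched_seeds)) {
      hit <- vapply(utrs$sequence[mat_idx],
                    function(s) grepl(tg, s, fixed = TRUE), logical(1))
      rate[hit] <- pmin(1, rate[hit] * cf$enriched_seeds[[tg]])
    }
  }
  stability <- data.frame(
    transcript_id = utrs$transcript_id[mat_idx],
    unstable = stats::rbinom(length(mat_idx), 1, rate),
    stringsAsFactors = FALSE
  )

  structure(list(config = cf, mirs = mirs, seeds = seeds, utrs = utrs,
                 snps = snp, gt = gt, outgroup = outgroup,
                 maternal_labels = maternal_labels, stability = stability,
                 truth_sites = truth_sites, truth_daf = truth_daf,
                 planted = plant),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits a genome FASTA, a UTR BED6, a VCF (v4.2, one haploid GT column per
#' line), mature microRNA FASTA and read-count TSV, maternal and stability
#' label TSVs, a sense-oriented outgroup allele TSV, and the ground-truth
#' tables.
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    utr_bed = file.path(out_dir, "utrs.bed"),
    vcf = file.path(out_dir, "snps.vcf.gz"),
    mir_fasta = file.path(out_dir, "mirs.fa"),
    mir_counts = file.path(out_dir, "mir_counts.tsv"),
    maternal_labels = file.path(out_dir, "maternal_labels.tsv"),
    stability = file.path(out_dir, "stability_labels.tsv"),
    outgroup = file.path(out_dir, "outgroup.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    truth_daf = file.path(out_dir, "truth_daf.tsv")
  )

  # genome: pad each UTR with fixed-length flanks of A so coordinates are
  # reproducible from the sense sequence alone
  utrs <- ds$utrs
  chrom_len <- utrs$end + 50L
  genome <- vapply(seq_len(nrow(utrs)), function(i) {
    body <- utrs$sequence[i]
    if (utrs$strand[i] == "-") body <- dna_revcomp(body)
    paste0(strrep("A", utrs$start[i]), body,
           strrep("A", chrom_len[i] - utrs$end[i]))
  }, character(1))
  gset <- Biostrings::DNAStringSet(genome)
  names(gset) <- utrs$chrom
  Biostrings::writeXStringSet(gset, paths["genome"])

  bed <- data.frame(utrs$chrom, utrs$start, utrs$end,
                    paste0(utrs$transcript_id, "|", utrs$gene_id),
                    0L, utrs$strand)
  utils::write.table(bed, paths["utr_bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # VCF via vcfR
  n_snp <- nrow(ds$snps)
  line_names <- sprintf("line_%03d", seq_len(ds$config$n_lines))
  fix <- cbind(CHROM = ds$snps$chrom, POS = as.character(ds$snps$pos),
               ID = paste0("snp", seq_len(n_snp)), REF = ds$snps$ref,
               ALT = ds$snps$alt, QUAL = ".", FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = rep("GT", n_snp), ds$gt)
  colnames(gt) <- c("FORMAT", line_names)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            sprintf("##contig=<ID=%s,length=%d>", utrs$chrom, chrom_len))
  if (n_snp > 0) {
    vcf <- methods::new(methods::getClass("vcfR",
                                          where = getNamespace("vcfR")),
                        meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(vcf, file = paths["vcf"])
  } else {  # header-only VCF (vcfR cannot serialize zero records)
    con <- gzfile(paths["vcf"], "w")
    writeLines(c(meta, paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                               "QUAL", "FILTER", "INFO", "FORMAT",
                               line_names), collapse = "\t")), con)
    close(con)
  }

  mir_set <- Biostrings::RNAStringSet(ds$mirs$sequence)
  names(mir_set) <- ds$mirs$name
  Biostrings::writeXStringSet(mir_set, paths["mir_fasta"])
  utils::write.table(ds$mirs[, c("name", "read_count")],
                     paths["mir_counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$maternal_labels, paths["maternal_labels"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$stability, paths["stability"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$outgroup, paths["outgroup"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth_sites, paths["truth_sites"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth_daf, paths["truth_daf"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
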