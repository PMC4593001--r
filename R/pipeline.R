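#' Read a pipeline configuration
#'
#' @param config a named list, or the path to a YAML file with the same
#'   keys (input paths, thresholds, miRNA name lists, output directory).
#' @return named list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

# header comment carried by every output table (timestamp-free so reruns
# are byte-identical)
provenance_line <- function() {
  paste0("# miravoid ",
         as.character(utils::packageVersion("miravoid")))
}

write_report_tsv <- function(df, path) {
  writeLines(provenance_line(), path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, append = TRUE)
  )
  path
}

#' Default maternal / nonmaternal mature microRNA name lists
#'
#' The mature products used by default to split the derived-allele-frequency
#' analysis: maternal = highly abundant in unfertilized eggs, nonmaternal =
#' not detected in the egg nor in other tissues. Both lists are ordinary
#' character vectors and can be replaced in any pipeline configuration.
#'
#' @return list with elements `maternal` (22 names) and `nonmaternal`
#'   (10 names).
#' @export
default_daf_mir_lists <- function() {
  list(
    maternal = c("bantam-3p", "mir-1010-3p", "mir-10-5p", "mir-11-3p",
                 "mir-14-3p", "mir-184-3p", "mir-263a-5p", "mir-276a-3p",
                 "mir-279-3p", "mir-281-2-5p", "mir-305-3p", "mir-305-5p",
                 "mir-306-5p", "mir-313-5p", "mir-318-3p", "mir-31a-5p",
                 "mir-33-5p", "mir-8-3p", "mir-956-3p", "mir-995-3p",
                 "mir-999-3p", "mir-9c-5p"),
    nonmaternal = c("mir-3644-5p", "mir-4941-3p", "mir-4944-3p",
                    "mir-4944-5p", "mir-4963-5p", "mir-4967-5p",
                    "mir-4972-3p", "mir-4979-5p", "mir-4982-3p",
                    "mir-4985-3p")
  )
}

# read a mature miRNA FASTA (RNA or DNA alphabet) into a name/sequence df
read_mature_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  data.frame(name = sub("\\s.*$", "", names(set)),
             sequence = as.character(set), stringsAsFactors = FALSE)
}

#' Read-profiling report: clusters, percentages, abundance classes
#'
#' Aggregates precursor read counts into genomic clusters (single linkage,
#' `cluster_gap` default 10 kb), reports each cluster's total as a
#' percentage of all microRNA-mapped reads, and classifies per-miRNA egg
#' abundance.
#'
#' @param config list (or YAML path) with keys `mir_counts` (TSV: name,
#'   read_count or name, count), optional `mir_loci` (BED6 of precursor
#'   loci), optional `cluster_gap` (default 10000), `out_dir`.
#' @return invisibly, a list with `clusters` (cluster/members/total/percent)
#'   and `mirs` (per-miRNA count/percent/class); written to
#'   `targets_summary.tsv` and `mir_classes.tsv` under `out_dir` when
#'   `out_dir` is given.
#' @export
run_targets <- function(config) {
  cf <- read_pipeline_config(config)
  counts <- utils::read.table(cf$mir_counts, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  names(counts)[1:2] <- c("name", "read_count")
  if (nrow(counts) == 0) stop("empty read-count table: ", cf$mir_counts)
  total <- sum(counts$read_count)
  if (total <= 0) stop("no mapped reads in: ", cf$mir_counts)
  mirs <- counts
  if (!is.null(cf$mir_loci)) {
    bed <- utils::read.table(cf$mir_loci, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    mirs$chrom <- bed[[1]][match(mirs$name, bed[[4]])]
    mirs$start <- bed[[2]][match(mirs$name, bed[[4]])]
  } else {
    # no loci: every precursor is its own cluster
    mirs$chrom <- mirs$name
    mirs$start <- 0L
  }
  clusters <- aggregate_clusters(mirs, max_gap = cf$cluster_gap %||% 10000)
  clusters$percent <- percent_of_total(clusters$total, total)
  per_mir <- data.frame(
    name = mirs$name, read_count = mirs$read_count,
    percent = percent_of_total(mirs$read_count, total),
    abundance_class = classify_abundance(mirs$read_count, total),
    stringsAsFactors = FALSE
  )
  if (!is.null(cf$out_dir)) {
    if (!dir.exists(cf$out_dir)) dir.create(cf$out_dir, recursive = TRUE)
    write_report_tsv(clusters, file.path(cf$out_dir,
                                         "targets_summary.tsv"))
    write_report_tsv(per_mir, file.path(cf$out_dir, "mir_classes.tsv"))
  }
  invisible(list(clusters = clusters, mirs = per_mir, total = total))
}

#' Selection analysis: site table, per-seed statistics, DAF report
#'
#' Runs the population-genetic stages: maps SNPs onto 3' UTRs, builds the
#' polymorphic target-site table, computes per-seed avoidance,
#' conservation and the one-sided KS left-shift test (maternal vs zygotic
#' transcripts), and - when an outgroup table is available - polarizes
#' sites to derived allele frequencies, compares maternal vs nonmaternal
#' microRNA DAF distributions and tests for singleton excess.
#'
#' @param config list (or YAML path) with keys `utr_bed`, `genome_fasta`,
#'   `maternal_labels`, `vcf`, `mir_fasta`, optional `mir_counts`,
#'   optional `outgroup`, optional `maternal_mirs`/`nonmaternal_mirs`
#'   (name vectors for the DAF split; default [default_daf_mir_lists()]),
#'   thresholds `low_thr` (0.1), `high_thr` (0.9), `min_lines` (20), and
#'   optional `out_dir`.
#' @return invisibly, a list with `sites`, `stats` (per-seed), `daf`
#'   (polarized table or NULL) and `daf_summary`; TSV/JSON reports are
#'   written under `out_dir` when given.
#' @export
run_selection <- function(config) {
  cf <- read_pipeline_config(config)
  mature <- read_mature_fasta(cf$mir_fasta)
  seeds <- extract_seed(mature$name, mature$sequence)
  utrs <- load_utrs(cf$utr_bed, cf$genome_fasta, cf$maternal_labels)
  snps <- load_snps(cf$vcf, min_lines = cf$min_lines %||% 20)
  message("loaded ", nrow(utrs), " UTRs, ", nrow(snps), " SNPs, ",
          nrow(seeds), " mature miRNAs")
  sites <- build_site_table(utrs, snps, seeds)
  message("site table: ", nrow(sites), " polymorphic target sites")

  low_thr <- cf$low_thr %||% 0.1
  high_thr <- cf$high_thr %||% 0.9
  classes <- NULL
  if (!is.null(cf$mir_counts)) {
    counts <- utils::read.table(cf$mir_counts, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    names(counts)[1:2] <- c("name", "read_count")
    cls <- classify_abundance(counts$read_count, sum(counts$read_count))
    classes <- stats::setNames(cls, counts$name)
  }
  stats_rows <- lapply(unique(seeds$target), function(tg) {
    sub <- sites[sites$seed_target == tg, , drop = FALSE]
    mat <- sub$p[sub$maternal]
    zyg <- sub$p[!sub$maternal]
    av <- target_avoidance(mat, zyg, low_thr)
    cv <- target_conservation(mat, zyg, high_thr)
    ks <- if (length(mat) > 0 && length(zyg) > 0) {
      ks_left_shift(mat, zyg)
    } else {
      list(d_plus = NA_real_, p_value = NA_real_)
    }
    mir_names <- sort(seeds$mir_name[seeds$target == tg])
    cls <- if (is.null(classes)) NA_character_ else {
      # a family's class is its most abundant member's class
      lv <- c("NULL", "LOW", "MID", "HIGH")
      lv[max(match(classes[mir_names], lv), na.rm = TRUE)]
    }
    data.frame(seed_target = tg,
               mirs = paste(mir_names, collapse = ";"),
               n_maternal = length(mat), n_zygotic = length(zyg),
               n_low_maternal = av$n_low_maternal,
               n_low_zygotic = av$n_low_zygotic,
               avoidance = av$avoidance,
               n_high_maternal = cv$n_high_maternal,
               n_high_zygotic = cv$n_high_zygotic,
               conservation = cv$conservation,
               ks_d_plus = ks$d_plus, ks_p = ks$p_value,
               abundance_class = cls, stringsAsFactors = FALSE)
  })
  seed_stats <- do.call(rbind, stats_rows)

  daf <- NULL
  daf_summary <- NULL
  if (!is.null(cf$outgroup) && file.exists(cf$outgroup)) {
    og <- utils::read.table(cf$outgroup, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    daf <- polarize(sites, og)
    lists <- default_daf_mir_lists()
    mat_mirs <- cf$maternal_mirs %||% lists$maternal
    non_mirs <- cf$nonmaternal_mirs %||% lists$nonmaternal
    mat_targets <- unique(seeds$target[seeds$mir_name %in% mat_mirs])
    non_targets <- unique(seeds$target[seeds$mir_name %in% non_mirs])
    # DAF is read in maternal transcripts only
    dm <- daf[daf$maternal & daf$seed_target %in% mat_targets, ,
              drop = FALSE]
    dn <- daf[daf$maternal & daf$seed_target %in% non_targets, ,
              drop = FALSE]
    if (nrow(dm) > 0 && nrow(dn) > 0) {
      sing <- tryCatch(singleton_excess(dm, dn), error = function(e) NULL)
      daf_summary <- list(
        n_maternal = nrow(dm), n_nonmaternal = nrow(dn),
        mean_daf_maternal = mean(dm$daf),
        mean_daf_nonmaternal = mean(dn$daf),
        ks_p_two_sided = daf_compare(dm$daf, dn$daf),
        ks_p_left_shift = daf_compare(dm$daf, dn$daf, "left_shift"),
        singleton = sing
      )
    } else {
      warning("DAF split produced an empty group; DAF comparison skipped")
    }
  } else if (!is.null(cf$outgroup)) {
    warning("outgroup file not found; DAF stage skipped")
  }

  if (!is.null(cf$out_dir)) {
    if (!dir.exists(cf$out_dir)) dir.create(cf$out_dir, recursive = TRUE)
    write_report_tsv(sites, file.path(cf$out_dir, "site_table.tsv"))
    write_report_tsv(seed_stats, file.path(cf$out_dir, "seed_stats.tsv"))
    if (!is.null(daf)) {
      write_report_tsv(daf, file.path(cf$out_dir, "daf_table.tsv"))
    }
    if (!is.null(daf_summary)) {
      jsonlite::write_json(daf_summary,
                           file.path(cf$out_dir, "daf_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(list(sites = sites, stats = seed_stats, daf = daf,
                 daf_summary = daf_summary))
}

#' MZT destabilization enrichment report
#'
#' Per seed family, tests whether targeted maternal transcripts are
#' enriched for transcripts destabilized across the maternal-to-zygotic
#' transition (upper-tail binomial against `p0`, BH FDR across families).
#'
#' @param config list (or YAML path) with keys `utr_bed`, `genome_fasta`,
#'   `maternal_labels`, `stability_labels`, `mir_fasta`, optional `p0`
#'   (default: estimated from the labels), optional `out_dir`.
#' @return invisibly, the enrichment data.frame (see
#'   [mzt_enrichment_table()]); written to `mzt_enrichment.tsv` under
#'   `out_dir` when given.
#' @export
run_mzt <- function(config) {
  cf <- read_pipeline_config(config)
  mature <- read_mature_fasta(cf$mir_fasta)
  seeds <- extract_seed(mature$name, mature$sequence)
  families <- collapse_seed_families(seeds)
  utrs <- load_utrs(cf$utr_bed, cf$genome_fasta, cf$maternal_labels)
  utrs <- utrs[utrs$maternal, , drop = FALSE]
  utr_seqs <- stats::setNames(utrs$sequence, utrs$transcript_id)
  stability <- utils::read.table(cf$stability_labels, sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  tab <- mzt_enrichment_table(families, utr_seqs, stability,
                              p0 = cf$p0 %||% NULL)
  if (!is.null(cf$out_dir)) {
    if (!dir.exists(cf$out_dir)) dir.create(cf$out_dir, recursive = TRUE)
    write_report_tsv(tab, file.path(cf$out_dir, "mzt_enrichment.tsv"))
  }
  invisible(tab)
}

#' Overlap of the top N entries of two ranked name lists
#'
#' @param list_a,list_b ranked character vectors (most abundant first).
#' @param n number of top entries to compare (`n <=` both lengths).
#' @param universe optional universe size for a hypergeometric enrichment
#'   p-value of the overlap.
#' @return list: `overlap`, `percent` (of `n`, 1 decimal), and `p_value`
#'   (NULL unless `universe` is given).
#' @export
top_n_overlap <- function(list_a, list_b, n, universe = NULL) {
  if (n > length(list_a) || n > length(list_b)) {
    stop("n exceeds the length of a ranked list")
  }
  k <- length(intersect(list_a[seq_len(n)], list_b[seq_len(n)]))
  p <- NULL
  if (!is.null(universe)) {
    p <- stats::phyper(k - 1, n, universe - n, n, lower.tail = FALSE)
  }
  list(overlap = k, percent = round_half_away(100 * k / n, 1), p_value = p)
}
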