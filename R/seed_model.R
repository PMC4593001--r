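#' Extract canonical seeds and DNA target sixmers from mature microRNAs
#'
#' The canonical seed of a mature microRNA is nucleotides 2-7 of the mature
#' sequence. Its target site is the DNA sixmer in a 3' UTR (sense strand)
#' exactly complementary to the seed, i.e. the reverse complement of the seed
#' with U written as T.
#'
#' @param name character vector of mature miRNA names (e.g. "mir-14-3p").
#' @param sequence character vector of mature sequences, 5' to 3', RNA or DNA
#'   alphabet (T is converted to U). Must be at least 7 nt long.
#' @return data.frame with columns `mir_name`, `seed` (RNA sixmer, positions
#'   2-7) and `target` (DNA sixmer, reverse complement of the seed).
#' @examples
#' extract_seed("mir-14-3p", "UCAGUCUUUUUCUCUCUCCUAU")
#' @export
extract_seed <- function(name, sequence) {
  stopifnot(length(name) == length(sequence))
  seq <- normalize_rna(sequence)
  short <- nchar(seq) < 7
  if (any(short)) {
    stop("mature sequence shorter than 7 nt for: ",
         paste(name[short], collapse = ", "))
  }
  seed <- substr(seq, 2, 7)
  target <- dna_revcomp(chartr("U", "T", seed))
  data.frame(mir_name = as.character(name), seed = seed, target = target,
             stringsAsFactors = FALSE)
}

#' The 18 one-nucleotide mutant neighbors of a target sixmer
#'
#' Every sixmer over ACGT has exactly 6 x 3 = 18 single-substitution variants;
#' these are the non-target neighbor alleles of the mutation model.
#'
#' @param target a single DNA sixmer (ACGT).
#' @return character vector of the 18 neighbor sixmers (target excluded),
#'   ordered by mutated position then substituted base.
#' @export
mutant_neighbors <- function(target) {
  stopifnot(length(target) == 1L, nchar(target) == 6L)
  check_dna(target, "target sixmer")
  bases <- strsplit(target, "")[[1]]
  out <- character(18L)
  k <- 0L
  for (i in 1:6) {
    for (b in setdiff(DNA_BASES, bases[i])) {
      k <- k + 1L
      v <- bases
      v[i] <- b
      out[k] <- paste(v, collapse = "")
    }
  }
  out
}

#' Scan a UTR sequence for exact target-sixmer occurrences
#'
#' @param utr_sequence a single DNA sequence in transcript (sense)
#'   orientation.
#' @param target a DNA sixmer (or a row of [extract_seed()] output, in which
#'   case its `target` column is used).
#' @return sorted integer vector of 0-based offsets of every occurrence;
#'   overlapping occurrences are all reported. Empty integer vector when
#'   there is no hit.
#' @export
scan_targets <- function(utr_sequence, target) {
  if (is.data.frame(target)) target <- target$target
  stopifnot(length(utr_sequence) == 1L, length(target) == 1L)
  if (nchar(utr_sequence) < nchar(target)) return(integer(0))
  hits <- Biostrings::matchPattern(target,
                                   Biostrings::DNAString(utr_sequence))
  sort(Biostrings::start(hits) - 1L)
}

#' Group mature microRNAs into seed families
#'
#' Mature products sharing positions 2-7 (hence the same target sixmer) form
#' one family and one row of any per-seed analysis.
#'
#' @param seeds data.frame from [extract_seed()].
#' @return data.frame with columns `target`, `members` (member mature names,
#'   sorted, ";"-joined) and `n_members`, one row per distinct target sixmer.
#' @export
collapse_seed_families <- function(seeds) {
  stopifnot(all(c("mir_name", "target") %in% names(seeds)))
  fam <- split(seeds$mir_name, seeds$target)
  data.frame(
    target = names(fam),
    members = vapply(fam, function(m) paste(sort(unique(m)), collapse = ";"),
                     character(1)),
    n_members = vapply(fam, function(m) length(unique(m)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Aggregate microRNA precursors into genomic clusters
#'
#' Single-linkage grouping of precursor loci on the same chromosome whose
#' start coordinates lie less than `max_gap` apart, summing member read
#' counts, as in read-profiling tables that report clustered loci together.
#'
#' @param mirs data.frame with columns `name`, `chrom`, `start`,
#'   `read_count`.
#' @param max_gap maximum inter-start distance (bp) joining two precursors
#'   into one cluster (default 10 kb).
#' @return data.frame with one row per cluster: `cluster` (member names
#'   joined with "/"), `n_members`, `total` (summed read counts).
#' @export
aggregate_clusters <- function(mirs, max_gap = 10000) {
  stopifnot(all(c("name", "chrom", "start", "read_count") %in% names(mirs)))
  ord <- order(mirs$chrom, mirs$start)
  m <- mirs[ord, , drop = FALSE]
  n <- nrow(m)
  if (n == 0L) {
    return(data.frame(cluster = character(0), n_members = integer(0),
                      total = integer(0), stringsAsFactors = FALSE))
  }
  new_cluster <- c(TRUE, m$chrom[-1] != m$chrom[-n] |
                     (m$start[-1] - m$start[-n]) >= max_gap)
  id <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_len(n), id), function(i) {
    data.frame(cluster = paste(m$name[i], collapse = "/"),
               n_members = length(i),
               total = sum(m$read_count[i]),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Percentage of a read-count total, rounded to one decimal
#'
#' @param count non-negative integer count.
#' @param total positive total; `count <= total`.
#' @return `100 * count / total`, rounded half away from zero to one decimal.
#' @export
percent_of_total <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(count < 0) || any(count > total)) {
    stop("count must lie in [0, total]")
  }
  round_half_away(100 * count / total, 1)
}

#' Classify microRNA abundance in the egg
#'
#' Classes follow the read-fraction thresholds used for the egg profiling
#' set: `NULL` not detected, `LOW` below 0.1% of the set, `MID` 0.1-1%,
#' `HIGH` above 1%. Boundaries are half-open: exactly 0.1% is MID, exactly
#' 1% is HIGH.
#'
#' @param count read count(s).
#' @param total total microRNA-associated reads (> 0).
#' @return character vector in `c("NULL", "LOW", "MID", "HIGH")`.
#' @export
classify_abundance <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0")
  f <- count / total
  ifelse(count == 0, "NULL",
         ifelse(f < 0.001, "LOW",
                ifelse(f < 0.01, "MID", "HIGH")))
}
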