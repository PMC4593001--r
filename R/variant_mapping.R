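#' Load 3' UTR records from BED + genome FASTA (+ maternal labels)
#'
#' Reads a BED6/BED12 file of 3' UTR intervals and extracts each UTR's
#' sequence from the genome FASTA, stored in transcript (sense) orientation:
#' minus-strand UTRs are the reverse complement of the genomic slice. UTRs
#' with more than one block (i.e. containing introns) are discarded. A label
#' table marks maternally deposited transcripts; transcripts absent from the
#' table are treated as zygotic.
#'
#' @param bed_path BED6 or BED12 file; column 4 is the transcript id
#'   (optionally "transcript|gene"), column 10 (if present) the block count.
#' @param fasta_path genome FASTA whose names are the BED chromosomes.
#' @param labels_path optional TSV with header columns `transcript_id` and
#'   `maternal` (0/1).
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `exon_count`, `sequence`
#'   (sense orientation), `maternal` (logical). Multi-exon records are
#'   removed (with a message).
#' @export
load_utrs <- function(bed_path, fasta_path, labels_path = NULL) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("BED file must have at least 6 columns")
  exon_count <- if (ncol(bed) >= 10) as.integer(bed[[10]]) else 1L
  ids <- strsplit(as.character(bed[[4]]), "|", fixed = TRUE)
  utrs <- data.frame(
    transcript_id = vapply(ids, `[`, character(1), 1L),
    gene_id = vapply(ids, function(x) x[min(2L, length(x))], character(1)),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    strand = as.character(bed[[6]]),
    exon_count = exon_count,
    stringsAsFactors = FALSE
  )
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(utrs$chrom), names(genome))
  if (length(missing) > 0) {
    stop("chromosome(s) in BED missing from FASTA: ",
         paste(missing, collapse = ", "))
  }
  too_long <- utrs$end > Biostrings::width(genome)[match(utrs$chrom,
                                                         names(genome))]
  if (any(too_long)) {
    stop("UTR interval extends beyond chromosome end for: ",
         paste(utrs$transcript_id[too_long], collapse = ", "))
  }
  multi <- utrs$exon_count > 1L
  if (any(multi)) {
    message("dropping ", sum(multi),
            " UTR(s) with introns (exon_count > 1)")
    utrs <- utrs[!multi, , drop = FALSE]
  }
  slice <- Biostrings::subseq(genome[utrs$chrom], start = utrs$start + 1L,
                              end = utrs$end)
  minus <- utrs$strand == "-"
  slice[minus] <- Biostrings::reverseComplement(slice[minus])
  utrs$sequence <- as.character(slice)
  utrs$maternal <- FALSE
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    mat_ids <- lab$transcript_id[lab$maternal == 1]
    utrs$maternal <- utrs$transcript_id %in% mat_ids
  }
  row.names(utrs) <- NULL
  utrs
}

#' Load biallelic SNPs with allele counts from a VCF
#'
#' Reads a VCF (v4.x) of a panel of inbred lines, keeps biallelic
#' single-nucleotide records, and counts one allele per line (the first GT
#' allele; inbred isogenic lines carry one allele each). Missing genotypes
#' are excluded from both counts; records genotyped in fewer than
#' `min_lines` lines are dropped.
#'
#' @param vcf_path path to a VCF or bgzipped VCF.
#' @param min_lines minimum number of genotyped lines per site (default 20).
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `count_ref`, `count_alt`, `n_lines` (number of genotype columns).
#' @export
load_snps <- function(vcf_path, min_lines = 20) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  # one allele per inbred line: first GT allele
  first_allele <- substr(gt, 1L, 1L)
  count_ref <- rowSums(first_allele == "0", na.rm = TRUE)
  count_alt <- rowSums(first_allele == "1", na.rm = TRUE)
  snps <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    count_ref = as.integer(count_ref),
    count_alt = as.integer(count_alt),
    n_lines = ncol(gt),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  snps <- snps[snps$count_ref + snps$count_alt >= min_lines, , drop = FALSE]
  row.names(snps) <- NULL
  snps
}

#' Project a genomic SNP onto UTR (sense) coordinates
#'
#' @param utr one row of [load_utrs()] output (data.frame or list).
#' @param pos 1-based genomic position of the SNP.
#' @param ref,alt single-base genomic alleles.
#' @return `NULL` if the position falls outside the UTR; otherwise a list
#'   with `offset` (0-based offset in the sense sequence) and `ref`, `alt`
#'   expressed on the sense strand (complemented for minus-strand UTRs).
#'   Errors if the UTR sense base at the offset differs from the sense
#'   reference allele.
#' @export
snp_to_utr <- function(utr, pos, ref, alt) {
  if (pos < utr$start + 1L || pos > utr$end) return(NULL)
  if (utr$strand == "-") {
    offset <- utr$end - pos
    ref <- dna_complement(ref)
    alt <- dna_complement(alt)
  } else {
    offset <- pos - 1L - utr$start
  }
  have <- substr(utr$sequence, offset + 1L, offset + 1L)
  if (have != ref) {
    stop("reference mismatch in ", utr$transcript_id, " at offset ", offset,
         ": UTR has ", have, ", VCF REF (sense) is ", ref)
  }
  list(offset = offset, ref = ref, alt = alt)
}

#' Classify one SNP against one seed target
#'
#' Examines each of the (up to 6) sixmer windows of the UTR covering the SNP
#' offset, substituting each allele in turn. A polymorphic target site is
#' emitted iff exactly one allele version of a window equals the target
#' sixmer (the other allele is then necessarily a one-nucleotide non-target
#' neighbor). When several windows qualify for the same (SNP, seed) pair,
#' only the leftmost is kept.
#'
#' @param utr_sequence UTR sense sequence.
#' @param offset 0-based SNP offset in the sense sequence.
#' @param a1,a2 the two sense alleles (single bases).
#' @param target target DNA sixmer.
#' @return `NULL` if no window qualifies, else a list with `window_offset`,
#'   `target_allele`, `nontarget_allele`.
#' @export
classify_site <- function(utr_sequence, offset, a1, a2, target) {
  len <- nchar(utr_sequence)
  lo <- max(0L, offset - 5L)
  hi <- min(offset, len - 6L)
  if (hi < lo) return(NULL)
  for (w in lo:hi) {
    win <- substr(utr_sequence, w + 1L, w + 6L)
    j <- offset - w + 1L
    w1 <- win; substr(w1, j, j) <- a1
    w2 <- win; substr(w2, j, j) <- a2
    hit1 <- w1 == target
    hit2 <- w2 == target
    if (xor(hit1, hit2)) {
      return(list(window_offset = w,
                  target_allele = if (hit1) a1 else a2,
                  nontarget_allele = if (hit1) a2 else a1))
    }
  }
  NULL
}

#' Build the polymorphic target-site table
#'
#' Crosses every UTR x SNP x seed combination, classifying each SNP against
#' each seed target with [classify_site()] and computing the target-allele
#' frequency `p` over genotyped lines. Duplicate genomic sites shared by
#' transcript isoforms are collapsed to one record per (chrom, pos, seed
#' target), keeping the maternal flag if any carrying transcript is
#' maternal.
#'
#' @param utrs data.frame from [load_utrs()].
#' @param snps data.frame from [load_snps()].
#' @param seeds data.frame from [extract_seed()] (or any data.frame with a
#'   `target` column of distinct DNA sixmers).
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `pos`, `strand`, `seed_target`, `window_offset`, `target_allele`,
#'   `nontarget_allele`, `n_target`, `n_nontarget`, `p`, `maternal`, sorted
#'   by (chrom, pos, seed_target).
#' @export
build_site_table <- function(utrs, snps, seeds) {
  targets <- unique(seeds$target)
  rows <- vector("list", 0L)
  for (u in seq_len(nrow(utrs))) {
    utr <- utrs[u, ]
    in_utr <- which(snps$chrom == utr$chrom &
                      snps$pos > utr$start & snps$pos <= utr$end)
    for (s in in_utr) {
      snp <- snps[s, ]
      proj <- snp_to_utr(utr, snp$pos, snp$ref, snp$alt)
      for (tg in targets) {
        cls <- classify_site(utr$sequence, proj$offset, proj$ref, proj$alt,
                             tg)
        if (is.null(cls)) next
        n_tar <- if (cls$target_allele == proj$ref) snp$count_ref
                 else snp$count_alt
        n_non <- if (cls$target_allele == proj$ref) snp$count_alt
                 else snp$count_ref
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = utr$transcript_id, gene_id = utr$gene_id,
          chrom = utr$chrom, pos = snp$pos, strand = utr$strand,
          seed_target = tg, window_offset = cls$window_offset,
          target_allele = cls$target_allele,
          nontarget_allele = cls$nontarget_allele,
          n_target = n_tar, n_nontarget = n_non,
          p = n_tar / (n_tar + n_non),
          maternal = utr$maternal,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), pos = integer(0), strand = character(0),
      seed_target = character(0), window_offset = integer(0),
      target_allele = character(0), nontarget_allele = character(0),
      n_target = integer(0), n_nontarget = integer(0), p = numeric(0),
      maternal = logical(0), stringsAsFactors = FALSE
    ))
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$chrom, tab$pos, tab$seed_target, sep = "\r")
  mat_any <- tapply(tab$maternal, key, any)
  tab <- tab[!duplicated(key), , drop = FALSE]
  tab$maternal <- as.logical(mat_any[paste(tab$chrom, tab$pos,
                                           tab$seed_target, sep = "\r")])
  tab <- tab[order(tab$chrom, tab$pos, tab$seed_target), , drop = FALSE]
  row.names(tab) <- NULL
  tab
}
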