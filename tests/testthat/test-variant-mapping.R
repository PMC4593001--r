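# A tiny two-chromosome fixture: one plus-strand UTR containing the
# mir-14-3p target AGACTG, one minus-strand UTR whose sense sequence also
# carries it, and one intron-containing UTR that must be dropped.
make_utr_fixture <- function(dir) {
  plus_seq <- "TTGGAGACTGCCAACCGGTTAA"          # AGACTG at sense offset 4
  minus_sense <- "AAGGAGACTGCCTTAACCGGTT"       # AGACTG at sense offset 4
  genome <- c(
    chrA = paste0(strrep("A", 10), plus_seq, strrep("A", 10)),
    chrB = paste0(strrep("C", 10), dna_revcomp(minus_sense),
                  strrep("C", 10))
  )
  fa <- write_fasta(genome, file.path(dir, "genome.fa"))
  bed <- data.frame(
    chrom = c("chrA", "chrB", "chrA"),
    start = c(10L, 10L, 0L),
    end = c(10L + nchar(plus_seq), 10L + nchar(minus_sense), 8L),
    name = c("txP|geneP", "txM|geneM", "txI|geneI"),
    score = 0L,
    strand = c("+", "-", "+"),
    thickStart = c(10L, 10L, 0L), thickEnd = c(10L, 10L, 0L),
    rgb = "0", blockCount = c(1L, 1L, 2L),
    blockSizes = c("0", "0", "3,3"), blockStarts = c("0", "0", "0,5")
  )
  bedp <- write_bed(bed, file.path(dir, "utrs.bed"))
  lab <- write_labels(data.frame(transcript_id = "txP", maternal = 1L),
                      file.path(dir, "labels.tsv"))
  list(fasta = fa, bed = bedp, labels = lab,
       plus_seq = plus_seq, minus_sense = minus_sense)
}

test_that("UTR loading is strand-aware and drops intron-containing records", {
  dir <- withr::local_tempdir()
  fx <- make_utr_fixture(dir)
  expect_message(
    utrs <- load_utrs(fx$bed, fx$fasta, fx$labels),
    "introns"
  )
  expect_equal(nrow(utrs), 2L)
  expect_false("txI" %in% utrs$transcript_id)
  expect_equal(utrs$sequence[utrs$transcript_id == "txP"], fx$plus_seq)
  # minus-strand record is stored sense-oriented
  expect_equal(utrs$sequence[utrs$transcript_id == "txM"], fx$minus_sense)
  expect_equal(utrs$gene_id, c("geneP", "geneM"))
  expect_equal(utrs$maternal, c(TRUE, FALSE))
})

test_that("UTR loading rejects inconsistent BED/FASTA pairs", {
  dir <- withr::local_tempdir()
  fx <- make_utr_fixture(dir)
  bad_bed <- write_bed(
    data.frame("chrZ", 0L, 10L, "tx|g", 0L, "+"),
    file.path(dir, "bad1.bed"))
  expect_error(load_utrs(bad_bed, fx$fasta), "missing from FASTA")
  long_bed <- write_bed(
    data.frame("chrA", 0L, 10000L, "tx|g", 0L, "+"),
    file.path(dir, "bad2.bed"))
  expect_error(load_utrs(long_bed, fx$fasta), "beyond chromosome end")
})

test_that("SNP projection onto UTR coordinates is strand-correct", {
  utr_p <- list(transcript_id = "x", start = 100L, end = 110L,
                strand = "+", sequence = "AACGTACGTA")
  expect_equal(snp_to_utr(utr_p, 103L, "C", "T"),
               list(offset = 2L, ref = "C", alt = "T"))
  # minus strand: offset flips, alleles complement
  utr_m <- list(transcript_id = "y", start = 100L, end = 110L,
                strand = "-", sequence = "GACGTACGTA")
  expect_equal(snp_to_utr(utr_m, 110L, "C", "T"),
               list(offset = 0L, ref = "G", alt = "A"))
  # outside the interval
  expect_null(snp_to_utr(utr_p, 100L, "A", "C"))
  expect_null(snp_to_utr(utr_p, 111L, "A", "C"))
  # reference mismatch is a hard error
  expect_error(snp_to_utr(utr_p, 103L, "G", "T"), "reference mismatch")
})

test_that("site classification finds the allele pair and the leftmost window", {
  cls <- classify_site("GGAGACTGCC", 5L, "C", "T", "AGACTG")
  expect_equal(cls, list(window_offset = 2L, target_allele = "C",
                         nontarget_allele = "T"))
  # argument order of the alleles does not matter
  expect_equal(classify_site("GGAGACTGCC", 5L, "T", "C", "AGACTG"), cls)
  # neither allele makes a target in any covering window
  expect_null(classify_site("GGGGGGGGGG", 5L, "A", "C", "AGACTG"))
  # several qualifying windows: the leftmost wins
  cls2 <- classify_site("AAAAAAA", 3L, "A", "C", "AAAAAA")
  expect_equal(cls2$window_offset, 0L)
  expect_equal(cls2$target_allele, "A")
})

test_that("VCF loading counts one allele per line and applies the floor", {
  dir <- withr::local_tempdir()
  fix <- data.frame(chrom = c("chrA", "chrA", "chrA", "chrA"),
                    pos = c(15L, 16L, 17L, 18L),
                    ref = c("A", "C", "G", "T"),
                    alt = c("G", "T", "GA", "A"))
  gt <- rbind(
    c("0", "0", "1", "1", "0"),          # haploid: 3 ref, 2 alt
    c("0/0", "1/1", "0/0", ".", "1/1"),  # diploid homozygous + missing
    c("0", "0", "0", "0", "0"),          # indel row: filtered on alleles
    c("0", ".", ".", ".", ".")           # only 1 genotyped line
  )
  vcf <- write_vcf_text(fix, gt, file.path(dir, "t.vcf"))
  snps <- load_snps(vcf, min_lines = 2)
  expect_equal(nrow(snps), 2L)
  expect_equal(snps$count_ref, c(3L, 2L))
  expect_equal(snps$count_alt, c(2L, 2L))
  expect_equal(snps$n_lines, c(5L, 5L))
  # the 1-line site survives only without a floor
  expect_equal(nrow(load_snps(vcf, min_lines = 1)), 3L)
})

test_that("the site table records strand-symmetric target/neighbor pairs", {
  dir <- withr::local_tempdir()
  fx <- make_utr_fixture(dir)
  suppressMessages(utrs <- load_utrs(fx$bed, fx$fasta, fx$labels))
  # SNP in txP at sense offset 7 (genomic pos 18): C->T breaks AGACTG
  # SNP in txM at sense offset 7: sense C/T = genomic G/A at pos
  # end - offset = 32 - 7 = 25
  fix <- data.frame(chrom = c("chrA", "chrB"), pos = c(18L, 25L),
                    ref = c("C", "G"), alt = c("T", "A"))
  gt <- rbind(c("0", "0", "0", "1", "1"),
              c("0", "0", "0", "0", "1"))
  vcf <- write_vcf_text(fix, gt, file.path(dir, "s.vcf"))
  snps <- load_snps(vcf, min_lines = 2)
  seeds <- extract_seed("mir-14-3p", "TCAGTCTTTTTCTCTCTCCTAT")
  sites <- build_site_table(utrs, snps, seeds)
  expect_equal(nrow(sites), 2L)
  p_row <- sites[sites$transcript_id == "txP", ]
  m_row <- sites[sites$transcript_id == "txM", ]
  # both strands classify identically in sense space
  expect_equal(p_row$window_offset, 4L)
  expect_equal(m_row$window_offset, 4L)
  expect_equal(p_row$target_allele, "C")
  expect_equal(m_row$target_allele, "C")
  expect_equal(p_row$p, 3 / 5)
  expect_equal(m_row$p, 4 / 5)
  expect_true(p_row$maternal)
  expect_false(m_row$maternal)
})

test_that("swapping which allele is REF inverts the frequency", {
  dir <- withr::local_tempdir()
  fx <- make_utr_fixture(dir)
  suppressMessages(utrs <- load_utrs(fx$bed, fx$fasta, fx$labels))
  seeds <- extract_seed("mir-14-3p", "TCAGTCTTTTTCTCTCTCCTAT")
  # same site, REF = target allele C
  fix1 <- data.frame(chrom = "chrA", pos = 18L, ref = "C", alt = "T")
  gt1 <- matrix(c("0", "0", "0", "1", "1"), nrow = 1)
  s1 <- load_snps(write_vcf_text(fix1, gt1, file.path(dir, "a.vcf")),
                  min_lines = 2)
  t1 <- build_site_table(utrs, s1, seeds)
  expect_equal(t1$p, 3 / 5)
  # mutate the genome so REF is the non-target allele T instead
  g2 <- c(chrA = sub("GGAGACTGCC", "GGAGATTGCC",
                     paste0(strrep("A", 10), fx$plus_seq,
                            strrep("A", 10))))
  fa2 <- write_fasta(g2, file.path(dir, "g2.fa"))
  bed2 <- write_bed(data.frame("chrA", 10L, 10L + nchar(fx$plus_seq),
                               "txP|geneP", 0L, "+"),
                    file.path(dir, "b2.bed"))
  fix2 <- data.frame(chrom = "chrA", pos = 18L, ref = "T", alt = "C")
  gt2 <- matrix(c("1", "1", "1", "0", "0"), nrow = 1)
  s2 <- load_snps(write_vcf_text(fix2, gt2, file.path(dir, "b.vcf")),
                  min_lines = 2)
  t2 <- build_site_table(load_utrs(bed2, fa2), s2, seeds)
  expect_equal(t2$target_allele, "C")
  expect_equal(t2$p, t1$p)  # p follows the target allele, not REF
})

test_that("isoforms sharing a genomic site collapse to one record", {
  dir <- withr::local_tempdir()
  fx <- make_utr_fixture(dir)
  bed <- write_bed(data.frame(
    chrom = "chrA", start = 10L, end = 10L + nchar(fx$plus_seq),
    name = c("txP1|geneP", "txP2|geneP"), score = 0L, strand = "+"),
    file.path(dir, "iso.bed"))
  lab <- write_labels(data.frame(transcript_id = "txP2", maternal = 1L),
                      file.path(dir, "isolab.tsv"))
  utrs <- load_utrs(bed, fx$fasta, lab)
  fix <- data.frame(chrom = "chrA", pos = 18L, ref = "C", alt = "T")
  gt <- matrix(c("0", "0", "0", "1", "1"), nrow = 1)
  snps <- load_snps(write_vcf_text(fix, gt, file.path(dir, "i.vcf")),
                    min_lines = 2)
  seeds <- extract_seed("mir-14-3p", "TCAGTCTTTTTCTCTCTCCTAT")
  sites <- build_site_table(utrs, snps, seeds)
  expect_equal(nrow(sites), 1L)
  expect_true(sites$maternal)  # maternal if any carrying isoform is
  # and an empty SNP panel gives an empty, well-formed table
  empty <- build_site_table(utrs, snps[0, ], seeds)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("p", "seed_target", "maternal") %in% names(empty)))
})
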