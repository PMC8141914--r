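test_that("GTF loading preserves genes, transcripts, exons and biotypes", {
  path <- tempfile(fileext = ".gtf")
  rows <- data.frame(
    chrom = "chr1", feature = "exon",
    start = c(101, 301, 101, 301, 601),
    end = c(200, 400, 200, 400, 700),
    strand = "+",
    attrs = c(gtf_exon_attrs("G1", "G1.t1"), gtf_exon_attrs("G1", "G1.t1"),
              gtf_exon_attrs("G1", "G1.t2"), gtf_exon_attrs("G1", "G1.t2"),
              gtf_exon_attrs("G1", "G1.t2")),
    stringsAsFactors = FALSE)
  write_toy_gtf(path, rows)
  m <- load_gene_models(path)
  expect_equal(nrow(m$genes), 1L)
  expect_equal(nrow(m$transcripts), 2L)
  expect_equal(nrow(m$exons), 5L)
  expect_equal(m$genes$biotype, "protein_coding")

  # rRNA biotype string survives verbatim for the downstream exclusion
  path2 <- tempfile(fileext = ".gtf")
  write_toy_gtf(path2, data.frame(
    chrom = "chr1", feature = "exon", start = 50, end = 500, strand = "+",
    attrs = gtf_exon_attrs("GR", "GR.t1", biotype = "rRNA"),
    stringsAsFactors = FALSE))
  expect_equal(load_gene_models(path2)$genes$biotype, "rRNA")
})

test_that("empty annotation yields an empty model set, malformed lines are named", {
  empty <- tempfile(fileext = ".gtf")
  file.create(empty)
  m <- load_gene_models(empty)
  expect_s3_class(m, "GeneModelSet")
  expect_equal(nrow(m$genes), 0L)

  bad <- tempfile(fileext = ".gtf")
  writeLines(c("# comment", "chr1\texon\tonly-three"), bad)
  expect_error(load_gene_models(bad), "line 2")
})

test_that("GFF3 dialect is auto-detected and resolved through Parent links", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t700\t.\t+\t.\tID=gene:G1;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t101\t700\t.\t+\t.\tID=transcript:G1.t1;Parent=gene:G1",
    "chr1\ttoy\texon\t101\t200\t.\t+\t.\tParent=transcript:G1.t1;Name=G1.e1",
    "chr1\ttoy\texon\t301\t700\t.\t+\t.\tParent=transcript:G1.t1;Name=G1.e2"),
    path)
  m <- load_gene_models(path)
  expect_equal(nrow(m$exons), 2L)
  expect_equal(unique(m$exons$gene_id), "G1")
  expect_equal(m$genes$biotype, "protein_coding")
})

test_that("intron derivation is strand-aware and skips mono-exonic transcripts", {
  path <- tempfile(fileext = ".gtf")
  rows <- data.frame(
    chrom = "chr1", feature = "exon",
    start = c(101, 301, 101, 301, 50),
    end = c(200, 400, 200, 400, 90),
    strand = c("+", "+", "-", "-", "+"),
    attrs = c(gtf_exon_attrs("GP", "GP.t1"), gtf_exon_attrs("GP", "GP.t1"),
              gtf_exon_attrs("GM", "GM.t1"), gtf_exon_attrs("GM", "GM.t1"),
              gtf_exon_attrs("GS", "GS.t1")),
    stringsAsFactors = FALSE)
  write_toy_gtf(path, rows)
  introns <- derive_introns(load_gene_models(path))
  expect_equal(nrow(introns), 2L)
  plus <- introns[introns$strand == "+", ]
  expect_equal(c(plus$start, plus$end, plus$donor_pos, plus$acceptor_pos),
               c(201, 300, 201, 300))
  minus <- introns[introns$strand == "-", ]
  expect_equal(c(minus$start, minus$end, minus$donor_pos, minus$acceptor_pos),
               c(201, 300, 300, 201))
})

test_that("overlapping exons within a transcript are an annotation error", {
  path <- tempfile(fileext = ".gtf")
  rows <- data.frame(
    chrom = "chr1", feature = "exon", start = c(101, 150), end = c(200, 400),
    strand = "+",
    attrs = gtf_exon_attrs("G1", "G1.t1"), stringsAsFactors = FALSE)
  write_toy_gtf(path, rows)
  expect_error(derive_introns(load_gene_models(path)), "overlapping")
})

test_that("exons plus introns tile each transcript span exactly", {
  set.seed(101)
  for (rep in 1:10) {
    n_ex <- sample(2:6, 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- sample(1:1000, 1)
    for (e in seq_len(n_ex)) {
      starts[e] <- p; ends[e] <- p + sample(50:300, 1)
      p <- ends[e] + sample(2:500, 1)
    }
    path <- tempfile(fileext = ".gtf")
    write_toy_gtf(path, data.frame(
      chrom = "chr1", feature = "exon", start = starts, end = ends,
      strand = sample(c("+", "-"), 1),
      attrs = gtf_exon_attrs("G1", "G1.t1"), stringsAsFactors = FALSE))
    m <- load_gene_models(path)
    introns <- derive_introns(m)
    covered <- sort(c(unlist(Map(seq, m$exons$start, m$exons$end)),
                      unlist(Map(seq, introns$start, introns$end))))
    expect_equal(covered, seq(min(starts), max(ends)))
  }
})

test_that("interval index agrees with a linear-scan oracle on random genomes", {
  set.seed(202)
  n_feat <- 60
  starts <- sample(1:20000, n_feat)
  feats <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_feat, replace = TRUE),
    start = starts, end = starts + sample(20:2000, n_feat, replace = TRUE),
    strand = sample(c("+", "-"), n_feat, replace = TRUE),
    stringsAsFactors = FALSE)
  # one transcript per feature so exon intervals survive unmodified
  path <- tempfile(fileext = ".gtf")
  write_toy_gtf(path, data.frame(
    chrom = feats$chrom, feature = "exon", start = feats$start,
    end = feats$end, strand = feats$strand,
    attrs = sprintf('gene_id "G%03d"; transcript_id "G%03d.t1"; gene_biotype "protein_coding";',
                    seq_len(n_feat), seq_len(n_feat)),
    stringsAsFactors = FALSE))
  idx <- build_feature_index(load_gene_models(path))
  key <- function(df) sort(paste(df$chrom, df$start, df$end))
  for (q in 1:1000) {
    chrom <- sample(c("chr1", "chr2", "chrEmpty"), 1)
    qs <- sample(1:25000, 1); qe <- qs + sample(0:3000, 1)
    got <- query_overlaps(idx, chrom, qs, qe, "exon")
    want <- scan_overlaps(feats, chrom, qs, qe)
    expect_identical(key(got), key(want))
  }
})
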