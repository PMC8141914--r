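# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, from-scratch computation kept free of package code
# paths.

# TMM: doubly trimmed, precision-weighted mean of M-values, written out
# directly from the published formula.
tmm_oracle <- function(counts, lib, trim_m = 0.30, trim_a = 0.05) {
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, p = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(obs, refc, nO, nR) {
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k] / v[k]) / sum(1 / v[k]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    one(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Linear-scan overlap oracle over a plain exon/intron table.
scan_overlaps <- function(features, chrom, start, end) {
  hit <- features$chrom == chrom & features$start <= end & features$end >= start
  features[hit, , drop = FALSE]
}

# Dictionary-count clustering oracle.
cluster_oracle <- function(ccrs) {
  key <- paste(ccrs$chrom, ccrs$strand, ccrs$start, ccrs$end, sep = ":")
  tab <- sort(table(key))
  data.frame(key = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)[order(names(tab)), ]
}

# Sort-then-sweep clustering oracle for the unannotated-region scan.
sweep_clusters_oracle <- function(df, window, min_count) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]; n <- 1
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - e <= window) {
        e <- max(e, d$end[i]); n <- n + 1
      } else {
        if (n >= min_count) out[[length(out) + 1]] <- c(s, e, n)
        s <- d$start[i]; e <- d$end[i]; n <- 1
      }
    }
    if (n >= min_count) out[[length(out) + 1]] <- c(s, e, n)
  }
  do.call(rbind, out)
}

# Rolling-concatenation oracle for junction sequences: read around the
# circle far enough, then cut the window centred on the junction.
wrap_junction_oracle <- function(chrom_seq, start, end, strand, flank) {
  circle <- substr(as.character(chrom_seq), start, end)
  rolled <- paste(rep(circle, ceiling(2 * flank / nchar(circle)) + 2),
                  collapse = "")
  # junction sits between the end of one lap and the start of the next
  laps <- ceiling(flank / nchar(circle)) + 1
  cut <- laps * nchar(circle)
  fwd <- paste0(substr(rolled, cut - flank + 1, cut),
                substr(rolled, cut + 1, cut + flank))
  if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  } else fwd
}

# Small GTF writer used to build fixtures in code.
write_toy_gtf <- function(path, rows) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    paste(r$chrom, "toy", r$feature, r$start, r$end, ".", r$strand, ".",
          r$attrs, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

gtf_exon_attrs <- function(gene, tx, biotype = "protein_coding", exon = NULL) {
  a <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
               gene, tx, biotype)
  if (!is.null(exon)) a <- paste0(a, sprintf(' exon_id "%s";', exon))
  a
}

# Two-gene toy annotation shared by several classifier tests:
#   GA (+, protein_coding): exons 101-200, 301-400, 601-700
#   GB (-, protein_coding): exons 1101-1300, 1501-1600
#   GR (+, rRNA):           exon 2001-2400
toy_index <- function() {
  path <- tempfile(fileext = ".gtf")
  rows <- data.frame(
    chrom = "chr1", feature = "exon",
    start = c(101, 301, 601, 1101, 1501, 2001),
    end = c(200, 400, 700, 1300, 1600, 2400),
    strand = c("+", "+", "+", "-", "-", "+"),
    attrs = c(gtf_exon_attrs("GA", "GA.t1", exon = "GA.e1"),
              gtf_exon_attrs("GA", "GA.t1", exon = "GA.e2"),
              gtf_exon_attrs("GA", "GA.t1", exon = "GA.e3"),
              gtf_exon_attrs("GB", "GB.t1", exon = "GB.e1"),
              gtf_exon_attrs("GB", "GB.t1", exon = "GB.e2"),
              gtf_exon_attrs("GR", "GR.t1", biotype = "rRNA", exon = "GR.e1")),
    stringsAsFactors = FALSE)
  write_toy_gtf(path, rows)
  build_feature_index(load_gene_models(path))
}

cand <- function(chrom = "chr1", strand = "+", start, end) {
  data.frame(chrom = chrom, strand = strand, start = start, end = end,
             ccr_count = 5L, dataset_id = "d1",
             genomic_size = end - start + 1L, stringsAsFactors = FALSE)
}

# Minimal chimeric junction line in the classic 14-column dialect.
chim_line <- function(read, chrom1, brk1, strand1, chrom2, brk2, strand2,
                      jtype, start1, cigar1, start2, cigar2) {
  paste(chrom1, brk1, strand1, chrom2, brk2, strand2, jtype, 0, 0,
        read, start1, cigar1, start2, cigar2, sep = "\t")
}
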