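#' Simulation specification for synthetic circRNA fixtures
#'
#' Describes a toy genome (multi-exon and mono-exonic genes across
#' biotypes, an rRNA gene, intergenic space), the circRNAs to plant in a
#' chimeric junction file (class, read support, intronic acceptor
#' offset), decoy reads that must never be detected, and the read
#' geometry. All randomness flows from a single seed, so a spec fully
#' determines its fixtures.
#'
#' The defaults mirror the study conditions the package targets: 100 bp
#' reads (the dominant 2x100 sequencing), 15 bp minimal mapped segments,
#' and a gene set containing multi-exon protein-coding genes, a
#' mono-exonic ribozyme-like small non-coding gene, a lncRNA, an rRNA
#' gene and free intergenic space.
#'
#' @param seed Integer seed.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_chroms Number of chromosomes.
#' @param genes Data frame (`biotype`, `n_exons`, `strand`) describing the
#'   genes per chromosome; `NULL` for the default layout.
#' @param exon_len,intron_len Length ranges (bp) for exons and introns.
#' @param read_length Read length (bp) the planted reads emulate.
#' @param segment_len Range of reference spans for planted segments.
#' @param planted Data frame (`class`, `ccr_count`, `acceptor_offset`)
#'   listing circRNAs to plant; `NULL` for a default mixture covering all
#'   classes. Class is one of `exonic`, `sub_exonic_sense`,
#'   `sub_exonic_antisense`, `intronic`, `intergenic`, `multi_gene`,
#'   `rrna_subexonic`.
#' @param decoys Named counts of decoy reads (`linear`, `trans`,
#'   `strand`, `short`).
#' @param divergence Substitution rate for the diverged second genome.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L,
                     chrom_length = 100000L,
                     n_chroms = 1L,
                     genes = NULL,
                     exon_len = c(150L, 400L),
                     intron_len = c(300L, 800L),
                     read_length = 100L,
                     segment_len = c(20L, 80L),
                     planted = NULL,
                     decoys = c(linear = 10L, trans = 5L, strand = 5L, short = 5L),
                     divergence = 0.05) {
  if (is.null(genes)) {
    genes <- data.frame(
      biotype = c("protein_coding", "protein_coding", "lncRNA",
                  "ribozyme", "rRNA", "protein_coding"),
      n_exons = c(5L, 4L, 3L, 1L, 1L, 4L),
      strand = c("+", "-", "+", "+", "+", "+"),
      stringsAsFactors = FALSE)
  }
  if (is.null(planted)) {
    planted <- data.frame(
      class = c(rep("exonic", 10L), rep("sub_exonic_sense", 8L),
                rep("sub_exonic_antisense", 2L), rep("intronic", 4L),
                rep("intergenic", 4L), "multi_gene",
                rep("rrna_subexonic", 2L)),
      ccr_count = c(7L, 12L, 5L, 9L, 21L, 6L, 8L, 15L, 5L, 11L,
                    6L, 8L, 15L, 5L, 9L, 7L, 13L, 6L,
                    8L, 5L,
                    5L, 6L, 9L, 7L,
                    10L, 7L, 5L, 8L,
                    6L,
                    5L, 6L),
      acceptor_offset = c(rep(NA_integer_, 20L), 0L, 5L, 30L, 60L,
                          rep(NA_integer_, 7L)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(planted$ccr_count >= 1L), divergence >= 0, divergence <= 0.3)
  structure(list(seed = as.integer(seed), chrom_length = as.integer(chrom_length),
                 n_chroms = as.integer(n_chroms), genes = genes,
                 exon_len = exon_len, intron_len = intron_len,
                 read_length = as.integer(read_length),
                 segment_len = as.integer(segment_len),
                 planted = planted, decoys = decoys,
                 divergence = divergence),
            class = "sim_spec")
}

#' Generate a toy genome with annotation
#'
#' Produces a seeded random genome, places the spec's genes without
#' overlap (exons separated by introns, genes separated by intergenic
#' gaps), and writes FASTA and GTF files that round-trip through
#' [load_gene_models()].
#'
#' @param spec A [sim_spec()].
#' @param out_dir Directory for `genome.fa` and `annotation.gtf`.
#' @return List: `fasta`, `gtf` (paths), `sequences` (`DNAStringSet`),
#'   `models` (`GeneModelSet`), `layout` (per-gene exon table).
#' @export
make_genome <- function(spec, out_dir = tempfile("simgenome")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(spec$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(seqs) <- paste0("chr", seq_len(spec$n_chroms))

  rint <- function(rng) if (rng[1L] == rng[2L]) rng[1L] else sample(rng[1L]:rng[2L], 1L)
  layout <- list()
  gtf_lines <- character()
  pos <- 2000L  # leading intergenic space
  chrom <- "chr1"
  for (gi in seq_len(nrow(spec$genes))) {
    g <- spec$genes[gi, ]
    gene_id <- sprintf("G%02d", gi)
    ex_start <- integer(g$n_exons); ex_end <- integer(g$n_exons)
    p <- pos
    for (e in seq_len(g$n_exons)) {
      len <- rint(spec$exon_len)
      ex_start[e] <- p; ex_end[e] <- p + len - 1L
      p <- ex_end[e] + 1L + if (e < g$n_exons) rint(spec$intron_len) else 0L
    }
    gene_end <- ex_end[g$n_exons]
    if (gene_end > spec$chrom_length - 2000L) {
      stop("genes do not fit on the chromosome; increase chrom_length")
    }
    tx_id <- paste0(gene_id, ".t1")
    attr_core <- sprintf('gene_id "%s"; gene_biotype "%s";', gene_id, g$biotype)
    gtf_lines <- c(gtf_lines,
      paste(chrom, "sim", "gene", ex_start[1L], gene_end, ".", g$strand, ".",
            attr_core, sep = "\t"),
      paste(chrom, "sim", "transcript", ex_start[1L], gene_end, ".", g$strand,
            ".", sprintf('%s transcript_id "%s";', attr_core, tx_id), sep = "\t"),
      vapply(seq_len(g$n_exons), function(e) {
        paste(chrom, "sim", "exon", ex_start[e], ex_end[e], ".", g$strand, ".",
              sprintf('%s transcript_id "%s"; exon_id "%s.e%d";',
                      attr_core, tx_id, gene_id, e), sep = "\t")
      }, character(1)))
    layout[[gene_id]] <- data.frame(
      gene_id = gene_id, biotype = g$biotype, strand = g$strand, chrom = chrom,
      exon = seq_len(g$n_exons), start = ex_start, end = ex_end,
      stringsAsFactors = FALSE)
    pos <- gene_end + 1L + 3000L  # intergenic gap
  }
  fasta <- file.path(out_dir, "genome.fa")
  gtf <- file.path(out_dir, "annotation.gtf")
  Biostrings::writeXStringSet(seqs, fasta)
  writeLines(gtf_lines, gtf)
  models <- load_gene_models(gtf)
  list(fasta = fasta, gtf = gtf, sequences = seqs, models = models,
       layout = do.call(rbind, c(layout, list(make.row.names = FALSE))))
}

# place each planted circRNA on the genome layout; returns the truth table
place_planted_circs <- function(spec, genome) {
  lay <- genome$layout
  multi <- lay[stats::ave(lay$exon, lay$gene_id, FUN = max) >= 2L, , drop = FALSE]
  multi_genes <- unique(multi$gene_id[!(multi$biotype %in% "rRNA")])
  mono_snc <- unique(lay$gene_id[lay$biotype %in% c("ribozyme", "snoRNA", "misc_RNA")])
  rrna_genes <- unique(lay$gene_id[lay$biotype == "rRNA"])
  chrom_len <- spec$chrom_length
  gene_max <- max(lay$end)

  used <- character()
  rows <- list()
  pl <- spec$planted
  for (i in seq_len(nrow(pl))) {
    cls <- pl$class[i]
    for (attempt in 1:200) {
      if (cls == "exonic") {
        g <- lay[lay$gene_id == sample(multi_genes, 1L), ]
        es <- sort(sample(g$exon, 2L, replace = TRUE))
        start <- g$start[g$exon == es[1L]]; end <- g$end[g$exon == es[2L]]
        strand <- g$strand[1L]; chrom <- g$chrom[1L]
        parent <- g$gene_id[1L]; truth_class <- "exonic"
      } else if (cls %in% c("sub_exonic_sense", "sub_exonic_antisense", "rrna_subexonic")) {
        pool <- if (cls == "rrna_subexonic") rrna_genes else
          unique(c(multi_genes, mono_snc))
        g <- lay[lay$gene_id == sample(pool, 1L), ]
        wide <- g[g$end - g$start + 1L >= 120L, , drop = FALSE]
        e <- wide[sample(nrow(wide), 1L), ]
        start <- e$start + sample(2:20, 1L)
        size <- sample(60:90, 1L)
        end <- start + size - 1L
        if (end >= e$end) next
        chrom <- e$chrom
        strand <- if (cls == "sub_exonic_antisense") {
          if (e$strand == "+") "-" else "+"
        } else e$strand
        parent <- if (cls == "rrna_subexonic") NA_character_ else e$gene_id
        truth_class <- if (cls == "rrna_subexonic") "unannotated"
          else "sub_exonic"
      } else if (cls == "intronic") {
        g <- lay[lay$gene_id == sample(multi_genes, 1L), ]
        if (nrow(g) < 2L) next
        e <- sample(nrow(g) - 1L, 1L)
        i_start <- g$end[e] + 1L; i_end <- g$start[e + 1L] - 1L
        off <- pl$acceptor_offset[i]
        if (is.na(off)) off <- 0L
        strand <- g$strand[1L]; chrom <- g$chrom[1L]
        if (strand == "+") { start <- i_start; end <- i_end - off }
        else { start <- i_start + off; end <- i_end }
        if (end - start + 1L < spec$read_length / 2 + 5) next
        parent <- g$gene_id[1L]
        truth_class <- if (off <= 60L) "intronic" else "unannotated"
      } else if (cls == "intergenic") {
        start <- sample((gene_max + 2000L):(chrom_len - 3000L), 1L)
        end <- start + sample(80:400, 1L)
        strand <- sample(c("+", "-"), 1L); chrom <- "chr1"
        parent <- NA_character_; truth_class <- "unannotated"
      } else if (cls == "multi_gene") {
        cand_genes <- multi_genes[lay$strand[match(multi_genes, lay$gene_id)] == "+"]
        if (length(cand_genes) < 2L) next
        gs <- sort(sample(cand_genes, 2L))
        ga <- lay[lay$gene_id == gs[1L], ]; gb <- lay[lay$gene_id == gs[2L], ]
        start <- ga$start[1L]; end <- gb$end[nrow(gb)]
        strand <- "+"; chrom <- ga$chrom[1L]
        parent <- NA_character_; truth_class <- "unannotated"
      } else stop("unknown planted class: ", cls)
      key <- paste(chrom, strand, start, end)
      if (start >= end || key %in% used) next
      used <- c(used, key)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = paste(chrom, strand, start, end, sep = ":"),
        chrom = chrom, strand = strand, start = start, end = end,
        class = truth_class, planted_as = cls, parent_gene = parent,
        ccr_count = pl$ccr_count[i],
        acceptor_offset = pl$acceptor_offset[i],
        stringsAsFactors = FALSE)
      break
    }
    if (length(rows) < i) stop("could not place planted circ of class ", cls)
  }
  do.call(rbind, rows)
}

#' Plant a chimeric junction file with ground truth
#'
#' Emits a STAR-dialect `chimeric.out.junction` file containing, for every
#' planted circRNA, `ccr_count` two-segment records with the circular
#' geometry (same chromosome and strand, inverted order, junction
#' coordinates equal to the planted circle), plus decoy records — linear
#' splice chimeras in non-inverted order, trans-chromosome chimeras,
#' wrong-strand pairs and undersized segments — which a correct detector
#' must reject.
#'
#' @param spec A [sim_spec()].
#' @param genome Output of [make_genome()].
#' @param out_dir Directory for `chimeric.out.junction` and
#'   `truth.tsv`.
#' @return List: `junction_file`, `truth_file` (paths), `truth`
#'   (data frame, one row per planted circRNA).
#' @export
plant_chimeric_file <- function(spec, genome, out_dir = tempfile("simchim")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  truth <- place_planted_circs(spec, genome)
  lines <- character()
  read_no <- 0L
  seg_rng <- spec$segment_len
  emit <- function(chrom1, brk1, strand, chrom2, brk2, strand2, jtype,
                   start1, cigar1, start2, cigar2) {
    read_no <<- read_no + 1L
    paste(chrom1, brk1, strand, chrom2, brk2, strand2, jtype, 0L, 0L,
          sprintf("read%05d", read_no), start1, cigar1, start2, cigar2,
          sep = "\t")
  }
  rspan <- function(max_span) {
    hi <- min(seg_rng[2L], max_span)
    lo <- min(seg_rng[1L], hi)
    if (lo >= hi) lo else sample(lo:hi, 1L)
  }
  cigar_for <- function(span) {
    # occasionally split the span around an insertion: same reference span
    if (span > 30L && stats::runif(1) < 0.2) {
      a <- sample(10L:(span - 10L), 1L)
      sprintf("%dM%dI%dM", a, sample(1:5, 1L), span - a)
    } else sprintf("%dM", span)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    size <- tr$end - tr$start + 1L
    for (k in seq_len(tr$ccr_count)) {
      # spans strictly below the circle size keep the segments inverted
      s1 <- rspan(size - 1L); s2 <- rspan(size - 1L)
      if (tr$strand == "+") {
        # read prefix ends at the junction end; suffix starts at the start
        lines <- c(lines, emit(tr$chrom, tr$end + 1L, "+", tr$chrom,
                               tr$start - 1L, "+", 1L,
                               tr$end - s1 + 1L, cigar_for(s1),
                               tr$start, cigar_for(s2)))
      } else {
        lines <- c(lines, emit(tr$chrom, tr$start - 1L, "-", tr$chrom,
                               tr$end + 1L, "-", 1L,
                               tr$start, cigar_for(s1),
                               tr$end - s2 + 1L, cigar_for(s2)))
      }
    }
  }
  # decoys: none of these may yield a CCR
  dk <- spec$decoys
  rpos <- function() sample(5000:(spec$chrom_length - 5000L), 1L)
  for (d in seq_len(dk[["linear"]])) {  # ordinary splice: non-inverted order
    a <- rpos(); b <- a + sample(500:2000, 1L); s <- rspan(Inf)
    lines <- c(lines, emit("chr1", a + s, "+", "chr1", b - 1L, "+", 0L,
                           a, sprintf("%dM", s), b, sprintf("%dM", rspan(Inf))))
  }
  for (d in seq_len(dk[["trans"]])) {   # segments on different chromosomes
    chr2 <- if (spec$n_chroms > 1L) "chr2" else "chrUn"
    a <- rpos(); b <- rpos()
    lines <- c(lines, emit("chr1", a - 1L, "+", chr2, b + 1L, "+", -1L,
                           a, sprintf("%dM", rspan(Inf)),
                           b, sprintf("%dM", rspan(Inf))))
  }
  for (d in seq_len(dk[["strand"]])) {  # segments on opposite strands
    a <- rpos(); b <- a + 800L
    lines <- c(lines, emit("chr1", b + 1L, "+", "chr1", a - 1L, "-", -1L,
                           b - 30L, "30M", a, "30M"))
  }
  for (d in seq_len(dk[["short"]])) {   # inverted order but undersized segment
    a <- rpos(); b <- a + 600L
    lines <- c(lines, emit("chr1", b + 1L, "+", "chr1", a - 1L, "+", 1L,
                           b - 9L, "10M", a, "40M"))
  }
  junction_file <- file.path(out_dir, "chimeric.out.junction")
  truth_file <- file.path(out_dir, "truth.tsv")
  writeLines(lines, junction_file)
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(junction_file = junction_file, truth_file = truth_file, truth = truth)
}

#' Derive a diverged ortholog genome
#'
#' Copies the genome with i.i.d. nucleotide substitutions at the given
#' rate (no indels), lifts the annotation unchanged, and emits the
#' one-to-one gene ortholog table plus the circRNA ortholog truth map.
#' Genes listed in `drop_genes` are removed from the second genome's
#' annotation and ortholog table, and their circRNAs from the circ truth.
#'
#' @param genome Output of [make_genome()].
#' @param truth Truth table from [plant_chimeric_file()].
#' @param divergence Substitution rate in `[0, 0.3]`.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param drop_genes Gene ids absent from the second species.
#' @return List: `fasta`, `gtf`, `sequences`, `models`,
#'   `gene_orthologs` (data frame `gene_a`, `gene_b`), `circ_orthologs`
#'   (data frame `circ_a`, `circ_b`).
#' @export
make_ortholog_genome <- function(genome, truth, divergence = 0.05, seed = 1L,
                                 out_dir = tempfile("simortho"),
                                 drop_genes = character()) {
  stopifnot(divergence >= 0, divergence <= 0.3)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seqs_b <- Biostrings::DNAStringSet(lapply(genome$sequences, function(s) {
    x <- strsplit(as.character(s), "")[[1L]]
    n <- length(x)
    mut <- which(stats::runif(n) < divergence)
    if (length(mut)) {
      # substitute with a uniformly chosen different base
      alt <- vapply(x[mut], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
      x[mut] <- alt
    }
    Biostrings::DNAString(paste(x, collapse = ""))
  }))
  names(seqs_b) <- names(genome$sequences)
  fasta <- file.path(out_dir, "genome_b.fa")
  Biostrings::writeXStringSet(seqs_b, fasta)

  gtf_lines <- readLines(genome$gtf)
  suffix_ids <- function(lines) {
    gsub('((?:gene|transcript|exon)_id ")([^"]+)(")', '\\1\\2_b\\3', lines)
  }
  keep <- rep(TRUE, length(gtf_lines))
  for (g in drop_genes) keep <- keep & !grepl(sprintf('gene_id "%s"', g), gtf_lines, fixed = TRUE)
  gtf_b <- file.path(out_dir, "annotation_b.gtf")
  writeLines(suffix_ids(gtf_lines[keep]), gtf_b)
  models_b <- load_gene_models(gtf_b)

  all_genes <- setdiff(unique(genome$layout$gene_id), drop_genes)
  gene_orthologs <- data.frame(gene_a = all_genes,
                               gene_b = paste0(all_genes, "_b"),
                               stringsAsFactors = FALSE)
  circ_keep <- is.na(truth$parent_gene) | !(truth$parent_gene %in% drop_genes)
  circ_orthologs <- data.frame(circ_a = truth$circ_id[circ_keep],
                               circ_b = truth$circ_id[circ_keep],
                               stringsAsFactors = FALSE)
  list(fasta = fasta, gtf = gtf_b, sequences = seqs_b, models = models_b,
       gene_orthologs = gene_orthologs, circ_orthologs = circ_orthologs)
}

#' Simulate a circRNA count matrix with batch structure
#'
#' Draws negative-binomial junction-read counts for every planted circRNA
#' across datasets, around the planted support scaled by a per-dataset
#' sequencing-depth factor, and assembles an [expression_table()] with
#' library sizes and batch definitions.
#'
#' @param truth Truth table from [plant_chimeric_file()].
#' @param batch_plan Data frame (`dataset_id`, `species`, `tissue`,
#'   `batch_id`), one row per dataset.
#' @param depth_range Range of per-dataset depth factors.
#' @param base_library_size Library size of a depth-1 dataset (uniquely
#'   mapped reads).
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return An [expression_table()].
#' @export
simulate_count_matrix <- function(truth, batch_plan,
                                  depth_range = c(0.5, 2),
                                  base_library_size = 2e7,
                                  dispersion = 10,
                                  seed = 1L) {
  stopifnot(nrow(batch_plan) >= 1L)
  set.seed(seed)
  n_ds <- nrow(batch_plan)
  depth <- stats::runif(n_ds, depth_range[1L], depth_range[2L])
  mu <- outer(truth$ccr_count * 10, depth)  # planted support sets the mean
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                   nrow = nrow(truth),
                   dimnames = list(truth$circ_id, batch_plan$dataset_id))
  lib <- stats::setNames(round(base_library_size * depth), batch_plan$dataset_id)
  if (any(lib <= 0)) stop("zero-depth dataset in the plan")
  expression_table(counts, lib, batch_plan)
}

#' Run the full detection pipeline on a chimeric junction file
#'
#' Convenience wrapper chaining parse, CCR selection, clustering, support
#' filtering and size partition — the complete path from a chimeric
#' junction file to an annotatable catalog.
#'
#' @param junction_file A `chimeric.out.junction` path.
#' @param read_length Read length (bp) for the size filter.
#' @param dataset_id Catalog label.
#' @param min_segment Minimal segment span (bp).
#' @param min_ccr Minimal CCR support.
#' @return List: `ccrs`, `catalog` (pre-filter), `retained`,
#'   `annotatable`, `size_excluded`.
#' @export
detect_circrnas <- function(junction_file, read_length, dataset_id = "dataset",
                            min_segment = 15L, min_ccr = 5L) {
  rec <- parse_chimeric_records(junction_file)
  ccrs <- select_ccrs(rec, min_segment = min_segment)
  catalog <- cluster_ccrs(ccrs, dataset_id)
  retained <- apply_ccr_threshold(catalog, min_ccr = min_ccr)
  parts <- size_partition(retained, read_length)
  list(ccrs = ccrs, catalog = catalog, retained = retained,
       annotatable = parts$annotatable, size_excluded = parts$size_excluded)
}
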