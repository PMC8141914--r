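#' Load Ensembl-style gene models from GTF or GFF3
#'
#' Reads a gene annotation file and assembles a `GeneModelSet`: the genes
#' (with their biotypes), their transcripts, and the ordered exons of each
#' transcript. The dialect (GTF vs GFF3) is auto-detected from the attribute
#' column: `key "value"` pairs mean GTF, `key=value` pairs mean GFF3.
#'
#' All coordinates are kept 1-based fully-closed, as in the input. Unknown
#' biotype strings are preserved verbatim so that downstream filters (for
#' instance the rRNA exclusion applied to sub-exonic circRNAs) can act on
#' them. Exon features lacking a transcript identifier cannot be attached to
#' a model and are skipped with a warning giving their count.
#'
#' @param path Path to a GTF or GFF3 file. May be empty (returns an empty
#'   model set).
#' @return An object of class `GeneModelSet`: a list with data frames
#'   `genes` (`gene_id`, `biotype`, `chrom`, `strand`), `transcripts`
#'   (`transcript_id`, `gene_id`) and `exons` (`chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`, `exon_id`), exons sorted by
#'   transcript then start.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
#'   'gene_id "G1"; transcript_id "G1.t1"; gene_biotype "protein_coding";',
#'   sep = "\t"), gtf)
#' m <- load_gene_models(gtf)
#' nrow(m$exons)
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    return(new_gene_model_set())
  }
  # column-count sanity scan so malformed lines are reported by line number
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    bad <- which(!grepl("^#", lines) & nzchar(lines))[which(nfield < 8L)[1L]]
    stop("malformed annotation line ", bad, ": expected 9 tab-separated columns")
  }
  fmt <- detect_annotation_dialect(body)
  gr <- rtracklayer::import(path, format = fmt)
  meta <- S4Vectors::mcols(gr)

  biotype_of <- function(m) {
    bt <- rep(NA_character_, nrow(m))
    for (col in c("gene_biotype", "biotype", "gene_type")) {
      if (col %in% colnames(m)) {
        v <- as.character(m[[col]])
        bt[is.na(bt) & !is.na(v)] <- v[is.na(bt) & !is.na(v)]
      }
    }
    bt
  }

  if (fmt == "gff3") {
    ids <- if ("ID" %in% colnames(meta)) sub("^(gene|transcript):", "", as.character(meta$ID)) else rep(NA_character_, length(gr))
    parents <- if ("Parent" %in% colnames(meta)) {
      vapply(meta$Parent, function(p) if (length(p)) sub("^(gene|transcript):", "", p[[1L]]) else NA_character_, character(1))
    } else rep(NA_character_, length(gr))
    typ <- as.character(meta$type)
    is_tx <- typ %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA", "rRNA", "snoRNA",
                        "snRNA", "miRNA", "tRNA", "pseudogenic_transcript", "unconfirmed_transcript")
    tx2gene <- stats::setNames(parents[is_tx], ids[is_tx])
    tx_id <- ifelse("transcript_id" %in% colnames(meta) & !is.na(meta$transcript_id),
                    as.character(meta$transcript_id), NA_character_)
    gene_id <- ifelse("gene_id" %in% colnames(meta) & !is.na(meta$gene_id),
                      as.character(meta$gene_id), NA_character_)
    is_exon <- typ == "exon"
    ex_tx <- ifelse(is.na(tx_id[is_exon]), parents[is_exon], tx_id[is_exon])
    ex_gene <- gene_id[is_exon]
    miss <- is.na(ex_gene) & !is.na(ex_tx)
    ex_gene[miss] <- unname(tx2gene[ex_tx[miss]])
    gene_bt <- biotype_of(meta)
    is_gene <- typ %in% c("gene", "ncRNA_gene", "pseudogene")
    gene_bt_map <- stats::setNames(gene_bt[is_gene], ids[is_gene])
    exon_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
      start = GenomicRanges::start(gr)[is_exon],
      end = GenomicRanges::end(gr)[is_exon],
      strand = as.character(GenomicRanges::strand(gr))[is_exon],
      gene_id = ex_gene, transcript_id = ex_tx,
      exon_id = exon_label(meta, is_exon),
      stringsAsFactors = FALSE)
    exon_df$biotype <- unname(gene_bt_map[exon_df$gene_id])
  } else {
    typ <- as.character(meta$type)
    is_exon <- typ == "exon"
    col_or_na <- function(col) {
      if (col %in% colnames(meta)) as.character(meta[[col]])[is_exon]
      else rep(NA_character_, sum(is_exon))
    }
    exon_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
      start = GenomicRanges::start(gr)[is_exon],
      end = GenomicRanges::end(gr)[is_exon],
      strand = as.character(GenomicRanges::strand(gr))[is_exon],
      gene_id = col_or_na("gene_id"),
      transcript_id = col_or_na("transcript_id"),
      exon_id = exon_label(meta, is_exon),
      biotype = biotype_of(meta)[is_exon],
      stringsAsFactors = FALSE)
  }

  orphan <- is.na(exon_df$transcript_id) | is.na(exon_df$gene_id)
  if (any(orphan)) {
    warning(sum(orphan), " exon feature(s) without a parent transcript/gene were skipped")
    exon_df <- exon_df[!orphan, , drop = FALSE]
  }
  if (nrow(exon_df) == 0L) {
    return(new_gene_model_set())
  }
  exon_df <- exon_df[order(exon_df$transcript_id, exon_df$start), , drop = FALSE]
  rownames(exon_df) <- NULL
  # fill exon ids where the annotation carries none
  need_id <- is.na(exon_df$exon_id)
  if (any(need_id)) {
    idx <- stats::ave(seq_len(nrow(exon_df)), exon_df$transcript_id, FUN = seq_along)
    exon_df$exon_id[need_id] <- paste0(exon_df$transcript_id[need_id], ".e", idx[need_id])
  }

  tx <- unique(exon_df[, c("transcript_id", "gene_id")])
  rownames(tx) <- NULL
  first_ex <- exon_df[!duplicated(exon_df$gene_id), , drop = FALSE]
  genes <- data.frame(
    gene_id = first_ex$gene_id,
    biotype = ifelse(is.na(first_ex$biotype), "unknown", first_ex$biotype),
    chrom = first_ex$chrom,
    strand = first_ex$strand,
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  out <- new_gene_model_set(genes = genes, transcripts = tx,
                            exons = exon_df[, c("chrom", "start", "end", "strand",
                                                "gene_id", "transcript_id", "exon_id")])
  out
}

exon_label <- function(meta, keep) {
  for (col in c("exon_id", "Name")) {
    if (col %in% colnames(meta)) {
      v <- as.character(meta[[col]])[keep]
      if (!all(is.na(v))) return(v)
    }
  }
  rep(NA_character_, sum(keep))
}

detect_annotation_dialect <- function(body_lines) {
  attr9 <- vapply(strsplit(body_lines[seq_len(min(50L, length(body_lines)))],
                           "\t", fixed = TRUE),
                  function(x) if (length(x) >= 9L) x[9L] else "", character(1))
  attr9 <- attr9[nzchar(attr9)]
  if (length(attr9) == 0L) return("gtf")
  # GTF: key "value"; GFF3: key=value
  if (any(grepl("=", attr9, fixed = TRUE)) && !any(grepl("\"", attr9, fixed = TRUE))) "gff3" else "gtf"
}

new_gene_model_set <- function(genes = NULL, transcripts = NULL, exons = NULL) {
  empty_genes <- data.frame(gene_id = character(), biotype = character(),
                            chrom = character(), strand = character(),
                            stringsAsFactors = FALSE)
  empty_tx <- data.frame(transcript_id = character(), gene_id = character(),
                         stringsAsFactors = FALSE)
  empty_ex <- data.frame(chrom = character(), start = integer(), end = integer(),
                         strand = character(), gene_id = character(),
                         transcript_id = character(), exon_id = character(),
                         stringsAsFactors = FALSE)
  structure(list(genes = if (is.null(genes)) empty_genes else genes,
                 transcripts = if (is.null(transcripts)) empty_tx else transcripts,
                 exons = if (is.null(exons)) empty_ex else exons),
            class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Derive introns from a gene model set
#'
#' One intron is emitted for every adjacent exon pair of every transcript.
#' Intron coordinates are 1-based inclusive on the first/last intronic base.
#' The donor position is the strand-aware first intronic base at the 5'
#' side of the intron (`start` on `+`, `end` on `-`); the acceptor position
#' is the last intronic base at the 3' side (`end` on `+`, `start` on `-`).
#'
#' Identical introns arising from several transcripts are all returned, one
#' row per (gene, transcript) attribution; coordinate-level deduplication
#' happens when the feature index is built.
#'
#' @param models A `GeneModelSet`.
#' @return Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `donor_pos`, `acceptor_pos`. Mono-exonic
#'   transcripts contribute no rows.
#' @export
derive_introns <- function(models) {
  stopifnot(inherits(models, "GeneModelSet"))
  ex <- models$exons
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ex) < 2L) return(empty)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  same_tx <- ex$transcript_id[-1L] == ex$transcript_id[-nrow(ex)]
  i_start <- ex$end[-nrow(ex)] + 1L
  i_end <- ex$start[-1L] - 1L
  if (any(same_tx & i_start > i_end)) {
    bad <- which(same_tx & i_start > i_end)[1L]
    stop("overlapping or abutting exons within transcript ",
         ex$transcript_id[bad], " — inconsistent annotation")
  }
  keep <- same_tx
  if (!any(keep)) return(empty)
  out <- data.frame(
    gene_id = ex$gene_id[-nrow(ex)][keep],
    transcript_id = ex$transcript_id[-nrow(ex)][keep],
    chrom = ex$chrom[-nrow(ex)][keep],
    strand = ex$strand[-nrow(ex)][keep],
    start = i_start[keep],
    end = i_end[keep],
    stringsAsFactors = FALSE)
  out$donor_pos <- ifelse(out$strand == "+", out$start, out$end)
  out$acceptor_pos <- ifelse(out$strand == "+", out$end, out$start)
  rownames(out) <- NULL
  out
}

#' Build interval indexes over exons, introns and gene spans
#'
#' Wraps the model set's features into per-chromosome interval structures
#' (GRanges) supporting overlap queries, plus exact-coordinate lookups for
#' exon starts, exon ends and intron donor positions, which the circRNA
#' classifier needs.
#'
#' @param models A `GeneModelSet`.
#' @param introns Optional intron table from [derive_introns()]; derived on
#'   the fly when missing.
#' @return An object of class `FeatureIndex`.
#' @export
build_feature_index <- function(models, introns = NULL) {
  stopifnot(inherits(models, "GeneModelSet"))
  if (is.null(introns)) introns <- derive_introns(models)
  ex <- models$exons
  exons_gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(exons_gr) <- S4Vectors::DataFrame(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    exon_id = ex$exon_id)

  # deduplicate introns on (chrom, strand, start, end), keep attributions
  if (nrow(introns)) {
    key <- paste(introns$chrom, introns$strand, introns$start, introns$end)
    uniq <- !duplicated(key)
    attribution <- vapply(split(paste0(introns$gene_id, "/", introns$transcript_id), key),
                          function(v) paste(unique(v), collapse = ","), character(1))
    iu <- introns[uniq, , drop = FALSE]
    introns_gr <- GenomicRanges::GRanges(
      seqnames = iu$chrom,
      ranges = IRanges::IRanges(start = iu$start, end = iu$end),
      strand = iu$strand)
    S4Vectors::mcols(introns_gr) <- S4Vectors::DataFrame(
      gene_id = iu$gene_id,
      donor_pos = iu$donor_pos, acceptor_pos = iu$acceptor_pos,
      attribution = unname(attribution[key[uniq]]))
  } else {
    introns_gr <- GenomicRanges::GRanges()
  }

  if (nrow(ex)) {
    spans <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
      data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                 strand = g$strand[1L], start = min(g$start), end = max(g$end),
                 stringsAsFactors = FALSE)
    }))
    genes_gr <- GenomicRanges::GRanges(
      seqnames = spans$chrom,
      ranges = IRanges::IRanges(start = spans$start, end = spans$end),
      strand = spans$strand)
    bt <- stats::setNames(models$genes$biotype, models$genes$gene_id)
    S4Vectors::mcols(genes_gr) <- S4Vectors::DataFrame(
      gene_id = spans$gene_id, biotype = unname(bt[spans$gene_id]))
  } else {
    genes_gr <- GenomicRanges::GRanges()
  }

  structure(list(exons = exons_gr, introns = introns_gr, genes = genes_gr,
                 models = models, intron_table = introns),
            class = "FeatureIndex")
}

#' @export
print.FeatureIndex <- function(x, ...) {
  cat("FeatureIndex:", length(x$exons), "exons,", length(x$introns),
      "unique introns,", length(x$genes), "gene spans\n")
  invisible(x)
}

#' Overlap query against a feature index
#'
#' Returns all features of the requested kind whose interval intersects
#' `[start, end]` on `chrom` (strand is ignored; classification applies its
#' own strand rules).
#'
#' @param index A `FeatureIndex`.
#' @param chrom,start,end Query interval, 1-based inclusive.
#' @param what One of `"exon"`, `"intron"`, `"gene"`.
#' @return Data frame of matching features (coordinates plus metadata).
#' @export
query_overlaps <- function(index, chrom, start, end,
                           what = c("exon", "intron", "gene")) {
  what <- match.arg(what)
  gr <- switch(what, exon = index$exons, intron = index$introns, gene = index$genes)
  if (length(gr) == 0L) return(gr_to_df(gr))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  # a chromosome absent from the annotation is a legitimate empty query
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE))
  gr_to_df(gr[S4Vectors::subjectHits(hits)])
}

gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(S4Vectors::mcols(gr)))
}

#' Write derived introns as TSV
#'
#' @param introns Intron table from [derive_introns()].
#' @param path Output file.
#' @export
write_introns_tsv <- function(introns, path) {
  utils::write.table(introns[, c("chrom", "start", "end", "strand",
                                 "gene_id", "transcript_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
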