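#' Classifier configuration
#'
#' @param acceptor_tolerance Maximal distance (bp, measured into the
#'   intron) between an intronic candidate's 3' junction and the intron
#'   acceptor site. Default 60.
#' @param exclude_biotypes_subexonic Gene biotypes whose exons never host
#'   sub-exonic calls (ribosomal RNA by default: back-splice-like reads on
#'   rRNA are overwhelmingly depletion artifacts).
#' @param allow_antisense_subexonic Whether sub-exonic calls antisense to
#'   the host gene are allowed.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(acceptor_tolerance = 60L,
                              exclude_biotypes_subexonic = "rRNA",
                              allow_antisense_subexonic = TRUE) {
  stopifnot(acceptor_tolerance >= 0)
  structure(list(acceptor_tolerance = as.integer(acceptor_tolerance),
                 exclude_biotypes_subexonic = exclude_biotypes_subexonic,
                 allow_antisense_subexonic = isTRUE(allow_antisense_subexonic)),
            class = "classifier_config")
}

gene_biotype_map <- function(index) {
  stats::setNames(index$models$genes$biotype, index$models$genes$gene_id)
}

#' Exonic classification of one candidate
#'
#' A candidate is exonic when both junctions coincide exactly with exon
#' boundaries of the same gene on the candidate's strand: some exon of the
#' gene starts at the candidate start and some exon of the gene (possibly
#' the same one) ends at the candidate end. Back-splicing reuses the
#' gene's own splice sites, so strand agreement with the gene is required.
#'
#' @param candidate One catalog row (list or single-row data frame with
#'   `chrom`, `strand`, `start`, `end`).
#' @param index A `FeatureIndex`.
#' @return `NULL`, or a list with `gene_id`, `exon_start_id`,
#'   `exon_end_id`; when start and end match exons of two different genes
#'   (no shared gene), a list with `multi_gene = TRUE` and the gene sets.
#' @export
classify_exonic <- function(candidate, index) {
  ex <- index$exons
  on_chrom <- as.character(GenomicRanges::seqnames(ex)) == candidate$chrom &
    as.character(GenomicRanges::strand(ex)) == candidate$strand
  at_start <- on_chrom & GenomicRanges::start(ex) == candidate$start
  at_end <- on_chrom & GenomicRanges::end(ex) == candidate$end
  if (!any(at_start) || !any(at_end)) return(NULL)
  g1 <- unique(S4Vectors::mcols(ex)$gene_id[at_start])
  g2 <- unique(S4Vectors::mcols(ex)$gene_id[at_end])
  shared <- intersect(g1, g2)
  if (length(shared) == 0L) {
    return(list(multi_gene = TRUE, genes_start = g1, genes_end = g2))
  }
  g <- sort(shared)[1L]
  es <- S4Vectors::mcols(ex)$exon_id[at_start & S4Vectors::mcols(ex)$gene_id == g][1L]
  ee <- S4Vectors::mcols(ex)$exon_id[at_end & S4Vectors::mcols(ex)$gene_id == g][1L]
  list(gene_id = g, exon_start_id = es, exon_end_id = ee)
}

#' Sub-exonic classification of one candidate
#'
#' A candidate is sub-exonic when both junctions fall strictly within a
#' single exon (`exon.start < start` and `end < exon.end`; a junction that
#' merely touches an exon boundary does not qualify). The call is sense
#' when the candidate strand equals the host gene's strand, antisense
#' otherwise. Exons of excluded biotypes (rRNA by default) never host
#' sub-exonic calls.
#'
#' @inheritParams classify_exonic
#' @param config A [classifier_config()].
#' @return `NULL`, or list with `gene_id`, `exon_id`, `sense`
#'   (`"sense"`/`"antisense"`); sense matches win over antisense ones.
#' @export
classify_subexonic <- function(candidate, index, config = classifier_config()) {
  hits <- query_overlaps(index, candidate$chrom, candidate$start, candidate$end, "exon")
  if (nrow(hits) == 0L) return(NULL)
  inside <- hits$start < candidate$start & candidate$end < hits$end
  hits <- hits[inside, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  bt <- gene_biotype_map(index)
  hits$biotype <- unname(bt[hits$gene_id])
  hits <- hits[!(hits$biotype %in% config$exclude_biotypes_subexonic), , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits$sense <- ifelse(hits$strand == candidate$strand, "sense", "antisense")
  if (!config$allow_antisense_subexonic) {
    hits <- hits[hits$sense == "sense", , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
  }
  hits <- hits[order(hits$sense != "sense", hits$gene_id, hits$exon_id), , drop = FALSE]
  list(gene_id = hits$gene_id[1L], exon_id = hits$exon_id[1L],
       sense = hits$sense[1L])
}

#' Intronic classification of one candidate
#'
#' A candidate is intronic when it lies entirely within one intron of its
#' own strand, its 5' junction coincides exactly with the intron donor
#' site, and its 3' junction lies no further than `acceptor_tolerance` bp
#' (60 by default) inside the intron from the acceptor site — the
#' signature of a lariat-derived circle whose tail is trimmed back from
#' the branch point.
#'
#' @inheritParams classify_subexonic
#' @return `NULL`, or list with `gene_id`, `intron` (coordinate string),
#'   `acceptor_offset`.
#' @export
classify_intronic <- function(candidate, index, config = classifier_config()) {
  hits <- query_overlaps(index, candidate$chrom, candidate$start, candidate$end, "intron")
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[hits$strand == candidate$strand &
                 hits$start <= candidate$start & candidate$end <= hits$end, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  if (candidate$strand == "+") {
    anchored <- candidate$start == hits$donor_pos
    offset <- hits$acceptor_pos - candidate$end
  } else {
    anchored <- candidate$end == hits$donor_pos
    offset <- candidate$start - hits$acceptor_pos
  }
  ok <- anchored & offset >= 0L & offset <= config$acceptor_tolerance
  if (!any(ok)) return(NULL)
  i <- which(ok)[order(offset[ok])][1L]
  list(gene_id = hits$gene_id[i],
       intron = paste0(hits$chrom[i], ":", hits$start[i], "-", hits$end[i]),
       acceptor_offset = as.integer(offset[i]))
}

#' Annotate a circRNA catalog
#'
#' Assigns each annotatable candidate one primary class with the
#' precedence exonic > intronic > sub-exonic (sense) > sub-exonic
#' (antisense) > unannotated; exonic is the only class backed by exact
#' evidence at both junctions, which is why it outranks the others. All
#' alternative classifications are preserved in `all_matches` so the
#' precedence choice stays auditable. Size-excluded candidates, when
#' given, are appended with class `size_excluded` and are never sent to
#' the classifier.
#'
#' @param candidates Annotatable catalog (see [size_partition()]).
#' @param index A `FeatureIndex`.
#' @param config A [classifier_config()].
#' @param size_excluded Optional catalog of size-excluded candidates.
#' @return Data frame: the catalog columns plus `circ_class`,
#'   `parent_gene_id`, `parent_biotype`, `matched_features`, `sense`,
#'   `acceptor_offset`, `all_matches`; attribute `class_summary` holds
#'   the per-class counts.
#' @export
annotate_catalog <- function(candidates, index, config = classifier_config(),
                             size_excluded = NULL) {
  bt <- gene_biotype_map(index)
  known_chroms <- unique(as.character(GenomicRanges::seqnames(index$genes)))
  missing_chroms <- character()
  n <- nrow(candidates)
  circ_class <- character(n); parent <- rep(NA_character_, n)
  feats <- rep(NA_character_, n); sense <- rep(NA_character_, n)
  acc_off <- rep(NA_integer_, n); all_matches <- character(n)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    if (!(cand$chrom %in% known_chroms) && !(cand$chrom %in% missing_chroms)) {
      missing_chroms <- c(missing_chroms, cand$chrom)
    }
    exo <- classify_exonic(cand, index)
    intro <- classify_intronic(cand, index, config)
    sub <- classify_subexonic(cand, index, config)
    alts <- character()
    if (!is.null(exo) && is.null(exo$multi_gene)) {
      alts <- c(alts, paste0("exonic:", exo$gene_id))
    }
    if (!is.null(exo) && isTRUE(exo$multi_gene)) {
      alts <- c(alts, paste0("multi_gene:", paste(exo$genes_start, collapse = "+"),
                             "|", paste(exo$genes_end, collapse = "+")))
    }
    if (!is.null(intro)) alts <- c(alts, paste0("intronic:", intro$gene_id))
    if (!is.null(sub)) alts <- c(alts, paste0("sub_exonic_", sub$sense, ":", sub$gene_id))
    all_matches[i] <- paste(alts, collapse = ";")
    if (!is.null(exo) && is.null(exo$multi_gene)) {
      circ_class[i] <- "exonic"; parent[i] <- exo$gene_id
      feats[i] <- paste(exo$exon_start_id, exo$exon_end_id, sep = ",")
      sense[i] <- "sense"
    } else if (!is.null(intro)) {
      circ_class[i] <- "intronic"; parent[i] <- intro$gene_id
      feats[i] <- intro$intron; sense[i] <- "sense"
      acc_off[i] <- intro$acceptor_offset
    } else if (!is.null(sub)) {
      circ_class[i] <- "sub_exonic"; parent[i] <- sub$gene_id
      feats[i] <- sub$exon_id; sense[i] <- sub$sense
    } else {
      circ_class[i] <- "unannotated"
    }
  }
  if (length(missing_chroms)) {
    message("chromosome(s) absent from annotation: ",
            paste(missing_chroms, collapse = ", "))
  }
  out <- cbind(as.data.frame(candidates), data.frame(
    circ_class = circ_class, parent_gene_id = parent,
    parent_biotype = ifelse(is.na(parent), NA_character_, unname(bt[parent])),
    matched_features = feats, sense = sense, acceptor_offset = acc_off,
    all_matches = all_matches, stringsAsFactors = FALSE))
  if (!is.null(size_excluded) && nrow(size_excluded) > 0L) {
    se <- cbind(as.data.frame(size_excluded), data.frame(
      circ_class = "size_excluded", parent_gene_id = NA_character_,
      parent_biotype = NA_character_, matched_features = NA_character_,
      sense = NA_character_, acceptor_offset = NA_integer_,
      all_matches = "", stringsAsFactors = FALSE))
    out <- rbind(out, se)
  }
  rownames(out) <- NULL
  lev <- c("exonic", "intronic", "sub_exonic", "unannotated", "size_excluded")
  attr(out, "class_summary") <- table(factor(out$circ_class, levels = lev))
  out
}

#' Per-gene sub-exonic production profile
#'
#' For each parent gene with sub-exonic calls: how many of its exons host
#' sub-exonic circRNAs, how many distinct circRNAs, and their total read
#' support. Biotypes are grouped into the broad classes used when
#' comparing coding genes, lncRNAs, pseudogenes and small non-coding
#' genes.
#'
#' @param annotated Output of [annotate_catalog()].
#' @return Data frame (`gene_id`, `biotype`, `biotype_class`,
#'   `n_exons_involved`, `n_subexonic`, `ccr_total`), empty when no
#'   sub-exonic calls exist.
#' @export
gene_subexonic_profile <- function(annotated) {
  sub <- annotated[annotated$circ_class == "sub_exonic", , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(gene_id = character(), biotype = character(),
                      biotype_class = character(), n_exons_involved = integer(),
                      n_subexonic = integer(), ccr_total = integer(),
                      stringsAsFactors = FALSE))
  }
  grp <- split(sub, sub$parent_gene_id)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(gene_id = g$parent_gene_id[1L], biotype = g$parent_biotype[1L],
               biotype_class = biotype_class(g$parent_biotype[1L]),
               n_exons_involved = length(unique(g$matched_features)),
               n_subexonic = nrow(g), ccr_total = sum(g$ccr_count),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

biotype_class <- function(bt) {
  ifelse(bt %in% "protein_coding", "protein_coding",
    ifelse(bt %in% c("lncRNA", "lincRNA"), "lncRNA",
      ifelse(grepl("pseudogene", bt), "pseudogene",
        ifelse(bt %in% c("snoRNA", "snRNA", "miRNA", "misc_RNA", "ribozyme",
                         "scaRNA", "sRNA"), "snc", "other"))))
}

#' Scan for clusters of unannotated circRNAs
#'
#' Dense stretches of unannotated circRNAs along a chromosome flag regions
#' with assembly or annotation problems rather than genuinely novel loci.
#' Unannotated junction intervals closer than `window` bp (gap between
#' successive intervals) are merged by a sort-then-sweep; clusters with at
#' least `min_count` members are reported with their share of all
#' unannotated circRNAs.
#'
#' @param annotated Output of [annotate_catalog()].
#' @param window Maximal gap (bp) between members of one cluster.
#' @param min_count Minimal cluster size reported.
#' @return Data frame (`chrom`, `start`, `end`, `n_circ`,
#'   `fraction_of_unannotated`).
#' @export
find_unannotated_clusters <- function(annotated, window = 10000L, min_count = 10L) {
  un <- annotated[annotated$circ_class == "unannotated", , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_circ = integer(), fraction_of_unannotated = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(un) == 0L) return(empty)
  total <- nrow(un)
  un <- un[order(un$chrom, un$start, un$end), , drop = FALSE]
  res <- list()
  for (chrom in unique(un$chrom)) {
    u <- un[un$chrom == chrom, , drop = FALSE]
    cl_start <- u$start[1L]; cl_end <- u$end[1L]; n <- 1L
    flush <- function(s, e, n) {
      if (n >= min_count) res[[length(res) + 1L]] <<- data.frame(
        chrom = chrom, start = s, end = e, n_circ = n,
        fraction_of_unannotated = n / total, stringsAsFactors = FALSE)
    }
    if (nrow(u) > 1L) for (i in 2L:nrow(u)) {
      if (u$start[i] - cl_end <= window) {
        cl_end <- max(cl_end, u$end[i]); n <- n + 1L
      } else {
        flush(cl_start, cl_end, n)
        cl_start <- u$start[i]; cl_end <- u$end[i]; n <- 1L
      }
    }
    flush(cl_start, cl_end, n)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write an annotated catalog as TSV
#'
#' @param annotated Output of [annotate_catalog()].
#' @param path Output file.
#' @export
write_annotated_tsv <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
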