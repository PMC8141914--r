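#' Cluster CCRs into circRNA candidates
#'
#' Groups circular chimeric reads by exact junction identity
#' (`chrom`, `strand`, `start`, `end`) and counts the supporting reads.
#' No fuzz window is applied: a circRNA is its junction, which keeps
#' identity well-defined for catalog intersections and orthology.
#'
#' @param ccrs CCR table from [select_ccrs()].
#' @param dataset_id Label stored with every candidate.
#' @return A `circ_catalog` data frame (`chrom`, `strand`, `start`, `end`,
#'   `ccr_count`, `dataset_id`, `genomic_size`), sorted by
#'   (chrom, start, end).
#' @export
cluster_ccrs <- function(ccrs, dataset_id = "dataset") {
  if (nrow(ccrs) == 0L) return(empty_catalog())
  key <- paste(ccrs$chrom, ccrs$strand, ccrs$start, ccrs$end, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    strand = vapply(parts, `[[`, character(1), 2L),
    start = as.integer(vapply(parts, `[[`, character(1), 3L)),
    end = as.integer(vapply(parts, `[[`, character(1), 4L)),
    ccr_count = as.integer(tab),
    dataset_id = dataset_id,
    stringsAsFactors = FALSE)
  out$genomic_size <- out$end - out$start + 1L
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("circ_catalog", "data.frame")
  out
}

empty_catalog <- function() {
  out <- data.frame(chrom = character(), strand = character(),
                    start = integer(), end = integer(),
                    ccr_count = integer(), dataset_id = character(),
                    genomic_size = integer(), stringsAsFactors = FALSE)
  class(out) <- c("circ_catalog", "data.frame")
  out
}

#' Canonical circRNA identifier
#'
#' `chrom:strand:start:end`, the junction-defined identity used across
#' expression tables, Top-N lists and orthology.
#'
#' @param catalog A catalog data frame.
#' @return Character vector of ids.
#' @export
circ_id <- function(catalog) {
  paste(catalog$chrom, catalog$strand, catalog$start, catalog$end, sep = ":")
}

#' Filter candidates on CCR support
#'
#' Candidates supported by fewer than `min_ccr` circular chimeric reads are
#' discarded as likely rare or spurious circularization events; the default
#' of 5 mirrors the support threshold used for exhaustive detection.
#'
#' @param candidates A `circ_catalog`.
#' @param min_ccr Minimal supporting read count.
#' @return Filtered catalog.
#' @export
apply_ccr_threshold <- function(candidates, min_ccr = 5L) {
  out <- candidates[candidates$ccr_count >= min_ccr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition candidates on genomic size ahead of annotation
#'
#' Candidates whose genomic size (end - start + 1) is below
#' `read_length / 2 + 5` are too small relative to the reads that support
#' them to be annotated confidently; they are excluded from classification
#' but kept in the catalog and reported as `size_excluded`. At 100 bp reads
#' the smallest annotatable size is 55 bp.
#'
#' @param candidates A `circ_catalog`.
#' @param read_length Sequencing read length in bp (required).
#' @return List with elements `annotatable` and `size_excluded`, both
#'   catalogs, plus `cutoff` (smallest annotatable size in bp).
#' @export
size_partition <- function(candidates, read_length) {
  if (missing(read_length) || is.null(read_length) || is.na(read_length)) {
    stop("read_length must be set for the size filter")
  }
  cutoff <- read_length / 2 + 5
  small <- candidates$genomic_size < cutoff
  list(annotatable = {
    x <- candidates[!small, , drop = FALSE]; rownames(x) <- NULL; x
  }, size_excluded = {
    x <- candidates[small, , drop = FALSE]; rownames(x) <- NULL; x
  }, cutoff = cutoff)
}

#' Intersect two circRNA catalogs and filter on junction-read support
#'
#' Keeps the circRNAs present in both lists (exact junction identity) whose
#' junction-read count reaches `min_bsj`; the support threshold is applied
#' after the intersection, matching the practice of intersecting two
#' detection tools and only then quantifying. List A is treated as the
#' quantification list: the retained record carries A's `bsj` count.
#' Records with strand `"."` (strand-unaware external tools) match either
#' strand; such lenient matches are counted in attribute
#' `lenient_matches`.
#'
#' @param list_a,list_b Data frames with `chrom`, `start`, `end`, `strand`
#'   and a `bsj` count column.
#' @param min_bsj Minimal junction-read count after intersection.
#' @return The intersected, filtered rows of `list_a`.
#' @export
intersect_catalogs <- function(list_a, list_b, min_bsj = 4L) {
  for (nm in c("list_a", "list_b")) {
    x <- get(nm)
    if (!"bsj" %in% names(x)) stop(nm, " lacks a 'bsj' column")
  }
  key_strict <- function(x) paste(x$chrom, x$strand, x$start, x$end, sep = ":")
  key_loose <- function(x) paste(x$chrom, x$start, x$end, sep = ":")
  kb <- key_strict(list_b)
  kb_loose <- key_loose(list_b)
  ka <- key_strict(list_a)
  ka_loose <- key_loose(list_a)
  strict_hit <- ka %in% kb
  amb_a <- list_a$strand == "."
  amb_b_keys <- kb_loose[list_b$strand == "."]
  lenient <- (amb_a & ka_loose %in% kb_loose) |
    (!amb_a & !strict_hit & ka_loose %in% amb_b_keys)
  in_both <- strict_hit | lenient
  n_lenient <- sum(lenient & !strict_hit)
  out <- list_a[in_both & list_a$bsj >= min_bsj, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lenient_matches") <- n_lenient
  out
}

#' Write a circRNA catalog as BED6
#'
#' Internal 1-based fully-closed coordinates are converted to BED's
#' 0-based half-open convention at this single point
#' (`chromStart = start - 1`, `chromEnd = end`). The name field is
#' `chrom:start|end` and the score is the CCR count.
#'
#' @param catalog A `circ_catalog`.
#' @param path Output BED path.
#' @export
write_bed <- function(catalog, path) {
  if (nrow(catalog) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start, end = catalog$end),
    strand = catalog$strand)
  S4Vectors::mcols(gr)$name <- paste0(catalog$chrom, ":", catalog$start, "|", catalog$end)
  S4Vectors::mcols(gr)$score <- catalog$ccr_count
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 circRNA catalog written by [write_bed()]
#'
#' @param path BED file.
#' @param dataset_id Label to attach.
#' @return A `circ_catalog`; the round trip through [write_bed()] is
#'   lossless for coordinates, strand and counts.
#' @export
read_bed <- function(path, dataset_id = "dataset") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(empty_catalog())
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    ccr_count = as.integer(S4Vectors::mcols(gr)$score),
    dataset_id = dataset_id,
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  out$genomic_size <- out$end - out$start + 1L
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("circ_catalog", "data.frame")
  out
}

#' Read an externally produced circRNA list
#'
#' TSV with columns `chrom`, `start`, `end`, `strand`, `bsj` (header
#' required). External tools differ in coordinate convention; set
#' `zero_based = TRUE` for BED-style half-open input, which is converted
#' to the package's 1-based fully-closed coordinates on read.
#'
#' @param path TSV path.
#' @param zero_based Whether `start` is 0-based half-open.
#' @return Data frame with 1-based inclusive `start`/`end` and `bsj`.
#' @export
read_external_list <- function(path, zero_based = FALSE) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "bsj")
  if (!all(need %in% names(x))) {
    stop("external list must have columns: ", paste(need, collapse = ", "))
  }
  if (zero_based) x$start <- x$start + 1L
  x
}
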