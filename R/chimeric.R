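#' Parse a STAR-dialect chimeric junction file
#'
#' Reads a tab-separated `chimeric.out.junction` table (classic 14-column
#' STAR dialect, trailing extra columns tolerated) into one record per
#' chimeric read. Each record carries the two aligned segments of the read:
#' segment 1 covers the read prefix, segment 2 the read suffix, each with
#' chromosome, strand, 1-based reference start and CIGAR. The file's
#' donor/acceptor breakpoint columns are preserved verbatim for
#' cross-checking but are not used to derive junctions.
#'
#' Comment lines (`#`) and header lines (first field `chr_donorA`) are
#' skipped. A line with fewer than 14 columns raises an error naming the
#' line number. Records whose CIGAR strings cannot be parsed are dropped
#' and counted in the `rejects` attribute of the result.
#'
#' @param path Path to the junction file.
#' @return Data frame with columns `read_id`, `chrom1`, `strand1`,
#'   `start1`, `cigar1`, `chrom2`, `strand2`, `start2`, `cigar2`,
#'   `junction_type`, `brk_donor`, `brk_acceptor`; attribute `rejects`
#'   holds a named count vector of skipped records.
#' @export
parse_chimeric_records <- function(path) {
  if (!file.exists(path)) stop("chimeric junction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(read_id = character(), chrom1 = character(),
                      strand1 = character(), start1 = integer(),
                      cigar1 = character(), chrom2 = character(),
                      strand2 = character(), start2 = integer(),
                      cigar2 = character(), junction_type = integer(),
                      brk_donor = integer(), brk_acceptor = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    attr(empty, "rejects") <- c(bad_cigar = 0L)
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- vapply(fields, function(x) identical(x[1L], "chr_donorA"), logical(1))
  fields <- fields[!hdr]
  lineno <- lineno[!hdr]
  if (length(fields) == 0L) {
    attr(empty, "rejects") <- c(bad_cigar = 0L)
    return(empty)
  }
  nf <- lengths(fields)
  if (any(nf < 14L)) {
    bad <- lineno[which(nf < 14L)[1L]]
    stop("line ", bad, ": expected >= 14 tab-separated columns, got ",
         nf[which(nf < 14L)[1L]])
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  rec <- data.frame(
    read_id = col(10L),
    chrom1 = col(1L), strand1 = col(3L),
    start1 = as.integer(col(11L)), cigar1 = col(12L),
    chrom2 = col(4L), strand2 = col(6L),
    start2 = as.integer(col(13L)), cigar2 = col(14L),
    junction_type = as.integer(col(7L)),
    brk_donor = as.integer(col(2L)), brk_acceptor = as.integer(col(5L)),
    stringsAsFactors = FALSE)
  ok1 <- cigar_ok(rec$cigar1)
  ok2 <- cigar_ok(rec$cigar2)
  bad_cigar <- sum(!(ok1 & ok2))
  rec <- rec[ok1 & ok2, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "rejects") <- c(bad_cigar = bad_cigar)
  rec
}

cigar_ok <- function(cigar) {
  grepl("^([0-9]+[MIDNSHPX=])+$", cigar) &
    grepl("[0-9]+[MDNX=]", cigar)
}

#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed by an alignment: the sum of the
#' lengths of `M`, `D`, `N`, `=` and `X` operations. Insertions and
#' clipping consume no reference.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference spans.
#' @examples
#' ref_span(c("30M", "10M5I20M", "10M100N10M"))
#' @export
ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- gregexpr("([0-9]+)([A-Z=])", cg)[[1L]]
    if (m[1L] == -1L) stop("unparseable CIGAR: ", cg)
    toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1L]]
    if (sum(nchar(toks)) != nchar(cg)) stop("unparseable CIGAR: ", cg)
    ops <- substr(toks, nchar(toks), nchar(toks))
    lens <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
    if (!all(ops %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X"))) {
      stop("unknown CIGAR opcode in: ", cg)
    }
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive back-splice junction coordinates from the two segments
#'
#' For reads whose segments lie on the same chromosome and strand in
#' inverted genomic order, the circular junction interval is recovered from
#' the segment reference starts and CIGAR spans. On the `+` strand the read
#' prefix (segment 1) maps to the 3' side of the circle, so
#' `junction_end = start1 + span1 - 1` and `junction_start = start2`;
#' on the `-` strand the mirror holds:
#' `junction_end = start2 + span2 - 1`, `junction_start = start1`.
#'
#' @param records Data frame as from [parse_chimeric_records()] (columns
#'   `chrom1`, `strand1`, `start1`, `cigar1`, `start2`, `cigar2`).
#' @return Data frame with `chrom`, `strand`, `junction_start`,
#'   `junction_end`, `span1`, `span2` (one row per input row; rows whose
#'   derived start is not strictly below the end carry `NA` coordinates).
#' @export
junction_from_segments <- function(records) {
  span1 <- ref_span(records$cigar1)
  span2 <- ref_span(records$cigar2)
  plus <- records$strand1 == "+"
  j_end <- ifelse(plus, records$start1 + span1 - 1L, records$start2 + span2 - 1L)
  j_start <- ifelse(plus, records$start2, records$start1)
  bad <- j_start >= j_end
  j_start[bad] <- NA_integer_
  j_end[bad] <- NA_integer_
  data.frame(chrom = records$chrom1, strand = records$strand1,
             junction_start = as.integer(j_start),
             junction_end = as.integer(j_end),
             span1 = span1, span2 = span2, stringsAsFactors = FALSE)
}

#' Select circular chimeric reads (CCRs)
#'
#' Applies the circular-read geometry rules to parsed chimeric records: the
#' two segments must map (a) to the same chromosome, (b) to the same
#' strand, (c) in inverted genomic order — on the `+` strand the read
#' prefix's reference start lies strictly downstream of the read suffix's
#' (mirrored on `-`) — and (d) both segment reference spans must reach the
#' minimal segment size (15 bp by default). Retained reads get back-splice
#' junction coordinates via [junction_from_segments()].
#'
#' @param records Parsed records from [parse_chimeric_records()].
#' @param min_segment Minimal reference span of the smaller segment (bp).
#' @return Data frame of CCRs (`read_id`, `chrom`, `strand`, `start`,
#'   `end`, `span1`, `span2`) with attribute `rejects`: counts per
#'   rejection reason (`trans_chrom`, `strand_mismatch`, `not_inverted`,
#'   `short_segment`, `inconsistent_junction`).
#' @export
select_ccrs <- function(records, min_segment = 15L) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), span1 = integer(), span2 = integer(),
                      stringsAsFactors = FALSE)
  rejects <- c(trans_chrom = 0L, strand_mismatch = 0L, not_inverted = 0L,
               short_segment = 0L, inconsistent_junction = 0L)
  if (nrow(records) == 0L) {
    attr(empty, "rejects") <- rejects
    return(empty)
  }
  same_chrom <- records$chrom1 == records$chrom2
  same_strand <- records$strand1 == records$strand2
  # evaluated hierarchically so each read is rejected for one reason
  alive <- rep(TRUE, nrow(records))
  rejects["trans_chrom"] <- sum(!same_chrom)
  alive <- alive & same_chrom
  rejects["strand_mismatch"] <- sum(alive & !same_strand)
  alive <- alive & same_strand
  inverted <- ifelse(records$strand1 == "+",
                     records$start1 > records$start2,
                     records$start1 < records$start2)
  rejects["not_inverted"] <- sum(alive & !inverted)
  alive <- alive & inverted
  jx <- junction_from_segments(records)
  long_enough <- pmin(jx$span1, jx$span2) >= min_segment
  rejects["short_segment"] <- sum(alive & !long_enough)
  alive <- alive & long_enough
  consistent <- !is.na(jx$junction_start)
  rejects["inconsistent_junction"] <- sum(alive & !consistent)
  alive <- alive & consistent
  out <- data.frame(read_id = records$read_id[alive],
                    chrom = jx$chrom[alive],
                    strand = jx$strand[alive],
                    start = jx$junction_start[alive],
                    end = jx$junction_end[alive],
                    span1 = jx$span1[alive],
                    span2 = jx$span2[alive],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}
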