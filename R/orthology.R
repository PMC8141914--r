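#' Junction-spanning sequence of a circRNA
#'
#' Builds the nucleotide sequence crossing the back-splice junction: the
#' last `flank` transcribed bases of the circle (ending at its 3' side)
#' concatenated with the first `flank` bases (starting at its 5' side),
#' 200 nt in total at the default flank of 100. On the `-` strand the
#' construction is the reverse complement of the `+` one. For circles
#' whose genomic size is below the flank, the sequence wraps around the
#' circle — the junction-crossing sequence is a property of the circular
#' transcript, which simply reads around the circle again.
#'
#' @param circ One catalog row (`chrom`, `strand`, `start`, `end`).
#' @param genome A `DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet()]) whose names include `circ$chrom`.
#' @param flank Bases on each side of the junction (default 100).
#' @return A `DNAString` of length `2 * flank`.
#' @export
junction_sequence <- function(circ, genome, flank = 100L) {
  if (!(circ$chrom %in% names(genome))) {
    stop("chromosome not in genome: ", circ$chrom)
  }
  chrom_seq <- genome[[circ$chrom]]
  if (circ$end > length(chrom_seq)) {
    stop("circRNA end ", circ$end, " beyond chromosome ", circ$chrom)
  }
  circle <- Biostrings::subseq(chrom_seq, circ$start, circ$end)
  L <- length(circle)
  if (L >= flank) {
    left <- Biostrings::subseq(chrom_seq, circ$end - flank + 1L, circ$end)
    right <- Biostrings::subseq(chrom_seq, circ$start, circ$start + flank - 1L)
  } else {
    reps <- Biostrings::DNAString(
      paste(rep(as.character(circle), ceiling(flank / L) + 1L), collapse = ""))
    nrep <- length(reps)
    left <- Biostrings::subseq(reps, nrep - flank + 1L, nrep)
    right <- Biostrings::subseq(reps, 1L, flank)
  }
  out <- Biostrings::xscat(left, right)
  if (circ$strand == "-") out <- Biostrings::reverseComplement(out)
  out
}

#' Junction sequences for a whole catalog
#'
#' @param catalog A `circ_catalog`.
#' @param genome A `DNAStringSet`.
#' @param flank Bases on each side of the junction.
#' @return A `DNAStringSet` named by circRNA id
#'   (`chrom:strand:start:end`).
#' @export
junction_sequences <- function(catalog, genome, flank = 100L) {
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(catalog)), function(i) {
    junction_sequence(catalog[i, ], genome, flank)
  }))
  names(seqs) <- circ_id(catalog)
  seqs
}

#' Best local-alignment hits between two sequence sets
#'
#' Aligns every query against every subject with a local (Smith-Waterman)
#' alignment under megablast-like scoring (match +2, mismatch -3, gap
#' open 5, gap extend 2) and reports each query's single best subject.
#' Queries whose best score stays below `min_score` get no hit; random
#' unrelated 200-mers score far below the default floor of 80, while even
#' substantially diverged homologs score far above it. Ties for the best
#' subject are flagged: a tied query cannot form an unambiguous ortholog
#' pair.
#'
#' @param seqs_a Query `DNAStringSet`.
#' @param seqs_b Subject `DNAStringSet`.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @param min_score Minimal reported score.
#' @return Data frame (`query`, `subject`, `score`, `identity_pct`,
#'   `aligned_length`, `tied`).
#' @export
best_hits <- function(seqs_a, seqs_b, match = 2L, mismatch = -3L,
                      gap_open = 5L, gap_ext = 2L, min_score = 80) {
  if (length(seqs_a) == 0L || length(seqs_b) == 0L) {
    stop("both sequence sets must be nonempty")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  scores <- matrix(NA_real_, nrow = length(seqs_a), ncol = length(seqs_b),
                   dimnames = list(names(seqs_a), names(seqs_b)))
  for (j in seq_along(seqs_b)) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      pattern = seqs_a, subject = seqs_b[[j]], type = "local",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
  }
  rows <- lapply(seq_along(seqs_a), function(i) {
    best <- max(scores[i, ])
    if (best < min_score) return(NULL)
    js <- which(scores[i, ] == best)
    j <- js[1L]
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs_a[[i]], subject = seqs_b[[j]], type = "local",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_ext)
    data.frame(query = names(seqs_a)[i], subject = names(seqs_b)[j],
               score = best, identity_pct = Biostrings::pid(aln),
               aligned_length = Biostrings::nchar(aln),
               tied = length(js) > 1L, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), identity_pct = numeric(),
                      aligned_length = integer(), tied = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two species' junction sequences
#'
#' A pair (a, b) is an orthologous circRNA candidate when b is a's best
#' hit and a is b's best hit, and neither side's best hit is tied
#' (ambiguous best hits are dropped rather than resolved arbitrarily).
#'
#' @param hits_ab Best-hit table, species A queries vs B subjects.
#' @param hits_ba Best-hit table, species B queries vs A subjects.
#' @return Data frame (`circ_a`, `circ_b`, `score_ab`, `score_ba`), a
#'   partial matching: no circRNA appears twice.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  ab <- hits_ab[!hits_ab$tied, , drop = FALSE]
  ba <- hits_ba[!hits_ba$tied, , drop = FALSE]
  back <- stats::setNames(ba$subject, ba$query)
  keep <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  keep[is.na(keep)] <- FALSE
  sc_ba <- stats::setNames(ba$score, ba$query)
  out <- data.frame(circ_a = ab$query[keep], circ_b = ab$subject[keep],
                    score_ab = ab$score[keep],
                    score_ba = unname(sc_ba[ab$subject[keep]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-level concordance of circRNA ortholog pairs
#'
#' Checks whether the parent genes of paired circRNAs are listed
#' one-to-one gene orthologs. Pairs with an unannotated parent on either
#' side cannot be assessed and are counted separately.
#'
#' @param pairs Output of [reciprocal_best_hits()].
#' @param parents_a,parents_b Named vectors mapping circ ids to parent
#'   gene ids (`NA` for unannotated).
#' @param ortholog_table Data frame with columns `gene_a`, `gene_b`
#'   (one-to-one orthologs).
#' @return List `n_pairs`, `n_assessable`, `n_concordant`, `fraction`
#'   (`NaN` when nothing is assessable).
#' @export
gene_concordance <- function(pairs, parents_a, parents_b, ortholog_table) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(n_pairs = 0L, n_assessable = 0L, n_concordant = 0L,
                fraction = NaN))
  }
  ga <- unname(parents_a[pairs$circ_a])
  gb <- unname(parents_b[pairs$circ_b])
  assessable <- !is.na(ga) & !is.na(gb)
  ortho_keys <- paste(ortholog_table$gene_a, ortholog_table$gene_b)
  concord <- assessable & paste(ga, gb) %in% ortho_keys
  list(n_pairs = n, n_assessable = sum(assessable),
       n_concordant = sum(concord),
       fraction = if (any(assessable)) sum(concord) / sum(assessable) else NaN)
}

#' Write junction sequences as FASTA
#'
#' @param seqs A named `DNAStringSet` from [junction_sequences()].
#' @param path Output FASTA.
#' @export
write_junction_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
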