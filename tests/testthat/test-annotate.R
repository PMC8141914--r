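# Uses the shared toy annotation:
#   GA (+): exons 101-200, 301-400, 601-700; introns 201-300, 401-600
#   GB (-): exons 1101-1300, 1501-1600; intron 1301-1500
#   GR (+, rRNA): exon 2001-2400

test_that("exonic calls need both boundaries on exons of one gene, same strand", {
  idx <- toy_index()
  hit <- classify_exonic(cand(start = 301, end = 700), idx)
  expect_equal(hit$gene_id, "GA")
  expect_equal(hit$exon_start_id, "GA.e2")

  # single-exon circle: the same exon provides both boundaries
  single <- classify_exonic(cand(start = 301, end = 400), idx)
  expect_equal(single$gene_id, "GA")

  # boundaries from two different (+) genes: multi_gene flag, not exonic
  multi <- classify_exonic(cand(start = 101, end = 2400), idx)
  expect_true(multi$multi_gene)
  expect_null(multi$gene_id)
  # start on GA (+) exon, end on GB exon, but GB is "-": end has no + exon
  expect_null(classify_exonic(cand(start = 101, end = 1600), idx))
  mg <- classify_exonic(cand(strand = "-", start = 1101, end = 1600), idx)
  expect_equal(mg$gene_id, "GB")

  # wrong strand never matches
  expect_null(classify_exonic(cand(strand = "-", start = 301, end = 700), idx))
})

test_that("sub-exonic calls are strictly inside one exon, sense or antisense", {
  idx <- toy_index()
  s <- classify_subexonic(cand(start = 150, end = 180), idx)
  expect_equal(s$sense, "sense")
  expect_equal(s$gene_id, "GA")

  anti <- classify_subexonic(cand(strand = "-", start = 150, end = 180), idx)
  expect_equal(anti$sense, "antisense")

  # touching a boundary is not "strictly within"
  expect_null(classify_subexonic(cand(start = 101, end = 180), idx))
  expect_null(classify_subexonic(cand(start = 150, end = 200), idx))

  # rRNA exons never host sub-exonic calls
  expect_null(classify_subexonic(cand(start = 2100, end = 2200), idx))
  permissive <- classifier_config(exclude_biotypes_subexonic = character())
  expect_equal(classify_subexonic(cand(start = 2100, end = 2200), idx,
                                  permissive)$gene_id, "GR")

  strict <- classifier_config(allow_antisense_subexonic = FALSE)
  expect_null(classify_subexonic(cand(strand = "-", start = 150, end = 180),
                                 idx, strict))
})

test_that("intronic calls anchor at the donor with a bounded acceptor offset", {
  idx <- toy_index()
  # + intron 201-300: donor 201, acceptor 300
  hit <- classify_intronic(cand(start = 201, end = 295), idx)
  expect_equal(hit$acceptor_offset, 5L)
  expect_equal(hit$gene_id, "GA")

  # 5' junction must equal the donor exactly
  expect_null(classify_intronic(cand(start = 205, end = 300), idx))

  # - intron 1301-1500: donor 1500, acceptor 1301
  m <- classify_intronic(cand(strand = "-", start = 1311, end = 1500), idx)
  expect_equal(m$acceptor_offset, 10L)

  # offset sweep on the 401-600 intron: largest accepted offset is 60
  accepted <- vapply(0:100, function(off) {
    !is.null(classify_intronic(cand(start = 401, end = 600 - off), idx))
  }, logical(1))
  expect_equal(max(which(accepted)) - 1L, 60L)
  expect_true(all(accepted[1:61]))
  expect_false(any(accepted[62:101]))
})

test_that("annotation assigns one primary class by precedence and keeps alternatives", {
  idx <- toy_index()
  cands <- rbind(
    cand(start = 101, end = 400),                 # exonic (GA e1..e2)
    cand(start = 201, end = 290),                 # intronic, offset 10
    cand(start = 620, end = 680),                 # sub-exonic sense in GA.e3
    cand(strand = "-", start = 1150, end = 1250), # sub-exonic sense in GB.e1
    cand(start = 1150, end = 1250),               # antisense of GB.e1
    cand(start = 5000, end = 5400),               # intergenic
    cand(start = 2100, end = 2200))               # inside rRNA: excluded
  ann <- annotate_catalog(cands, idx)
  expect_equal(ann$circ_class,
               c("exonic", "intronic", "sub_exonic", "sub_exonic",
                 "sub_exonic", "unannotated", "unannotated"))
  expect_equal(ann$sense[3:5], c("sense", "sense", "antisense"))
  expect_equal(as.integer(attr(ann, "class_summary")), c(1L, 1L, 3L, 2L, 0L))
  expect_true(all(table(ann$circ_class) ==
                    attr(ann, "class_summary")[names(table(ann$circ_class))]))

  # every candidate gets exactly one primary class
  expect_equal(sum(attr(ann, "class_summary")), nrow(cands))
})

test_that("boundary-exact candidates outrank their sub-exonic alternatives", {
  idx <- toy_index()
  # exonic single-exon circle is also NOT sub-exonic (not strictly inside);
  # precedence must still pick exonic even where both match, so build a
  # candidate matching exonic on GA and sub-exonic on nothing else.
  ann <- annotate_catalog(cand(start = 101, end = 200), idx)
  expect_equal(ann$circ_class, "exonic")
  expect_match(ann$all_matches, "exonic:GA")
})

test_that("planted mixtures are recovered class-for-class", {
  spec <- sim_spec(seed = 91)
  g <- make_genome(spec)
  pc <- plant_chimeric_file(spec, g)
  det <- detect_circrnas(pc$junction_file, read_length = spec$read_length)
  idx <- build_feature_index(g$models)
  ann <- annotate_catalog(det$annotatable, idx, size_excluded = det$size_excluded)
  m <- merge(data.frame(circ_id = circ_id(ann), got = ann$circ_class,
                        got_parent = ann$parent_gene_id,
                        got_count = ann$ccr_count, stringsAsFactors = FALSE),
             pc$truth, by = "circ_id")
  expect_equal(nrow(m), nrow(pc$truth))
  expect_identical(m$got, m$class)
  expect_identical(m$got_count, m$ccr_count)
  annotated <- !is.na(m$parent_gene)
  expect_identical(m$got_parent[annotated], m$parent_gene[annotated])
  # the multi-gene fusion-like candidate is flagged, not classified
  mg <- m[m$planted_as == "multi_gene", ]
  expect_match(ann$all_matches[match(mg$circ_id, circ_id(ann))], "multi_gene:")
})

test_that("acceptor tolerance and biotype exclusion act monotonically", {
  idx <- toy_index()
  cands <- rbind(cand(start = 401, end = 530),  # offset 70 intron call
                 cand(start = 401, end = 580),  # offset 20
                 cand(start = 2100, end = 2200))
  n_intronic <- function(tol) {
    cfg <- classifier_config(acceptor_tolerance = tol)
    sum(annotate_catalog(cands, idx, cfg)$circ_class == "intronic")
  }
  counts <- vapply(c(0, 20, 60, 70, 100), n_intronic, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts, c(0, 1, 1, 2, 2))

  n_sub <- function(excl) {
    cfg <- classifier_config(exclude_biotypes_subexonic = excl)
    sum(annotate_catalog(cands, idx, cfg)$circ_class == "sub_exonic")
  }
  expect_true(n_sub(character()) >= n_sub("rRNA"))
  expect_equal(n_sub(character()) - n_sub("rRNA"), 1)
})

test_that("per-gene sub-exonic profiles count exons and circles", {
  idx <- toy_index()
  cands <- rbind(cand(start = 120, end = 180), cand(start = 130, end = 190),
                 cand(start = 320, end = 380), cand(start = 620, end = 680))
  ann <- annotate_catalog(cands, idx)
  prof <- gene_subexonic_profile(ann)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$n_exons_involved, 3L)  # circles in 3 of GA's 3 exons
  expect_equal(prof$n_subexonic, 4L)
  expect_equal(prof$ccr_total, 20L)
  expect_equal(prof$biotype_class, "protein_coding")
  expect_equal(nrow(gene_subexonic_profile(annotate_catalog(
    cand(start = 5000, end = 5400), idx))), 0L)
})

test_that("unannotated cluster scan matches a sort-then-sweep oracle", {
  set.seed(404)
  # a dense clustered region plus scattered singletons, 40% clustered:
  # clustered gaps stay below the window, scattered gaps above it
  n_clustered <- 40; n_scattered <- 60
  clustered <- data.frame(chrom = "chr3",
                          start = 500000 + cumsum(sample(100:5000, n_clustered, TRUE)))
  clustered$end <- clustered$start + sample(60:200, n_clustered, replace = TRUE)
  scattered <- data.frame(chrom = "chr3",
                          start = 3e6 + cumsum(sample(20000:50000, n_scattered, TRUE)))
  scattered$end <- scattered$start + 100
  un <- rbind(clustered, scattered)
  ann <- data.frame(chrom = un$chrom, strand = "+", start = un$start,
                    end = un$end, ccr_count = 5L, dataset_id = "d",
                    genomic_size = un$end - un$start + 1L,
                    circ_class = "unannotated", stringsAsFactors = FALSE)
  got <- find_unannotated_clusters(ann, window = 10000, min_count = 10)
  expect_gte(nrow(got), 1L)
  main <- got[which.max(got$n_circ), ]
  expect_equal(main$n_circ, n_clustered)
  expect_equal(main$fraction_of_unannotated, 0.40)

  want <- sweep_clusters_oracle(ann, window = 10000, min_count = 10)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$n_circ, unname(want[, 3]))

  # merge-order invariance
  got2 <- find_unannotated_clusters(ann[sample(nrow(ann)), ],
                                    window = 10000, min_count = 10)
  expect_equal(got, got2)

  # uniform singletons form no cluster at min_count 10
  sparse <- ann[ann$start >= 3e6, ]
  expect_equal(nrow(find_unannotated_clusters(sparse, 10000, 10)), 0L)
})
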