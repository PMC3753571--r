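cassette_tm <- function() {
  transcript_models(
    transcript_id = rep(c("t1", "t2"), c(3L, 2L)),
    gene_id = "gA", strand = "+",
    start = c(0, 200, 400, 0, 400), end = c(100, 300, 500, 100, 500))
}

test_that("segment projection unions exon boundaries", {
  one <- transcript_models("t1", "g", "+", 100, 400)
  ps <- project_segments(one)
  expect_equal(nrow(ps$segments), 1L)
  expect_equal(ps$segments$length, 300)

  two <- transcript_models(rep(c("t1", "t2"), each = 2L), "g", "+",
                           start = c(0, 200, 0, 250), end = c(100, 300, 100, 300))
  ps2 <- project_segments(two)
  expect_equal(ps2$segments$tstart, c(0, 200, 250))
  expect_equal(ps2$segments$tend, c(100, 250, 300))

  dupd <- transcript_models(rep(c("t1", "t2"), each = 1L), "g", "+", 0, 100)
  expect_equal(nrow(project_segments(dupd)$segments), 1L)

  expect_error(transcript_models(rep("t1", 2L), "g", "+",
                                 start = c(0, 50), end = c(100, 150)),
               "overlapping")
})

test_that("line and exon graphs encode the cassette with one free parameter", {
  tm <- cassette_tm()
  for (fl in c("line", "exon")) {
    g <- build_graph(tm, fl)
    expect_length(validate_graph(g), 0L)
    expect_equal(length(g$ids) - 2L, 3L)
    expect_identical(free_parameter_count(g), 1L)
  }
})

test_that("unfactorized graphs have one disjoint path per transcript", {
  tm <- transcript_models(
    transcript_id = rep(sprintf("t%d", 1:3), each = 2L),
    gene_id = "g", strand = "+",
    start = c(0, 200, 0, 300, 0, 400),
    end = c(100, 250, 100, 350, 100, 450))
  g <- build_graph(tm, "unfactorized")
  iso <- enumerate_isoforms(g)
  expect_equal(nrow(iso), 3L)
  expect_equal(length(g$ids) - 2L, 6L)  # disjoint: no vertex sharing
})

test_that("order-2 exon graphs split vertices by left context", {
  tm <- transcript_models(
    transcript_id = rep(c("t1", "t2", "t3"), each = 3L),
    gene_id = "g", strand = "+",
    start = c(0, 100, 200,   50, 100, 300,   50, 100, 200),
    end   = c(90, 190, 290,  95, 190, 390,   95, 190, 290))
  g1 <- build_graph(tm, "exon", order = 1L)
  g2 <- build_graph(tm, "exon", order = 2L)
  ## order 1: X, Y, M, P, Q -> 5 internal; order 2 duplicates M per context
  expect_equal(length(g1$ids) - 2L, 5L)
  expect_equal(length(g2$ids) - 2L, 6L)
  ## locate the two M contexts via provenance (coordinates 100-190)
  prov <- g2$provenance
  Ms <- prov$id[!is.na(prov$start) & prov$start == 100]
  expect_length(Ms, 2L)
  outdeg <- lengths(g2$out)[match(Ms, g2$ids)]
  expect_setequal(outdeg, c(1L, 2L))  # (X,M) -> P only; (Y,M) -> {P, Q}
})

test_that("every annotated transcript is a complete path of the graph", {
  tm <- cassette_tm()
  for (fl in c("line", "exon", "unfactorized")) {
    g <- build_graph(tm, fl)
    for (ch in g$annotated_paths) {
      w <- subpath_weight(g, c("v0", ch, "vM"))  # errors if an edge is absent
      expect_gt(w, 0)
    }
  }
  ## line/exon admit a superset of annotated isoforms, unfactorized exactly
  gex <- build_graph(tm, "exon")
  gun <- build_graph(tm, "unfactorized")
  expect_gte(nrow(enumerate_isoforms(gex)), 2L)
  expect_identical(nrow(enumerate_isoforms(gun)), 2L)
})

test_that("construction is deterministic under input reordering", {
  tm <- cassette_tm()
  tm_shuf <- tm[rev(seq_len(nrow(tm))), ]
  class(tm_shuf) <- class(tm)
  g1 <- build_graph(tm, "exon")
  g2 <- build_graph(tm_shuf, "exon")
  expect_identical(g1$ids, g2$ids)
  expect_identical(g1$edges[c("from", "to", "weight")],
                   g2$edges[c("from", "to", "weight")])
})

test_that("minus-strand genes are normalized to transcription orientation", {
  genome <- list(chr = paste(rep(c("A", "C", "G", "T"), 250), collapse = ""))
  tm <- transcript_models(rep("t1", 2L), "gm", "-",
                          start = c(100, 300), end = c(200, 400),
                          chrom = "chr")
  g <- build_graph(tm, "line", genome = genome)
  ## first vertex in transcription order is the genomically-last exon
  first <- g$ids[2L]
  prov <- g$provenance[g$provenance$id == first, ]
  expect_equal(prov$start, 300)
  plus_seq <- substr(genome$chr, 301, 400)
  expect_identical(unname(g$seq[first]),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(plus_seq))))
})

test_that("reference windows cover junctions, short vertices and poly(A)", {
  g <- make_toy_graph("G1")
  w <- extract_reference_sequences(g, 50L)
  bc <- w[w$chain == "B,C", ]
  expect_equal(nchar(bc$seq), 98L)  # 49 + 49
  expect_equal(bc$offset, 1L)
  ## poly(A) record for the 3' end
  expect_true("E,vM" %in% w$chain)
  expect_match(w$seq[w$chain == "E,vM"], "A{49}$")
  ## L = 1: vertex records only
  w1 <- extract_reference_sequences(g, 1L)
  expect_equal(nrow(w1), 5L)

  ## a vertex shorter than L - 1 forces three-vertex windows
  gs <- splice_graph("short",
    data.frame(id = c("v0", "a", "m", "b", "vM"),
               seq = c("", strrep("ACGT", 25), "ACGTACGTAC",
                       strrep("TGCA", 25), "")),
    data.frame(from = c("v0", "a", "m", "b"), to = c("a", "m", "b", "vM"),
               weight = 1))
  ws <- extract_reference_sequences(gs, 50L)
  expect_true("a,m,b" %in% ws$chain)
})

test_that("windows are complete: every simulated read aligns at its placement", {
  for (s in c(2L, 5L)) {
    g <- random_psg(n_internal = 5L, seed = s, len_range = c(15L, 80L))
    L <- 30L
    win <- extract_reference_sequences(g, L)
    sim <- simulate_fragments(g, 40L, L, error_rate = 0, seed = s + 100L)
    for (i in seq_len(nrow(sim$truth))) {
      r <- sim$reads$seq1[i]
      hit <- FALSE
      for (j in seq_len(nrow(win)))
        if (grepl(r, win$seq[j], fixed = TRUE)) { hit <- TRUE; break }
      expect_true(hit, info = sprintf("seed %d read %d", s, i))
    }
  }
})
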