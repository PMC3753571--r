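test_that("census certifies the two-cassette gene and detects duplication", {
  g <- make_toy_graph("G1")
  cen <- unique_read_census(g, 50L)
  chk <- check_identifiability(g, cen)
  expect_true(chk$certified)
  expect_true(all(chk$table$pass))

  ## two byte-identical copies of the gene: no unique windows anywhere
  g2 <- g; g2$gene_id <- "G1copy"
  cen2 <- unique_read_census(list(g, g2), 50L)
  expect_false(any(cen2[["G1"]]$edge_unique))
  expect_false(any(cen2[["G1"]]$vertex_unique))
  chk2 <- check_identifiability(g, cen2)
  expect_false(chk2$certified)
  expect_true(all(chk2$table$condition == "none"))
})

test_that("single-vertex genes certify through the vertex condition", {
  solo_seq <- withr::with_seed(5L, rand_dna(100L))
  g <- splice_graph("solo",
    data.frame(id = c("v0", "a", "vM"), seq = c("", solo_seq, "")),
    data.frame(from = c("v0", "a"), to = c("a", "vM"), weight = 1))
  cen <- unique_read_census(g, 30L)
  expect_true(cen[["solo"]]$vertex_unique["a"])
  expect_true(check_identifiability(g, cen)$certified)
})

test_that("an edge whose target repeats elsewhere and has no unique junction fails", {
  ## vertex y's sequence equals vertex z's (a repeated 60-mer), and x -> y's
  ## junction window also occurs at x -> z: the edge x -> y cannot be
  ## certified by either condition
  rep60 <- strrep("ACGTTG", 10L)
  withr::with_seed(99L, {
    xs <- rand_dna(80L); ss <- rand_dna(80L)
  })
  g <- splice_graph("rep",
    data.frame(id = c("v0", "x", "y", "z", "s", "vM"),
               seq = c("", xs, rep60, rep60, ss, "")),
    data.frame(from = c("v0", "x", "x", "y", "z", "s"),
               to = c("x", "y", "z", "s", "s", "vM"),
               weight = c(1, 0.5, 0.5, 1, 1, 1)))
  cen <- unique_read_census(g, 30L)
  chk <- check_identifiability(g, cen)
  expect_false(chk$certified)
  bad <- chk$table[chk$table$from == "x", ]
  expect_true(all(!bad$pass))
})

test_that("the full-isoform model of the two-cassette gene admits a witness", {
  g <- make_toy_graph("G1")
  wit <- demonstrate_nonidentifiability(g, 100L)
  expect_false(is.null(wit))
  expect_lt(wit$max_placement_diff, 1e-12)
  expect_gt(max(abs(wit$theta1 - wit$theta2)), 0.05)
  ## expected transcript lengths agree (the distributions must match)
  expect_equal(sum(wit$theta1 * wit$isoforms$length),
               sum(wit$theta2 * wit$isoforms$length))

  ## the defining property: identical data log-likelihoods under both
  ## frequency vectors, on reads simulated from the unfactorized model
  tm <- transcript_models(
    transcript_id = rep(sprintf("t%d", 1:4),
                        times = c(5L, 4L, 4L, 3L)),
    gene_id = "G1u", strand = "+",
    start = c(0, 100, 150, 350, 400,
              0, 100, 150, 400,
              0, 150, 350, 400,
              0, 150, 400),
    end = c(100, 150, 350, 400, 500,
            100, 150, 350, 500,
            100, 350, 400, 500,
            100, 350, 500))
  genome <- list(chr = paste(c(substring(g$seq["A"], 1, 100),
                               substring(g$seq["B"], 1, 50),
                               substring(g$seq["C"], 1, 200),
                               substring(g$seq["D"], 1, 50),
                               substring(g$seq["E"], 1, 100)), collapse = ""))
  gu <- build_graph(tm, "unfactorized", genome = genome)
  iso_u <- enumerate_isoforms(gu)
  stopifnot(nrow(iso_u) == 4L)
  ## map witness isoforms onto gu's paths by their spliced sequences
  spliced <- function(gx, paths) vapply(strsplit(paths, ","), function(p)
    paste(gx$seq[p], collapse = ""), "")
  seq_wit <- spliced(g, wit$isoforms$path)
  seq_u <- spliced(gu, iso_u$path)
  ord <- match(seq_u, seq_wit)   # gu isoform i corresponds to witness ord[i]
  stopifnot(!anyNA(ord))
  v0_rows <- which(gu$edges$from == "v0")
  v0_iso <- match(vapply(strsplit(iso_u$path, ","), `[`, "", 1L),
                  gu$edges$to[v0_rows])
  set_theta <- function(th) {
    w <- gu$edges$weight
    w[v0_rows[v0_iso]] <- th[ord]
    set_edge_weights(gu, w)
  }
  g1 <- set_theta(wit$theta1)
  sim <- simulate_fragments(g1, 150L, 100L, seed = 8L)
  ## reads must carry all their placements: the duplicated transcript copies
  ## share sequences, so every read multi-maps across compatible isoforms
  plc <- do.call(rbind, lapply(seq_len(150L), function(i) {
    al <- align_read(gu, sim$reads$seq1[i])
    data.frame(read = i, chain = al$chain, stringsAsFactors = FALSE)
  }))
  ds <- psg_dataset(gu, plc)
  ll1 <- dataset_log_likelihood(set_theta(wit$theta1), ds)
  ll2 <- dataset_log_likelihood(set_theta(wit$theta2), ds)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("long reads spanning both cassettes remove the witness", {
  g <- make_toy_graph("G1")
  expect_null(demonstrate_nonidentifiability(g, 210L))
  single <- splice_graph("solo",
    data.frame(id = c("v0", "a", "vM"), seq = c("", strrep("ACGT", 30L), "")),
    data.frame(from = c("v0", "a"), to = c("a", "vM"), weight = 1))
  expect_null(demonstrate_nonidentifiability(single, 50L))
})

test_that("certified graphs yield stable, distinguishable EM estimates", {
  g <- make_toy_graph("G1")
  stopifnot(check_identifiability(g, unique_read_census(g, 50L))$certified)
  galt <- make_toy_graph("G1", p1 = 0.8, p2 = 0.6)
  fits <- lapply(list(g, galt), function(gt) {
    sim <- simulate_fragments(gt, 50000L, 50L, emit_reads = FALSE, seed = 17L)
    run_em(g, dataset_from_truth(g, sim$truth))
  })
  ## distinct truths recover distinct estimates
  expect_gt(max(vertex_distance(g, fits[[1]], fits[[2]])), 0.2)
  expect_lt(max(vertex_distance(g, fits[[1]], g$edges$weight)), 0.02)
  expect_lt(max(vertex_distance(g, fits[[2]], galt$edges$weight)), 0.02)
})
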