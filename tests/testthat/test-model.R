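test_that("align_read finds within-vertex, junction and poly(A) placements", {
  g <- make_toy_graph("G1")
  a <- align_read(g, substr(g$seq["C"], 51, 100))
  expect_equal(nrow(a), 1L)
  expect_identical(a$chain, "C")
  expect_identical(a$b, 50L)

  aj <- align_read(g, paste0(substr(g$seq["B"], 26, 50),
                             substr(g$seq["C"], 1, 25)))
  expect_identical(aj$chain, "B,C")
  expect_identical(aj$b, 25L)

  apa <- align_read(g, paste0(substr(g$seq["E"], 71, 100), strrep("A", 20)))
  expect_identical(apa$chain, "E,vM")  # overhang certifies the transcript end
  expect_identical(apa$polya, 20L)

  expect_equal(nrow(align_read(g, strrep("N", 30))), 0L)
  ## one mismatch tolerated only when allowed
  r <- substr(g$seq["C"], 51, 100)
  substr(r, 10, 10) <- if (substr(r, 10, 10) == "A") "C" else "A"
  expect_equal(nrow(align_read(g, r, max_mismatch = 0L)), 0L)
  expect_equal(align_read(g, r, max_mismatch = 1L)$mm, 1L)
})

test_that("read marginals match the closed form and the enumeration oracle", {
  g <- make_toy_graph("G1")
  a <- data.frame(chain = "C", b = 10L, mm = 0L, polya = 0L)
  expect_equal(read_log_marginal(g, a, 50L), log(1 / 437.5))
  aj <- data.frame(chain = "A,B", b = 80L, mm = 0L, polya = 0L)
  expect_equal(read_log_marginal(g, aj, 50L), log(0.5 / 437.5))
  ## a mismatching alignment contributes nothing at error rate 0
  am <- data.frame(chain = c("C", "D"), b = c(10L, 5L), mm = c(0L, 2L),
                   polya = 0L)
  expect_equal(read_log_marginal(g, am, 50L, error_rate = 0),
               log(1 / 437.5))
  expect_true(is.infinite(read_log_marginal(g, a[0, ], 50L)))

  for (s in 1:10) {
    gr <- random_psg(n_internal = 2L + (s %% 5L), seed = 50L + s,
                     len_range = c(20L, 60L))
    sim <- simulate_fragments(gr, 5L, 20L, error_rate = 0, seed = s)
    for (i in 1:5) {
      al <- align_read(gr, sim$reads$seq1[i])
      expect_gt(nrow(al), 0L)
      expect_equal(read_log_marginal(gr, al, 20L),
                   log(oracle_read_marginal(gr, al, 20L)),
                   tolerance = 1e-9)
    }
  }
})

test_that("fragment marginals handle point-mass lengths and spanning paths", {
  single <- splice_graph("single",
    data.frame(id = c("v0", "a", "vM"),
               seq = c("", paste(rep(c("A","C","G","T"), 75), collapse = ""), "")),
    data.frame(from = c("v0", "a"), to = c("a", "vM"), weight = 1))
  flm <- fragment_length_model(200)
  a1 <- data.frame(chain = "a", b = 0L, mm = 0L, polya = 0L)
  a2 <- data.frame(chain = "a", b = 150L, mm = 0L, polya = 0L)
  expect_equal(fragment_log_marginal(single, a1, a2, flm, 50L),
               log(1 / 300))
  ## no compatible spanning subpath
  a2bad <- data.frame(chain = "a", b = 10L, mm = 0L, polya = 0L)
  expect_true(is.infinite(
    fragment_log_marginal(single, a2, a2bad, flm, 50L)))

  g <- make_toy_graph("G1")
  ## mate1 in B, mate2 in D: feasible only along A,B,C,D,E
  m1 <- data.frame(chain = "B", b = 0L, mm = 0L, polya = 0L)
  m2 <- data.frame(chain = "D", b = 0L, mm = 0L, polya = 0L)
  f0 <- 50L + 200L + 50L  # B start to D end
  expect_equal(fragment_log_marginal(g, m1, m2, fragment_length_model(f0), 50L),
               log(0.125 * 1 / 437.5))
})

test_that("dataset log-likelihood is additive and matches brute force", {
  g <- make_toy_graph("G1")
  empty <- psg_dataset(g, data.frame(read = character(0), chain = character(0)))
  expect_identical(dataset_log_likelihood(g, empty), 0)

  sim <- simulate_fragments(g, 20L, 50L, error_rate = 0, seed = 9L)
  ds <- dataset_from_truth(g, sim$truth)
  per_read <- vapply(sim$truth$chain, function(ch)
    log(oracle_read_marginal(g, data.frame(chain = ch, mm = 0L), 50L)), 0)
  expect_equal(dataset_log_likelihood(g, ds), sum(per_read), tolerance = 1e-9)
})

test_that("placement measure is complete for length-1 reads", {
  ## sum over all (s, b) of F(v0, first) w(s) / mu = 1: for L = 1 every
  ## placement is a single base of a single vertex
  for (s in c(3L, 8L)) {
    g <- random_psg(n_internal = 2L + s %% 7L, seed = 30L + s,
                    len_range = c(5L, 30L))
    Fv0 <- inclusion_probability(g, "v0")
    mu <- expected_lengths(g)$mu
    tot <- sum(Fv0[g$ids] * g$len[g$ids]) / mu
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("simulated start vertices and paths follow the model", {
  single <- splice_graph("single",
    data.frame(id = c("v0", "a", "vM"),
               seq = c("", paste(rep(c("A","C","G","T"), 50), collapse = ""), "")),
    data.frame(from = c("v0", "a"), to = c("a", "vM"), weight = 1))
  sim <- simulate_fragments(single, 50000L, 10L, emit_reads = FALSE, seed = 2L)
  expect_true(all(sim$truth$path == "a"))
  tab <- table(factor(sim$truth$b %/% 20L, levels = 0:9))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  g <- make_toy_graph("G1")
  sim2 <- simulate_fragments(g, 100000L, 100L, emit_reads = FALSE, seed = 4L)
  fb <- mean(grepl("(^|,)B(,|$)", sim2$truth$path))
  p_true <- 231.25 / 437.5
  expect_lt(abs(fb - p_true), 3 * sqrt(p_true * (1 - p_true) / 100000))
  ## start-vertex frequencies match F(v0,i) l(i) / mu within 4 sigma
  first_v <- vapply(strsplit(sim2$truth$chain, ","), `[`, "", 1L)
  Fv0 <- inclusion_probability(g, "v0")
  mu <- expected_lengths(g)$mu
  for (v in c("A", "B", "C", "D", "E")) {
    p <- unname(Fv0[v] * g$len[v] / mu)
    obs <- mean(first_v == v)
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / 100000) + 1e-12)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  g <- make_toy_graph("G1")
  s1 <- simulate_fragments(g, 200L, 50L, flm = fragment_length_model(150, 10),
                           error_rate = 0.005, seed = 42L)
  s2 <- simulate_fragments(g, 200L, 50L, flm = fragment_length_model(150, 10),
                           error_rate = 0.005, seed = 42L)
  expect_identical(s1, s2)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a_1.fq"); f2 <- file.path(td, "a_2.fq")
  g1 <- file.path(td, "b_1.fq"); g2 <- file.path(td, "b_2.fq")
  write_fastq(s1$reads, f1, f2)
  write_fastq(s2$reads, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("error-free simulated reads re-align to their truth placement", {
  g <- make_toy_graph("G1")
  sim <- simulate_fragments(g, 30L, 60L, error_rate = 0, seed = 5L)
  for (i in seq_len(30L)) {
    al <- align_read(g, sim$reads$seq1[i])
    key <- paste(al$chain, al$b)
    expect_true(paste(sim$truth$chain[i], sim$truth$b_chain[i]) %in% key)
  }
})
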