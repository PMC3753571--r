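test_that("E-step expected counts match the posterior enumeration oracle", {
  g <- make_toy_graph("G1")
  ds <- psg_dataset(g, data.frame(read = "r1", chain = "C"))
  es <- e_step(g, ds)
  expect_equal(unname(es$edge_counts[c("A->B", "A->C", "C->D", "C->E",
                                       "v0->A", "E->vM")]),
               c(0.5, 0.5, 0.25, 0.75, 1, 1))
  ds2 <- psg_dataset(g, data.frame(read = "r1", chain = "B,C"))
  es2 <- e_step(g, ds2)
  expect_equal(unname(es2$edge_counts[c("A->B", "A->C", "C->D")]),
               c(1, 0, 0.25))
  empty <- psg_dataset(g, data.frame(read = character(0), chain = character(0)))
  expect_true(all(e_step(g, empty)$counts == 0))

  ## random graphs, multi-placement reads, against the oracle
  for (s in 1:8) {
    gr <- random_psg(n_internal = 3L + (s %% 4L), seed = 70L + s,
                     len_range = c(20L, 50L))
    sim <- simulate_fragments(gr, 6L, 25L, error_rate = 0, seed = s)
    plc <- do.call(rbind, lapply(seq_len(6L), function(i) {
      al <- align_read(gr, sim$reads$seq1[i])
      data.frame(read = i, chain = al$chain, stringsAsFactors = FALSE)
    }))
    ds <- psg_dataset(gr, plc)
    es <- e_step(gr, ds)
    oracle <- Reduce(`+`, lapply(split(plc, plc$read), function(d)
      oracle_estep_read(gr, data.frame(chain = d$chain, mm = 0L), 25L)))
    expect_equal(unname(es$edge_counts), unname(oracle[names(es$edge_counts)]),
                 tolerance = 1e-9)
  }
})

test_that("sufficient statistics conserve flow through always-included vertices", {
  g <- make_toy_graph("G1")
  sim <- simulate_fragments(g, 3000L, 80L, emit_reads = FALSE, seed = 12L)
  es <- e_step(g, dataset_from_truth(g, sim$truth))
  Fv0 <- inclusion_probability(g, "v0")
  for (v in c("A", "C", "E")) {
    i <- match(v, g$ids)
    expect_equal(sum(es$counts[g$inn[[i]]]), es$n, tolerance = 1e-6)
    expect_equal(sum(es$counts[g$out[[i]]]), es$n, tolerance = 1e-6)
  }
  expect_true(all(es$counts >= 0))
})

test_that("multinomial M-step normalizes pseudocounted expected counts", {
  g <- make_toy_graph("cassette")
  es <- structure(list(counts = numeric(nrow(g$edges)), n = 100),
                  class = "psg_suffstats")
  ek <- paste0(g$edges$from, "->", g$edges$to)
  es$counts[ek == "E1->E2"] <- 30
  es$counts[ek == "E1->E3"] <- 70
  es$counts[ek %in% c("v0->E1", "E2->E3", "E3->vM")] <- 100
  w <- m_step(g, es, variant = "multinomial")
  expect_equal(w[ek == "E1->E2"], 0.3)

  g2 <- psg_set_beta(g, 2)
  es$counts[ek == "E1->E2"] <- 3
  es$counts[ek == "E1->E3"] <- 1
  w2 <- m_step(g2, es, variant = "multinomial")
  expect_equal(w2[ek == "E1->E2"], 4 / 6)
  g3 <- psg_set_beta(g, 0.1)
  es$counts[ek == "E1->E2"] <- 0   # count 0 with beta < 1: negative numerator
  expect_error(m_step(g3, es, variant = "multinomial"), "degenerate")
})

test_that("exact and multinomial M-steps agree when all paths share a length", {
  ## mutually exclusive equal-length alternatives: mu is constant in alpha
  vs <- data.frame(id = c("v0", "S0", "X", "Y", "S1", "vM"),
                   seq = c("", strrep("AC", 50), strrep("GT", 40),
                           strrep("TG", 40), strrep("CA", 50), ""))
  ed <- data.frame(from = c("v0", "S0", "S0", "X", "Y", "S1"),
                   to = c("S0", "X", "Y", "S1", "S1", "vM"),
                   weight = c(1, 0.5, 0.5, 1, 1, 1))
  g <- splice_graph("eq", vs, ed)
  sim <- simulate_fragments(g, 2000L, 40L, emit_reads = FALSE, seed = 3L)
  ds <- dataset_from_truth(g, sim$truth)
  f1 <- run_em(g, ds, variant = "exact")
  f2 <- run_em(g, ds, variant = "multinomial")
  expect_equal(unname(f1$alpha), unname(f2$alpha), tolerance = 1e-9)
})

test_that("EM recovers simulated parameters and keeps a monotone trace", {
  g <- make_toy_graph("G1")
  sim <- simulate_fragments(g, 10000L, 100L, emit_reads = FALSE, seed = 21L)
  ds <- dataset_from_truth(g, sim$truth)
  ## the exact variant handles the N log mu(alpha) term and is unbiased here
  fit <- run_em(g, ds, variant = "exact")
  expect_true(fit$converged)
  expect_lt(max(vertex_distance(g, fit, g$edges$weight)), 0.02)
  expect_true(all(diff(fit$trace) > -1e-8))
  ## the multinomial approximation still ascends the posterior monotonically,
  ## but with unequal path lengths its fixed point is biased
  fitm <- run_em(g, ds, variant = "multinomial")
  expect_true(fitm$converged)
  expect_true(all(diff(fitm$trace) > -1e-8))
  expect_lte(fitm$loglik, fit$loglik + 1e-6)
})

test_that("EM on an unfactorized graph equals the full-length-isoform EM", {
  for (s in 1:6) {
    k <- 3L + (s %% 3L)
    tm <- transcript_models(
      transcript_id = rep(sprintf("t%d", 1:k), each = 2L),
      gene_id = "g", strand = "+",
      start = c(rbind(0, 100 + 70 * (1:k))),
      end = c(rbind(80, 160 + 70 * (1:k))))
    withr::with_seed(200L + s, {
      genome <- NULL
      g <- build_graph(tm, "unfactorized")
      ## give it random sequences and random isoform frequencies
      vs <- data.frame(id = g$ids,
                       seq = c("", vapply(g$len[-c(1, length(g$ids))],
                                          function(l) paste(sample(c("A","C","G","T"),
                                                                   l, TRUE), collapse = ""), ""), ""))
      g <- splice_graph("g", vs, g$edges[c("from", "to", "weight")])
      th <- rdirichlet1(k)
      w <- g$edges$weight
      w[g$edges$from == "v0"] <- th
      g <- set_edge_weights(g, w)
    })
    sim <- simulate_fragments(g, 400L, 40L, emit_reads = FALSE, seed = 300L + s)
    ds <- dataset_from_truth(g, sim$truth)
    fit <- run_em(g, ds, tol = 1e-12)
    iso_fit <- isoform_frequencies(fit)
    tab <- truth_chain_counts(sim$truth)
    oracle <- oracle_full_isoform_em(g, as.list(tab$chain), tab$n)
    m <- match(oracle$path, iso_fit$path)
    expect_false(anyNA(m))
    expect_lt(max(abs(iso_fit$prob[m] - oracle$freq)), 1e-6)
  }
})

test_that("EM with no fragments returns the prior mean", {
  g <- psg_set_beta(make_toy_graph("G1"), 2)
  empty <- psg_dataset(g, data.frame(read = character(0), chain = character(0)))
  fit <- run_em(g, empty)
  expect_equal(unname(fit$alpha[c("A->B", "A->C")]), c(0.5, 0.5))
})

test_that("junction-read estimator counts junction placements with pseudocounts", {
  g <- make_toy_graph("G1")
  plc <- data.frame(
    read = c(1:3, 4L, 5L),
    chain = c("A,B", "A,B", "A,B", "A,C", "C"),
    stringsAsFactors = FALSE)
  jr <- junction_read_estimator(g, psg_dataset(g, plc), pseudocount = 1)
  expect_equal(unname(jr$alpha[c("A->B", "A->C")]), c(4 / 6, 2 / 6))
  ## no junction reads anywhere: uniform
  jr0 <- junction_read_estimator(g,
    psg_dataset(g, data.frame(read = 1L, chain = "C")), pseudocount = 1)
  expect_equal(unname(jr0$alpha[c("C->D", "C->E")]), c(0.5, 0.5))
  expect_error(junction_read_estimator(g, psg_dataset(g, plc), pseudocount = -1))

  ## consistency: close to truth at large n
  sim <- simulate_fragments(g, 100000L, 100L, emit_reads = FALSE, seed = 31L)
  jrc <- junction_read_estimator(g, dataset_from_truth(g, sim$truth))
  expect_lt(max(vertex_distance(g, jrc, g$edges$weight)[c("A", "C")]), 0.01)
})

test_that("vertex distances are symmetric infinity norms per branch vertex", {
  g <- make_toy_graph("G1")
  a <- g$edges$weight
  expect_true(all(vertex_distance(g, a, a) == 0))
  b <- a
  b[g$edges$from == "A"] <- c(0.5, 0.5)
  a[g$edges$from == "A"] <- c(0.3, 0.7)
  d <- vertex_distance(g, a, b)
  expect_equal(unname(d["A"]), 0.2)
  expect_identical(vertex_distance(g, a, b), vertex_distance(g, b, a))
  expect_true(all(d <= 1))
})

test_that("bootstrap distances shrink with sample size; EM converges faster than JR", {
  g <- make_toy_graph("G1")
  sim <- simulate_fragments(g, 20000L, 100L, emit_reads = FALSE, seed = 41L)
  ds <- dataset_from_truth(g, sim$truth)
  sizes <- c(100L, 1000L, 10000L)
  bem <- bootstrap_convergence(g, ds, sizes, replicates = 30L,
                               estimator = "em", seed = 7L)
  bjr <- bootstrap_convergence(g, ds, sizes, replicates = 30L,
                               estimator = "jr", seed = 7L)
  expect_true(all(diff(bem$mean_distance) < 0.02))   # non-increasing + noise
  expect_true(all(diff(bjr$mean_distance) < 0.02))
  expect_true(all(bem$mean_distance <= bjr$mean_distance + 0.005))
})
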