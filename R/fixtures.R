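## ---------------------------------------------------------------------------
## Programmatic fixtures: deterministic toy graphs, random valid PSGs and the
## two-condition differential-processing benchmark.  All randomness is seeded
## through withr::with_seed so fixtures are reproducible and do not disturb
## the caller's RNG stream.
## ---------------------------------------------------------------------------

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rdirichlet1 <- function(k, conc = 1) {
  x <- stats::rgamma(k, conc)
  x / sum(x)
}

#' Deterministic toy splice graphs
#'
#' Named fixtures used throughout the package's tests and documentation:
#' \describe{
#'   \item{`G1`}{A two-independent-cassette gene: internal vertices
#'     `A`(100 nt), `B`(50), `C`(200), `D`(50), `E`(100); edges
#'     `v0->A`:1, `A->B`:p1, `A->C`:1-p1, `B->C`:1, `C->D`:p2, `C->E`:1-p2,
#'     `D->E`:1, `E->vM`:1.  Four isoforms; two free parameters.}
#'   \item{`cassette`}{A single cassette exon (one free parameter).}
#'   \item{`four_domain`}{A chain of four mutually exclusive choice blocks
#'     with 12, 48, 33 and 2 alternatives: 38,016 possible isoforms, the
#'     regime where per-isoform enumeration is infeasible but the PSG
#'     dynamic programs stay polynomial.}
#' }
#' Vertex sequences are random but fixed by `seed`.
#'
#' @param name One of `"G1"`, `"cassette"`, `"four_domain"`.
#' @param p1,p2 Branch probabilities for `G1` (`p1` also used by `cassette`).
#' @param seed Seed for the vertex sequences.
#' @return A valid `splice_graph`.
#' @export
make_toy_graph <- function(name = c("G1", "cassette", "four_domain"),
                           p1 = 0.5, p2 = 0.25, seed = 20260930L) {
  name <- match.arg(name)
  withr::with_seed(seed, {
    switch(name,
      G1 = {
        lens <- c(A = 100L, B = 50L, C = 200L, D = 50L, E = 100L)
        vertices <- data.frame(
          id = c("v0", names(lens), "vM"),
          seq = c("", vapply(lens, rand_dna, ""), ""),
          stringsAsFactors = FALSE)
        edges <- data.frame(
          from = c("v0", "A", "A", "B", "C", "C", "D", "E"),
          to = c("A", "B", "C", "C", "D", "E", "E", "vM"),
          weight = c(1, p1, 1 - p1, 1, p2, 1 - p2, 1, 1),
          stringsAsFactors = FALSE)
        splice_graph("G1", vertices, edges)
      },
      cassette = {
        lens <- c(E1 = 150L, E2 = 80L, E3 = 150L)
        vertices <- data.frame(
          id = c("v0", names(lens), "vM"),
          seq = c("", vapply(lens, rand_dna, ""), ""),
          stringsAsFactors = FALSE)
        edges <- data.frame(
          from = c("v0", "E1", "E1", "E2", "E3"),
          to = c("E1", "E2", "E3", "E3", "vM"),
          weight = c(1, p1, 1 - p1, 1, 1),
          stringsAsFactors = FALSE)
        splice_graph("cassette", vertices, edges)
      },
      four_domain = {
        sizes <- c(12L, 48L, 33L, 2L)
        vid <- "S0"; vseq <- rand_dna(150L)
        ef <- character(0); et <- character(0); ew <- numeric(0)
        prev <- "S0"
        for (b in seq_along(sizes)) {
          alts <- sprintf("D%da%d", b, seq_len(sizes[b]))
          sp <- sprintf("S%d", b)
          vid <- c(vid, alts, sp)
          vseq <- c(vseq, vapply(rep(60L, sizes[b]), rand_dna, ""), rand_dna(150L))
          ef <- c(ef, rep(prev, sizes[b]), alts)
          et <- c(et, alts, rep(sp, sizes[b]))
          ew <- c(ew, rep(1 / sizes[b], sizes[b]), rep(1, sizes[b]))
          prev <- sp
        }
        vertices <- data.frame(id = c("v0", vid, "vM"),
                               seq = c("", vseq, ""), stringsAsFactors = FALSE)
        edges <- data.frame(from = c("v0", ef, prev),
                            to = c("S0", et, "vM"),
                            weight = c(1, ew, 1), stringsAsFactors = FALSE)
        splice_graph("four_domain", vertices, edges)
      })
  })
}

#' Random valid PSG
#'
#' Generates a random DAG over `n_internal` sequence-carrying vertices in a
#' fixed topological order, guaranteeing a unique source and sink, full
#' reachability/co-reachability and Dirichlet-distributed out-edge simplexes.
#' Used for property-style tests against enumeration oracles.
#'
#' @param n_internal Number of internal vertices (small; enumeration-friendly).
#' @param seed Seed.
#' @param len_range Vertex sequence length range.
#' @param p_extra Probability of each feasible extra edge.
#' @param gene_id Gene identifier.
#' @return A valid `splice_graph`.
#' @export
random_psg <- function(n_internal = 6L, seed = 1L, len_range = c(60L, 160L),
                       p_extra = 0.3, gene_id = sprintf("rg%d", seed)) {
  stopifnot(n_internal >= 1L)
  withr::with_seed(seed, {
    ids <- sprintf("x%d", seq_len(n_internal))
    ef <- character(0); et <- character(0)
    add <- function(a, b) { ef <<- c(ef, a); et <<- c(et, b) }
    ## backbone keeps every vertex connected
    for (i in seq_len(n_internal - 1L)) add(ids[i], ids[i + 1L])
    ## random skip edges
    if (n_internal >= 3L)
      for (i in seq_len(n_internal - 2L))
        for (j in seq(i + 2L, n_internal))
          if (stats::runif(1) < p_extra) add(ids[i], ids[j])
    add("v0", ids[1L])
    add(ids[n_internal], "vM")
    ## alternative starts / polyadenylation sites
    if (n_internal >= 2L)
      for (i in seq(2L, n_internal))
        if (stats::runif(1) < 0.15) add("v0", ids[i])
    if (n_internal >= 2L)
      for (i in seq_len(n_internal - 1L))
        if (stats::runif(1) < 0.15) add(ids[i], "vM")
    keep <- !duplicated(paste(ef, et))
    ef <- ef[keep]; et <- et[keep]
    lens <- sample(seq(len_range[1L], len_range[2L]), n_internal, replace = TRUE)
    vertices <- data.frame(
      id = c("v0", ids, "vM"),
      seq = c("", vapply(lens, rand_dna, ""), ""),
      stringsAsFactors = FALSE)
    w <- numeric(length(ef))
    for (v in unique(ef)) {
      e <- which(ef == v)
      w[e] <- rdirichlet1(length(e))
    }
    edges <- data.frame(from = ef, to = et, weight = w, stringsAsFactors = FALSE)
    splice_graph(gene_id, vertices, edges)
  })
}

## A random multi-isoform gene in first-order exon style: a chain of spacer
## exons with `n_branch` choice blocks (mutually exclusive alternatives or a
## cassette exon) between them.  Every complete path visits every spacer, so
## conditional-probability factorization of any isoform distribution is exact
## for these topologies.
random_benchmark_gene <- function(gene_id, seed, n_branch_range = c(2L, 6L),
                                  len_range = c(80L, 300L)) {
  withr::with_seed(seed, {
    B <- sample(seq(n_branch_range[1L], n_branch_range[2L]), 1L)
    rl <- function() sample(seq(len_range[1L], len_range[2L]), 1L)
    vid <- "S0"; vlen <- rl()
    ef <- "v0"; et <- "S0"
    prev <- "S0"
    for (b in seq_len(B)) {
      sp <- sprintf("S%d", b)
      if (stats::runif(1) < 0.4) {           # cassette block
        ex <- sprintf("B%dc", b)
        vid <- c(vid, ex, sp); vlen <- c(vlen, rl(), rl())
        ef <- c(ef, prev, prev, ex); et <- c(et, ex, sp, sp)
      } else {                               # mutually exclusive alternatives
        k <- sample(2:4, 1L)
        alts <- sprintf("B%da%d", b, seq_len(k))
        vid <- c(vid, alts, sp); vlen <- c(vlen, vapply(alts, function(.) rl(), 0L), rl())
        ef <- c(ef, rep(prev, k), alts); et <- c(et, alts, rep(sp, k))
      }
      prev <- sp
    }
    ef <- c(ef, prev); et <- c(et, "vM")
    vertices <- data.frame(id = c("v0", vid, "vM"),
                           seq = c("", vapply(vlen, rand_dna, ""), ""),
                           stringsAsFactors = FALSE)
    w <- numeric(length(ef))
    for (v in unique(ef)) {
      e <- which(ef == v)
      w[e] <- 1 / length(e)
    }
    splice_graph(gene_id, vertices,
                 data.frame(from = ef, to = et, weight = w,
                            stringsAsFactors = FALSE))
  })
}

#' Refactorize isoform frequencies onto a PSG
#'
#' Sets each edge weight to the conditional probability
#' `sum of theta over isoforms using the edge / sum over isoforms through the
#' source vertex` — the Markov factorization of the isoform distribution,
#' exact whenever the distribution lies in the graph's family (e.g. any
#' distribution on a chain-of-blocks exon graph).
#'
#' @param g A valid `splice_graph`.
#' @param theta Isoform frequencies aligned with `enumerate_isoforms(g)`.
#' @param max_count Enumeration bound.
#' @return The graph with refitted weights.
#' @export
refit_weights_from_isoforms <- function(g, theta, max_count = 10000L) {
  iso <- enumerate_isoforms(g, max_count = max_count)
  stopifnot(length(theta) == nrow(iso), abs(sum(theta) - 1) < 1e-6)
  paths <- lapply(chain_split(iso$path), function(p) c(g$v0, p, g$vM))
  w <- g$edges$weight
  for (i in seq_along(g$ids)) {
    e <- g$out[[i]]
    if (length(e) < 2L) { if (length(e)) w[e] <- 1; next }
    vnum <- numeric(length(e))
    vden <- 0
    for (t in seq_along(paths)) {
      p <- paths[[t]]
      pos <- match(g$ids[i], p)
      if (is.na(pos)) next
      vden <- vden + theta[t]
      nxt <- p[pos + 1L]
      vnum[match(nxt, g$ids[g$eTo[e]])] <- vnum[match(nxt, g$ids[g$eTo[e]])] + theta[t]
    }
    w[e] <- if (vden > 0) vnum / vden else 1 / length(e)
  }
  set_edge_weights(g, w)
}

#' Generate a two-condition differential-processing benchmark
#'
#' Simulates the evaluation design for the gene-level DP test: random
#' multi-isoform exon-style genes; four samples (two replicates for each of
#' two conditions A and B); within-condition replicates share isoform
#' frequencies while gene-level depths vary independently across all
#' samples; a `frac_dp` fraction of genes (floor rule) is differentially
#' processed, their isoform-frequency vectors randomly permuted between the
#' conditions (re-drawn when the permutation leaves the vector numerically
#' unchanged) and refactorized onto the graph.  Reads are paired-end and
#' error-free; each fragment's placement (its spanning subpath) is returned
#' as a collapsed dataset per gene and sample, and read sequences can be
#' emitted as FASTQ.
#'
#' @param n_genes Number of genes.
#' @param frac_dp Fraction of genes set to be differentially processed.
#' @param mean_fragments Mean fragments per expressed gene (log-normal
#'   across genes and samples, sdlog 0.5).
#' @param read_length Read length.
#' @param frag_mean,frag_sd Fragment length model.
#' @param seed Master seed (all per-gene seeds derive from it).
#' @param emit_fastq Also generate read sequences.
#' @param out_dir When `emit_fastq`, write `<sample>_1.fastq`,
#'   `<sample>_2.fastq` and `<sample>_truth.tsv` here.
#' @param n_branch_range Range of branch-vertex counts per gene.
#' @return A list with `graphs` (named list), `samples` (named list
#'   `A1`,`A2`,`B1`,`B2` of per-gene [psg_dataset()]s), `truth_dp`
#'   (character vector of DP gene ids), `weights` (per condition, named
#'   lists of edge-weight vectors), and `files` (when FASTQ was written).
#' @export
make_dp_benchmark <- function(n_genes = 300L, frac_dp = 0.10,
                              mean_fragments = 5000, read_length = 100L,
                              frag_mean = 250, frag_sd = 25, seed = 1L,
                              emit_fastq = FALSE, out_dir = NULL,
                              n_branch_range = c(2L, 6L)) {
  stopifnot(frac_dp >= 0, frac_dp <= 1, n_genes >= 1L)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  flm <- fragment_length_model(frag_mean, frag_sd)
  samples <- c("A1", "A2", "B1", "B2")
  cond <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  pars <- withr::with_seed(seed, {
    gseed <- sample.int(.Machine$integer.max - 1L, n_genes)
    sseed <- matrix(sample.int(.Machine$integer.max - 1L, 4L * n_genes), nrow = 4L)
    dp <- sort(sample.int(n_genes, floor(frac_dp * n_genes)))
    depths <- matrix(pmax(20, round(stats::rlnorm(4L * n_genes,
                                                  log(mean_fragments) - 0.125,
                                                  0.5))), nrow = 4L)
    perm_seed <- sample.int(.Machine$integer.max - 1L, n_genes)
    list(gseed = gseed, sseed = sseed, dp = dp, depths = depths,
         perm_seed = perm_seed)
  })
  graphs <- list(); wA <- list(); wB <- list()
  ds <- lapply(samples, function(s) list())
  names(ds) <- samples
  reads_out <- lapply(samples, function(s) list())
  names(reads_out) <- samples
  truths_out <- lapply(samples, function(s) list())
  names(truths_out) <- samples
  for (k in seq_len(n_genes)) {
    gene <- genes[k]
    g <- random_benchmark_gene(gene, pars$gseed[k],
                               n_branch_range = n_branch_range)
    gA <- withr::with_seed(pars$gseed[k] + 1L, {
      w <- g$edges$weight
      for (i in seq_along(g$ids)) {
        e <- g$out[[i]]
        if (length(e) >= 2L) w[e] <- rdirichlet1(length(e))
      }
      set_edge_weights(g, w)
    })
    if (k %in% pars$dp) {
      iso <- enumerate_isoforms(gA)
      gB <- withr::with_seed(pars$perm_seed[k], {
        repeat {
          prm <- sample.int(nrow(iso))
          if (max(abs(iso$prob[prm] - iso$prob)) > 1e-9) break
        }
        refit_weights_from_isoforms(gA, iso$prob[prm])
      })
    } else {
      gB <- gA
    }
    graphs[[gene]] <- g
    wA[[gene]] <- gA$edges$weight
    wB[[gene]] <- gB$edges$weight
    for (si in seq_along(samples)) {
      s <- samples[si]
      gs <- if (cond[s] == "A") gA else gB
      sim <- simulate_fragments(gs, pars$depths[si, k], read_length, flm = flm,
                                error_rate = 0, emit_reads = emit_fastq,
                                seed = pars$sseed[si, k])
      ds[[s]][[gene]] <- dataset_from_truth(g, sim$truth)
      if (emit_fastq) {
        sim$reads$id <- paste0(s, "_", sim$reads$id)
        reads_out[[s]][[gene]] <- sim$reads
        truths_out[[s]][[gene]] <- sim$truth
      }
    }
  }
  files <- NULL
  if (emit_fastq && !is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (s in samples) {
      rd <- do.call(rbind, reads_out[[s]])
      f1 <- file.path(out_dir, paste0(s, "_1.fastq"))
      f2 <- file.path(out_dir, paste0(s, "_2.fastq"))
      write_fastq(rd, f1, f2)
      ft <- file.path(out_dir, paste0(s, "_truth.tsv"))
      write_truth(do.call(rbind, truths_out[[s]]), ft)
      files[[s]] <- c(f1, f2, ft)
    }
  }
  list(graphs = graphs, samples = ds, truth_dp = genes[pars$dp],
       weights = list(A = wA, B = wB), files = files,
       spec = list(n_genes = n_genes, frac_dp = frac_dp,
                   mean_fragments = mean_fragments, read_length = read_length,
                   frag_mean = frag_mean, frag_sd = frag_sd, seed = seed))
}

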