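# Brute-force oracles, independent of the package's dynamic-programming
# implementations: they work by explicit enumeration of complete paths and
# start positions, reading only the graph's raw fields (ids, lengths,
# sequences, edge table).

# all v0 -> vM paths with probabilities and lengths, by naive DFS on the
# edge table
oracle_paths <- function(g) {
  e <- g$edges
  froms <- split(seq_len(nrow(e)), e$from)
  res <- list()
  rec <- function(v, chain, p) {
    rows <- froms[[v]]
    if (is.null(rows)) {           # sink
      res[[length(res) + 1L]] <<- list(chain = chain, prob = p)
      return(invisible())
    }
    for (r in rows) rec(e$to[r], c(chain, e$to[r]), p * e$weight[r])
  }
  v0 <- setdiff(e$from, e$to)
  stopifnot(length(v0) == 1L)
  rec(v0, character(0), 1)
  vM <- setdiff(e$to, e$from)
  paths <- lapply(res, function(x) setdiff(x$chain, vM))
  data.frame(
    path = vapply(paths, paste, "", collapse = ","),
    prob = vapply(res, `[[`, 0, "prob"),
    length = vapply(paths, function(p) sum(g$len[p]), 0),
    stringsAsFactors = FALSE)
}

oracle_mu <- function(g) {
  p <- oracle_paths(g)
  sum(p$prob * p$length)
}

# inclusion frequency of each vertex among complete paths (the terminal
# vertices lie on every path by definition)
oracle_inclusion <- function(g) {
  p <- oracle_paths(g)
  sets <- strsplit(p$path, ",", fixed = TRUE)
  out <- vapply(g$ids, function(v)
    sum(p$prob[vapply(sets, function(s) v %in% s, NA)]), 0)
  out[c(g$v0, g$vM)] <- 1
  out
}

# does chain (id vector) occur consecutively in path (id vector)?  A chain
# terminated by the end vertex requires its real part to be a suffix of the
# path (the read overhangs into the poly(A) tail).
oracle_chain_in <- function(chain, path) {
  k <- length(chain); n <- length(path)
  if (k >= 1L && chain[k] == "vM") {
    chain <- chain[-k]; k <- k - 1L
    if (k > n) return(FALSE)
    return(all(path[seq.int(n - k + 1L, n)] == chain))
  }
  if (k > n) return(FALSE)
  for (s in seq_len(n - k + 1L))
    if (all(path[seq.int(s, s + k - 1L)] == chain)) return(TRUE)
  FALSE
}

# marginal probability of a read given its placement set, by enumerating
# isoforms: sum over alignments, over isoforms containing the chain, of
# w(t)/mu times the per-base error term
oracle_read_marginal <- function(g, alignments, read_length, error_rate = 0) {
  p <- oracle_paths(g)
  mu <- sum(p$prob * p$length)
  sets <- strsplit(p$path, ",", fixed = TRUE)
  tot <- 0
  for (i in seq_len(nrow(alignments))) {
    ch <- strsplit(alignments$chain[i], ",", fixed = TRUE)[[1L]]
    mm <- alignments$mm[i]
    err <- if (mm == 0L) (1 - error_rate)^read_length else
      (1 - error_rate)^(read_length - mm) * (error_rate / 3)^mm
    for (t in seq_along(sets))
      if (oracle_chain_in(ch, sets[[t]])) tot <- tot + p$prob[t] * err / mu
  }
  tot
}

# expected edge-usage counts for one read (posterior over isoform and
# placement), enumerating every (alignment, isoform) pair
oracle_estep_read <- function(g, alignments, read_length, error_rate = 0) {
  p <- oracle_paths(g)
  mu <- sum(p$prob * p$length)
  sets <- strsplit(p$path, ",", fixed = TRUE)
  ekey <- paste0(g$edges$from, "->", g$edges$to)
  counts <- setNames(numeric(nrow(g$edges)), ekey)
  Z <- 0
  contrib <- list()
  for (i in seq_len(nrow(alignments))) {
    ch <- strsplit(alignments$chain[i], ",", fixed = TRUE)[[1L]]
    mm <- alignments$mm[i]
    err <- if (mm == 0L) (1 - error_rate)^read_length else
      (1 - error_rate)^(read_length - mm) * (error_rate / 3)^mm
    for (t in seq_along(sets)) {
      if (!oracle_chain_in(ch, sets[[t]])) next
      wt <- p$prob[t] * err / mu
      Z <- Z + wt
      full <- c(g$v0, sets[[t]], g$vM)
      e <- paste0(full[-length(full)], "->", full[-1L])
      contrib[[length(contrib) + 1L]] <- list(e = e, w = wt)
    }
  }
  for (x in contrib) counts[x$e] <- counts[x$e] + x$w / Z
  counts
}

# maximum-likelihood EM over enumerated full-length isoforms (the classic
# transcript-quantification EM on fragment proportions nu_t = w_t l_t / mu),
# for datasets whose reads each carry a set of placement chains
oracle_full_isoform_em <- function(g, chain_sets, n_per_set,
                                   max_iter = 5000, tol = 1e-12) {
  p <- oracle_paths(g)
  sets <- strsplit(p$path, ",", fixed = TRUE)
  ## compatibility counts: number of placements of read r consistent with t
  A <- vapply(seq_along(sets), function(t) {
    vapply(chain_sets, function(cs)
      sum(vapply(cs, function(c)
        oracle_chain_in(strsplit(c, ",", fixed = TRUE)[[1L]], sets[[t]]), NA)), 0)
  }, numeric(length(chain_sets)))
  A <- matrix(A, nrow = length(chain_sets))
  lens <- p$length
  nu <- rep(1 / nrow(p), nrow(p))
  N <- sum(n_per_set)
  for (it in seq_len(max_iter)) {
    M <- sweep(A, 2L, nu / lens, `*`)
    rs <- rowSums(M)
    gam <- sweep(M, 1L, rs, `/`)
    nu_new <- colSums(gam * n_per_set) / N
    if (max(abs(nu_new - nu)) < tol) { nu <- nu_new; break }
    nu <- nu_new
  }
  w <- nu / lens
  w <- w / sum(w)
  data.frame(path = p$path, freq = w, stringsAsFactors = FALSE)
}

# scalar log-likelihood for a single-free-parameter cassette gene, by direct
# enumeration (used to check the LRT optimum by golden-section search)
oracle_cassette_loglik <- function(g, chains_tab, pval) {
  # chains_tab: data.frame(chain, n); pval = inclusion probability of the
  # cassette exon (edge E1->E2 of make_toy_graph("cassette"))
  w <- g$edges$weight
  w[paste0(g$edges$from, "->", g$edges$to) == "E1->E2"] <- pval
  w[paste0(g$edges$from, "->", g$edges$to) == "E1->E3"] <- 1 - pval
  g2 <- set_edge_weights(g, w)
  p <- oracle_paths(g2)
  mu <- sum(p$prob * p$length)
  sets <- strsplit(p$path, ",", fixed = TRUE)
  ll <- 0
  for (i in seq_len(nrow(chains_tab))) {
    ch <- strsplit(chains_tab$chain[i], ",", fixed = TRUE)[[1L]]
    m <- 0
    for (t in seq_along(sets))
      if (oracle_chain_in(ch, sets[[t]])) m <- m + p$prob[t]
    ll <- ll + chains_tab$n[i] * (log(m) - log(mu))
  }
  ll
}

golden_max <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) > f(d)) b <- d else a <- c
    c <- b - gr * (b - a); d <- a + gr * (b - a)
  }
  (a + b) / 2
}

# collapse a truth table into (chain, n) counts
truth_chain_counts <- function(truth) {
  tab <- table(truth$chain)
  data.frame(chain = names(tab), n = as.numeric(tab), stringsAsFactors = FALSE)
}
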