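## ---------------------------------------------------------------------------
## Generative RNA-Seq model on a PSG.  A fragment is drawn by picking a
## transcript path t with probability proportional to w(t) * length(t), and a
## start position b uniformly along it; reads overhanging the 3' end are
## matched against an infinite poly(A) tail.  The transcript-length factors
## cancel, so the joint probability of (t, b) is w(t) / mu, and the marginal
## probability of a read placement (s, b) is F(v0, first(s)) * w(s) / mu.
## ---------------------------------------------------------------------------

#' Fragment length model
#'
#' Discretized truncated normal (or point mass when `sd = 0`) over integer
#' fragment lengths, used by the paired-end model and the simulator.
#'
#' @param mean,sd Mean and standard deviation of the fragment length.
#' @param min,max Truncation bounds (defaults: `mean -/+ 4 sd`, floored at 1).
#' @return A list with integer `support` and `prob` summing to 1.
#' @export
fragment_length_model <- function(mean, sd = 0,
                                  min = base::max(1, floor(mean - 4 * sd)),
                                  max = ceiling(mean + 4 * sd)) {
  stopifnot(mean > 0, sd >= 0, min >= 1, max >= min)
  if (sd == 0) {
    support <- as.integer(round(mean)); prob <- 1
  } else {
    support <- seq.int(min, max)
    prob <- stats::dnorm(support, mean, sd)
    prob <- prob / sum(prob)
  }
  list(support = as.integer(support), prob = prob)
}

flm_prob <- function(flm, f) {
  i <- match(f, flm$support)
  p <- ifelse(is.na(i), 0, flm$prob[i])
  p
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---------------------------------------------------------------------------
## Internal exact / k-mismatch alignment against the graph
## ---------------------------------------------------------------------------

#' Align a read to a PSG by exhaustive subpath matching
#'
#' Finds every distinct placement `(s, b)` of the read with at most
#' `max_mismatch` mismatches, where `s` is the minimal vertex chain touched
#' by the read and `b` the 0-based offset of its first base in the first
#' vertex of `s`.  Bases extending past the end vertex are matched against a
#' poly(A) tail and reported as `polya` overhang.  This is the package's
#' internal matcher; external SAM alignments against the reference windows of
#' [extract_reference_sequences()] are interchangeable.
#'
#' @param g A valid `splice_graph`.
#' @param read Read sequence (character).
#' @param max_mismatch Maximum number of mismatches.
#' @return Data frame with columns `chain`, `b`, `mm`, `polya`
#'   (zero rows when the read has no placement).
#' @export
align_read <- function(g, read, max_mismatch = 0L) {
  read <- toupper(read)
  L <- nchar(read)
  stopifnot(L >= 1L)
  rchars <- strsplit(read, "")[[1L]]
  vM <- psg_vi(g, g$vM)
  res_chain <- character(0); res_b <- integer(0)
  res_mm <- integer(0); res_pa <- integer(0)
  count_mm <- function(a, b) sum(a != b)
  for (v in seq_along(g$ids)) {
    lv <- g$len[v]
    if (lv == 0L) next
    vseq <- strsplit(g$seq[v], "")[[1L]]
    for (b in 0:(lv - 1L)) {
      take <- min(L, lv - b)
      mm0 <- count_mm(rchars[seq_len(take)], vseq[b + seq_len(take)])
      if (mm0 > max_mismatch) next
      if (take == L) {
        res_chain <- c(res_chain, g$ids[v]); res_b <- c(res_b, b)
        res_mm <- c(res_mm, mm0); res_pa <- c(res_pa, 0L)
        next
      }
      ## extend across junctions
      rec <- function(chain, pos, mm, cur) {
        for (e in g$out[[cur]]) {
          nv <- g$eTo[e]
          if (nv == vM) {
            ## remaining bases against poly(A); the placement certifies the
            ## transcript end, so the chain is vM-terminated and its weight
            ## carries the polyadenylation edge
            rest <- rchars[seq.int(pos + 1L, L)]
            mm2 <- mm + sum(rest != "A")
            if (mm2 <= max_mismatch) {
              res_chain <<- c(res_chain, paste(g$ids[c(chain, vM)], collapse = ","))
              res_b <<- c(res_b, b); res_mm <<- c(res_mm, mm2)
              res_pa <<- c(res_pa, L - pos)
            }
            next
          }
          ln <- g$len[nv]
          tk <- min(L - pos, ln)
          nseq <- substr(g$seq[nv], 1L, tk)
          mm2 <- mm + count_mm(rchars[pos + seq_len(tk)],
                               strsplit(nseq, "")[[1L]])
          if (mm2 > max_mismatch) next
          if (pos + tk == L) {
            res_chain <<- c(res_chain, paste(g$ids[c(chain, nv)], collapse = ","))
            res_b <<- c(res_b, b); res_mm <<- c(res_mm, mm2)
            res_pa <<- c(res_pa, 0L)
          } else {
            rec(c(chain, nv), pos + tk, mm2, nv)
          }
        }
      }
      rec(v, take, mm0, v)
    }
  }
  out <- data.frame(chain = res_chain, b = res_b, mm = res_mm, polya = res_pa,
                    stringsAsFactors = FALSE)
  unique(out)
}

## ---------------------------------------------------------------------------
## Marginal read / fragment probabilities
## ---------------------------------------------------------------------------

placement_prob <- function(g, chains, mm, read_length, error_rate) {
  mu <- expected_lengths(g)$mu
  Fv0 <- psg_inclusion_from(g, psg_vi(g, g$v0))
  vapply(seq_along(chains), function(i) {
    vs <- psg_vi(g, chain_split(chains[i])[[1L]])
    w <- if (length(vs) > 1L) prod(g$edges$weight[psg_edge_ids(g, vs)]) else 1
    err <- if (mm[i] == 0L) (1 - error_rate)^read_length else
      (1 - error_rate)^(read_length - mm[i]) * (error_rate / 3)^mm[i]
    Fv0[vs[1L]] * w * err / mu
  }, 0)
}

#' Marginal log-probability of a single-end read
#'
#' `log sum over placements of (1/mu) * F(v0, first(s)) * w(s) * P(r | s, b)`
#' where the per-base error term is `(1-eps)^matches * (eps/3)^mismatches`.
#' Poly(A) overhang bases count as matches against `A` (their mismatches are
#' already included in `mm`).
#'
#' @param g A valid `splice_graph`.
#' @param alignments Data frame as returned by [align_read()].
#' @param read_length Read length used for the error term.
#' @param error_rate Per-base substitution probability `eps` (in `[0, 0.25)`).
#' @return Log-probability; `-Inf` with attribute `unalignable = TRUE` when
#'   no placement has positive probability.
#' @export
read_log_marginal <- function(g, alignments, read_length, error_rate = 0) {
  stopifnot(error_rate >= 0, error_rate < 0.25)
  if (nrow(alignments) == 0L)
    return(structure(-Inf, unalignable = TRUE))
  p <- placement_prob(g, alignments$chain, alignments$mm, read_length, error_rate)
  s <- sum(p)
  if (s == 0) return(structure(-Inf, unalignable = TRUE))
  log(s)
}

#' Marginal log-probability of a paired-end fragment
#'
#' Sums over compatible placements of the two mates on a common spanning
#' subpath running from the first vertex of the mate-1 placement to the last
#' vertex of the mate-2 placement, weighting each by
#' `(1/mu) * F(v0, first) * w(spanning subpath) * P(f) * P(bases | eps)`,
#' where `f` is the implied fragment length under `flm`.  Mate 2 is assumed
#' given in fragment orientation (i.e. already reverse-complemented by the
#' aligner); fragment lengths are not renormalized per transcript.
#'
#' @param g A valid `splice_graph`.
#' @param aln1,aln2 Placements of mate 1 and mate 2 ([align_read()] output,
#'   mate 2 aligned as the reverse complement of the sequenced mate).
#' @param flm A [fragment_length_model()].
#' @param read_length Length of each mate.
#' @param error_rate Per-base substitution probability.
#' @return Log-probability (`-Inf`, flagged, when no compatible placement).
#' @export
fragment_log_marginal <- function(g, aln1, aln2, flm, read_length,
                                  error_rate = 0) {
  if (nrow(aln1) == 0L || nrow(aln2) == 0L)
    return(structure(-Inf, unalignable = TRUE))
  mu <- expected_lengths(g)$mu
  Fv0 <- psg_inclusion_from(g, psg_vi(g, g$v0))
  fmax <- max(flm$support)
  total <- 0
  seen <- character(0)
  vM <- psg_vi(g, g$vM)
  for (i1 in seq_len(nrow(aln1))) {
    c1 <- psg_vi(g, chain_split(aln1$chain[i1])[[1L]])
    b1 <- aln1$b[i1]
    ## enumerate spanning chains: extensions of c1 up to fmax bases from b1
    ext <- function(chain, cum) {
      ## try to settle every mate-2 placement on this chain
      for (i2 in seq_len(nrow(aln2))) {
        c2 <- psg_vi(g, chain_split(aln2$chain[i2])[[1L]])
        b2 <- aln2$b[i2]
        k <- length(c2)
        nch <- length(chain)
        if (k > nch) next
        if (!all(chain[seq.int(nch - k + 1L, nch)] == c2)) next
        ## global start position of mate 2 within the spanning chain
        off2 <- sum(g$len[chain[seq_len(nch - k)]]) + b2
        f <- off2 + read_length - b1   # implied fragment length (incl. polyA)
        if (f < read_length || off2 < b1) next
        key <- paste(paste(chain, collapse = ","), f, b1)
        if (key %in% seen) next
        pf <- flm_prob(flm, f)
        if (pf == 0) next
        mm <- aln1$mm[i1] + aln2$mm[i2]
        err <- if (mm == 0L) (1 - error_rate)^(2 * read_length) else
          (1 - error_rate)^(2 * read_length - mm) * (error_rate / 3)^mm
        w <- if (nch > 1L) prod(g$edges$weight[psg_edge_ids(g, chain)]) else 1
        seen <<- c(seen, key)
        total <<- total + Fv0[chain[1L]] * w * pf * err / mu
      }
      if (cum >= b1 + fmax) return(invisible())
      last <- chain[length(chain)]
      if (last == vM) return(invisible())
      for (e in g$out[[last]]) {
        nv <- g$eTo[e]
        ext(c(chain, nv), cum + g$len[nv])  # vM allowed as a terminal element
      }
    }
    ext(c1, sum(g$len[c1]))
  }
  if (total == 0) return(structure(-Inf, unalignable = TRUE))
  log(total)
}

#' Log-likelihood of an aligned dataset
#'
#' Sum over fragments of the marginal log-probability of their placement
#' sets under the graph's current edge weights, plus (optionally) the
#' unnormalized Dirichlet log-prior of the weights.  This is the EM objective
#' and the ingredient of the likelihood-ratio tests (prior off for ML).
#'
#' @param g A valid `splice_graph` (its current edge weights are used).
#' @param dataset A [psg_dataset()].
#' @param include_prior Add `sum (beta - 1) log alpha`.
#' @return Scalar log-probability (0 for an empty dataset without prior).
#' @export
dataset_log_likelihood <- function(g, dataset, include_prior = FALSE) {
  ll <- 0
  if (dataset$n_total > 0) {
    cw <- chain_weights(g, dataset)
    pv <- cw[dataset$plc$chain] * exp(dataset$plc$extra)
    denom <- rowsum(pv, dataset$plc$group)
    dv <- numeric(length(dataset$group_n))
    dv[as.integer(rownames(denom))] <- denom[, 1L]
    mu <- expected_lengths(g)$mu
    ll <- sum(dataset$group_n * (log(dv) - log(mu)))
  }
  if (include_prior) {
    b <- g$edges$beta
    ll <- ll + sum((b - 1) * log(pmax(g$edges$weight, 1e-300)))
  }
  ll
}

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

## vectorized categorical draw of successors for a vector of current vertices
draw_step <- function(cur, nbr, prb) {
  nxt <- integer(length(cur))
  for (v in unique(cur)) {
    i <- which(cur == v)
    cand <- nbr[[v]]
    if (length(cand) == 1L) nxt[i] <- cand
    else nxt[i] <- cand[sample.int(length(cand), length(i), replace = TRUE,
                                   prob = prb[[v]])]
  }
  nxt
}

add_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs[1L])
  nerr <- stats::rbinom(length(seqs), L, error_rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L, nerr[i])
    s <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate fragments from the PSG model
#'
#' Samples `(t, b)` pairs from `P(t, b) = w(t) / mu` without enumerating
#' isoforms: the start vertex `i` is drawn with probability
#' `F(v0, i) l(i) / mu`, the offset `b` uniformly within it, the path suffix
#' is extended forward by out-edge weights and the prefix backward by
#' in-edge posterior probabilities proportional to `F(v0, u) alpha(u -> i)`.
#' Read bases are copied from the path (poly(A) beyond the end vertex) and
#' substituted at rate `error_rate`.  Deterministic given `seed`.
#'
#' @param g A valid `splice_graph`.
#' @param n Number of fragments.
#' @param read_length Read length `L`.
#' @param flm `NULL` for single-end data, otherwise a
#'   [fragment_length_model()] for paired-end fragments (mate 2 is reported
#'   reverse-complemented, as sequenced).
#' @param error_rate Per-base substitution probability.
#' @param emit_reads Generate read sequences (set `FALSE` to produce only
#'   placements and truth, which is considerably faster).
#' @param seed Seed (local to this call).
#' @return A list with `reads` (data frame `id`, `seq1`, and `seq2` for
#'   paired data; `NULL` when `emit_reads = FALSE`) and `truth` (data frame
#'   `fragment_id`, `gene`, `path`, `b_path` offset of the start vertex
#'   within the path, `b` offset within the start vertex, `chain` minimal
#'   spanning subpath of the fragment, `b_chain`, `polya` overhang).
#' @export
simulate_fragments <- function(g, n, read_length, flm = NULL, error_rate = 0,
                               emit_reads = TRUE, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0)
    return(list(reads = NULL, truth = data.frame()))
  withr::with_seed(seed, {
    v0 <- psg_vi(g, g$v0); vM <- psg_vi(g, g$vM)
    Fv0 <- psg_inclusion_from(g, v0)
    mu <- expected_lengths(g)$mu
    len <- as.numeric(g$len)
    w <- g$edges$weight
    pstart <- Fv0 * len / mu
    start <- sample.int(length(g$ids), n, replace = TRUE, prob = pstart)
    b <- floor(stats::runif(n) * len[start])
    ## neighbor tables
    out_nbr <- lapply(g$out, function(e) g$eTo[e])
    out_prb <- lapply(g$out, function(e) w[e])
    in_nbr <- lapply(seq_along(g$ids), function(x) g$eFrom[g$inn[[x]]])
    in_prb <- lapply(seq_along(g$ids), function(x) {
      u <- g$eFrom[g$inn[[x]]]
      p <- Fv0[u] * w[g$inn[[x]]]
      if (length(p) && sum(p) > 0) p / sum(p) else p
    })
    ## forward extension to vM
    fwd <- list(); cur <- start
    alive <- cur != vM
    while (any(alive)) {
      nxt <- cur
      nxt[alive] <- draw_step(cur[alive], out_nbr, out_prb)
      fwd[[length(fwd) + 1L]] <- ifelse(alive, nxt, NA_integer_)
      cur <- nxt
      alive <- cur != vM
    }
    ## backward extension to v0
    bwd <- list(); cur <- start
    alive <- cur != v0
    while (any(alive)) {
      prv <- cur
      prv[alive] <- draw_step(cur[alive], in_nbr, in_prb)
      bwd[[length(bwd) + 1L]] <- ifelse(alive, prv, NA_integer_)
      cur <- prv
      alive <- cur != v0
    }
    fwdm <- if (length(fwd)) do.call(cbind, fwd) else matrix(NA_integer_, n, 0)
    bwdm <- if (length(bwd)) do.call(cbind, bwd) else matrix(NA_integer_, n, 0)
    ## assemble paths (internal vertices only) as dot-joined index strings
    cols <- c(rev(lapply(seq_len(ncol(bwdm)), function(j) bwdm[, j])),
              list(start),
              lapply(seq_len(ncol(fwdm)), function(j) fwdm[, j]))
    cols <- lapply(cols, function(x) {
      x[is.na(x) | x == v0 | x == vM] <- NA_integer_
      ifelse(is.na(x), "", paste0(".", x))
    })
    paths <- do.call(paste0, cols)
    paths <- substring(paths, 2L)
    startpos <- rowSums(!is.na(bwdm) & bwdm != v0) + 1L
    if (!ncol(bwdm)) startpos <- rep.int(1L, n)
    ## fragment lengths
    if (is.null(flm)) {
      f <- rep.int(read_length, n)
    } else {
      f <- flm$support[sample.int(length(flm$support), n, replace = TRUE,
                                  prob = flm$prob)]
    }
    ## per unique path: cumulative lengths -> spanning chain, b_t
    upath <- unique(paths)
    pid <- match(paths, upath)
    chain <- character(n); b_chain <- integer(n); polya <- integer(n)
    b_t <- integer(n); tlen <- numeric(n)
    seq1 <- seq2 <- NULL
    if (emit_reads) { seq1 <- character(n); if (!is.null(flm)) seq2 <- character(n) }
    upathlist <- lapply(strsplit(upath, ".", fixed = TRUE), as.integer)
    for (u in seq_along(upath)) {
      sel <- which(pid == u)
      p <- upathlist[[u]]
      cl <- cumsum(len[p])
      cstart <- c(0, cl[-length(cl)])
      lt <- cl[length(cl)]
      bt <- cstart[startpos[sel]] + b[sel]
      b_t[sel] <- bt
      tlen[sel] <- lt
      lastbase <- pmin(bt + f[sel] - 1L, lt - 1L)
      i1 <- findInterval(bt, cstart)
      i2 <- findInterval(lastbase, cstart)
      polya[sel] <- pmax(0L, bt + f[sel] - lt)
      b_chain[sel] <- bt - cstart[i1]
      ## fragments overhanging the 3' end certify the transcript end: their
      ## chains terminate at vM
      pa <- polya[sel] > 0L
      cmb <- paste(i1, i2, pa)
      ucmb <- !duplicated(cmb)
      cstr <- vapply(which(ucmb), function(k)
        paste(c(g$ids[p[seq.int(i1[k], i2[k])]], if (pa[k]) g$vM),
              collapse = ","), "")
      chain[sel] <- cstr[match(cmb, cmb[ucmb])]
      if (emit_reads) {
        tseq <- paste0(paste(g$seq[p], collapse = ""),
                       strrep("A", read_length + max(0, max(f[sel]) - read_length)))
        seq1[sel] <- substring(tseq, bt + 1L, bt + read_length)
        if (!is.null(flm))
          seq2[sel] <- revcomp(substring(tseq, bt + f[sel] - read_length + 1L,
                                         bt + f[sel]))
      }
    }
    reads <- NULL
    if (emit_reads) {
      seq1 <- add_seq_errors(seq1, error_rate)
      reads <- data.frame(id = sprintf("%s_frag%d", g$gene_id, seq_len(n)),
                          seq1 = seq1, stringsAsFactors = FALSE)
      if (!is.null(flm)) reads$seq2 <- add_seq_errors(seq2, error_rate)
    }
    pathstr <- vapply(upathlist, function(p) paste(g$ids[p], collapse = ","), "")
    truth <- data.frame(
      fragment_id = sprintf("%s_frag%d", g$gene_id, seq_len(n)),
      gene = g$gene_id,
      path = pathstr[pid],
      b_path = startpos,
      b = b,
      b_t = b_t,
      frag_len = f,
      chain = chain,
      b_chain = b_chain,
      polya = polya,
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Dataset from simulator truth placements
#'
#' Convenience constructor turning the truth table of [simulate_fragments()]
#' into a [psg_dataset()] with one placement per fragment (the spanning
#' subpath), which is exactly what the internal matcher recovers for
#' error-free reads with unique sequences.
#'
#' @param g A valid `splice_graph`.
#' @param truth Truth table from [simulate_fragments()].
#' @export
dataset_from_truth <- function(g, truth) {
  psg_dataset(g, data.frame(read = truth$fragment_id, chain = truth$chain,
                            stringsAsFactors = FALSE))
}
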