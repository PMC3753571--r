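## ---------------------------------------------------------------------------
## Identifiability certification.  A PSG model is identifiable when distinct
## parameter vectors induce distinct read distributions.  A simple sufficient
## condition: for each edge, either some length-L read is derivable from a
## subpath crossing that edge and from nowhere else in the whole graph
## collection, or the edge's target vertex can produce such a globally unique
## read.  The check is sequence-level and exact-match; failing it means "not
## certified", never "proven unidentifiable".
## ---------------------------------------------------------------------------

## All (chain, b) placements of length-L reads for one gene, with sequences.
## Chains are minimal (the read touches the first and last listed vertex);
## reads overhanging the 3' end carry a positive poly(A) overhang.
census_placements <- function(g, L) {
  recs <- extract_reference_sequences(g, L)
  out <- vector("list", nrow(recs))
  vMid <- g$vM
  for (i in seq_len(nrow(recs))) {
    ch <- chain_split(recs$chain[i])[[1L]]
    wlen <- nchar(recs$seq[i])
    if (length(ch) == 1L) {
      if (wlen < L) next
      p <- 0:(wlen - L)
      out[[i]] <- data.frame(chain = recs$chain[i], b = p, polya = 0L,
                             seq = substring(recs$seq[i], p + 1L, p + L),
                             stringsAsFactors = FALSE)
    } else {
      first <- ch[1L]; last <- ch[length(ch)]
      flank1 <- min(L - 1L, g$len[first])
      inner <- if (length(ch) > 2L) sum(g$len[ch[seq.int(2L, length(ch) - 1L)]]) else 0L
      pmaxv <- min(flank1 - 1L, wlen - L)
      pminv <- max(0L, flank1 + inner + 1L - L)
      if (pmaxv < pminv) next
      p <- pminv:pmaxv
      ispA <- last == vMid
      realchain <- if (ispA) paste(ch[-length(ch)], collapse = ",") else recs$chain[i]
      overh <- if (ispA) p + L - flank1 - inner else 0L
      out[[i]] <- data.frame(chain = realchain, b = recs$offset[i] + p,
                             polya = as.integer(overh),
                             seq = substring(recs$seq[i], p + 1L, p + L),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, NA)])
  if (is.null(res)) res <- data.frame(chain = character(0), b = integer(0),
                                      polya = integer(0), seq = character(0))
  res
}

#' Unique-read census over a collection of PSGs
#'
#' Enumerates every length-`L` read placement over all subpaths of all graphs
#' (via the reference-window machinery), maps read sequences to placements,
#' and marks, for each edge, whether some read crossing it is derivable from
#' no other placement in the whole collection, and for each vertex whether
#' some read within it is globally unique.
#'
#' @param graphs A `splice_graph` or list of them (uniqueness is judged
#'   jointly across all of them).
#' @param read_length Read length `L` (>= 1).
#' @return A list of class `psg_census`, one entry per gene, each with
#'   logical vectors `edge_unique` (named `from->to`) and `vertex_unique`.
#' @export
unique_read_census <- function(graphs, read_length) {
  stopifnot(read_length >= 1L)
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  plc <- lapply(graphs, census_placements, L = read_length)
  gene <- rep.int(vapply(graphs, `[[`, "", "gene_id"), vapply(plc, nrow, 0L))
  all_seq <- unlist(lapply(plc, `[[`, "seq"), use.names = FALSE)
  dup <- duplicated(all_seq) | duplicated(all_seq, fromLast = TRUE)
  off <- 0L
  out <- list()
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    pk <- plc[[k]]
    uniq <- !dup[off + seq_len(nrow(pk))]
    off <- off + nrow(pk)
    ek <- paste0(g$edges$from, "->", g$edges$to)
    edge_unique <- setNames(rep(FALSE, nrow(g$edges)), ek)
    vertex_unique <- setNames(rep(FALSE, length(g$ids)), g$ids)
    up <- pk[uniq, , drop = FALSE]
    if (nrow(up)) {
      for (i in seq_len(nrow(up))) {
        ch <- chain_split(up$chain[i])[[1L]]
        if (length(ch) == 1L && up$polya[i] == 0L) {
          vertex_unique[ch] <- TRUE
        } else {
          if (length(ch) > 1L) {
            e <- paste0(ch[-length(ch)], "->", ch[-1L])
            edge_unique[e] <- TRUE
          }
          if (up$polya[i] > 0L)
            edge_unique[paste0(ch[length(ch)], "->", g$vM)] <- TRUE
        }
      }
    }
    out[[g$gene_id]] <- list(edge_unique = edge_unique,
                             vertex_unique = vertex_unique,
                             n_placements = nrow(pk))
  }
  structure(out, read_length = read_length, class = "psg_census")
}

#' Check the identifiability conditions for one PSG
#'
#' An edge passes when it has a globally unique crossing read or its target
#' vertex has a globally unique within-vertex read; the graph is certified
#' identifiable when every edge passes.  The condition is sufficient, not
#' necessary, so the negative verdict is `"not certified"`.
#'
#' @param g A valid `splice_graph`.
#' @param census A [unique_read_census()] that includes `g`.
#' @return A list with `table` (per-edge data frame: `from`, `to`,
#'   `condition` in `{edge-unique, vertex-unique, none}`, `pass`) and
#'   `certified` (logical).
#' @export
check_identifiability <- function(g, census) {
  cg <- census[[g$gene_id]]
  if (is.null(cg)) stop("census does not cover gene ", g$gene_id)
  ek <- paste0(g$edges$from, "->", g$edges$to)
  if (!all(ek %in% names(cg$edge_unique))) stop("census/graph edge mismatch")
  eu <- cg$edge_unique[ek]
  vu <- cg$vertex_unique[g$edges$to]
  condition <- ifelse(eu, "edge-unique", ifelse(vu, "vertex-unique", "none"))
  tab <- data.frame(gene = g$gene_id, from = g$edges$from, to = g$edges$to,
                    condition = condition, pass = eu | vu,
                    stringsAsFactors = FALSE)
  list(table = tab, certified = all(tab$pass),
       read_length = attr(census, "read_length"))
}

## is `chain` (character ids) derivable from isoform path `tpath`?  With a
## poly(A) overhang the chain must additionally be a suffix of the path.
chain_in_path <- function(chain, tpath, overhang = FALSE) {
  k <- length(chain); n <- length(tpath)
  if (k > n) return(FALSE)
  if (overhang)
    return(all(tpath[seq.int(n - k + 1L, n)] == chain))
  for (s in seq_len(n - k + 1L))
    if (all(tpath[seq.int(s, s + k - 1L)] == chain)) return(TRUE)
  FALSE
}

#' Search for a non-identifiability witness of the full-isoform model
#'
#' For the full-length-isoform model implied by a PSG (every complete path a
#' free frequency), finds two distinct isoform-frequency vectors whose
#' expected read-placement distributions at the given read length are
#' identical, by solving the linear system of placement probabilities over
#' the isoform simplex.  A witness demonstrates non-identifiability of the
#' unfactorized/full-isoform model where the factorized PSG may still be
#' identifiable.
#'
#' @param g A valid `splice_graph`.
#' @param read_length Read length.
#' @param max_count Isoform enumeration bound.
#' @return `NULL` when no witness exists; otherwise a list with `theta1`
#'   (the graph's own isoform frequencies), `theta2`, `isoforms` and
#'   `max_placement_diff` (verified maximal absolute difference between the
#'   two placement distributions).
#' @export
demonstrate_nonidentifiability <- function(g, read_length, max_count = 10000L) {
  iso <- enumerate_isoforms(g, max_count = max_count)
  if (nrow(iso) < 2L) return(NULL)
  tpaths <- chain_split(iso$path)
  plc <- census_placements(g, read_length)
  key <- paste(plc$chain, plc$polya > 0L)
  classes <- !duplicated(key)
  C <- t(vapply(which(classes), function(i) {
    ch <- chain_split(plc$chain[i])[[1L]]
    vapply(tpaths, function(tp) as.numeric(chain_in_path(ch, tp, plc$polya[i] > 0L)), 0)
  }, numeric(nrow(iso))))
  M <- rbind(C, 1)
  sv <- svd(M, nu = 0L, nv = ncol(M))
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  if (rank >= ncol(M)) return(NULL)
  ns <- sv$v[, seq.int(rank + 1L, ncol(M)), drop = FALSE]
  theta1 <- iso$prob
  best <- NULL; bestgam <- 0
  for (j in seq_len(ncol(ns))) for (sgn in c(1, -1)) {
    z <- sgn * ns[, j]
    neg <- z < -1e-12
    if (!any(neg)) next
    gam <- min(-theta1[neg] / z[neg])
    if (gam > bestgam) { bestgam <- gam; best <- z }
  }
  if (is.null(best) || bestgam < 1e-9) return(NULL)
  theta2 <- theta1 + bestgam * best
  theta2[abs(theta2) < 1e-15] <- 0
  ## verify: identical expected placement distributions
  mu1 <- sum(theta1 * iso$length); mu2 <- sum(theta2 * iso$length)
  p1 <- as.numeric(C %*% theta1) / mu1
  p2 <- as.numeric(C %*% theta2) / mu2
  list(theta1 = theta1, theta2 = theta2, isoforms = iso,
       max_placement_diff = max(abs(p1 - p2)))
}
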