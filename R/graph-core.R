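#' @import methods
#' @importFrom stats runif rnorm setNames pchisq p.adjust uniroot rmultinom
#' @importFrom utils head tail write.table read.table
NULL

SIMPLEX_TOL <- 1e-9

## ---------------------------------------------------------------------------
## Probabilistic splice graph (PSG): a weighted DAG with a start vertex v0 and
## an end vertex vM (both with empty sequences), in which every isoform is a
## v0 -> vM path whose probability is the product of its edge weights, and the
## out-edge weights of each vertex form a probability simplex.
## ---------------------------------------------------------------------------

#' Construct a probabilistic splice graph
#'
#' A PSG is a directed acyclic graph with a unique source (`v0`, in-degree 0)
#' and a unique sink (`vM`, out-degree 0), both carrying empty sequences.
#' Every other vertex carries a non-empty nucleotide sequence (an exonic
#' segment, exon, or exon-with-context depending on the graph flavor).  The
#' out-edge weights of each vertex sum to one and act as conditional
#' probabilities of alternative processing events; the probability of an
#' isoform is the product of the edge weights along its path.
#'
#' @param gene_id Gene identifier (no whitespace, `|`, `,` or `:`).
#' @param vertices Data frame with columns `id` and `seq` (and optionally
#'   `chrom`, `start`, `end`, `strand` genomic provenance).  The start/end
#'   vertices are recognised by their empty sequences together with their
#'   in/out degrees.
#' @param edges Data frame with columns `from`, `to` and `weight`.
#' @param beta Dirichlet concentration for every edge (scalar, or a vector
#'   aligned with the rows of `edges`).  `beta = 1` makes MAP estimation
#'   coincide with maximum likelihood.
#' @param validate Check all PSG invariants and raise an error if violated.
#'   Set to `FALSE` to build a possibly invalid graph for inspection with
#'   [validate_graph()].
#' @return An object of class `splice_graph`.
#' @seealso [validate_graph()], [inclusion_probability()], [expected_lengths()]
#' @export
splice_graph <- function(gene_id, vertices, edges, beta = 1, validate = TRUE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "seq") %in% names(vertices)),
            all(c("from", "to", "weight") %in% names(edges)))
  ids <- as.character(vertices$id)
  if (anyDuplicated(ids)) stop("duplicated vertex ids")
  if (any(grepl("[|,: \t]", c(ids, gene_id))))
    stop("identifiers must not contain '|', ',', ':' or whitespace")

  g <- list(gene_id = gene_id)
  class(g) <- "splice_graph"
  g$ids <- ids
  g$seq <- setNames(toupper(as.character(vertices$seq)), ids)
  g$len <- setNames(nchar(g$seq), ids)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (length(beta) == 1L) beta <- rep(beta, nrow(edges))
  edges$beta <- as.numeric(beta)
  g$edges <- edges
  if (all(c("chrom", "start", "end", "strand") %in% names(vertices)))
    g$provenance <- vertices[c("id", "chrom", "start", "end", "strand")]

  g <- psg_index(g)
  if (validate) {
    rep <- validate_graph(g)
    if (length(rep)) stop("invalid splice graph:\n  ", paste(rep, collapse = "\n  "))
    ## silent renormalization of sub-tolerance simplex drift
    g <- psg_renormalize(g)
  }
  g
}

## Build adjacency indexes, topological order and a DP cache.  Tolerant of
## invalid graphs (cycles leave topo_ok FALSE) so validate_graph can report.
psg_index <- function(g) {
  ids <- g$ids
  n <- length(ids)
  vi <- setNames(seq_len(n), ids)
  unknown <- setdiff(c(g$edges$from, g$edges$to), ids)
  if (length(unknown))
    stop("edge references unknown vertex: ", paste(unknown, collapse = ", "))
  g$eFrom <- vi[g$edges$from]
  g$eTo <- vi[g$edges$to]
  g$out <- lapply(seq_len(n), function(i) which(g$eFrom == i))
  g$inn <- lapply(seq_len(n), function(i) which(g$eTo == i))
  indeg <- lengths(g$inn)
  outdeg <- lengths(g$out)
  ## Kahn topological sort
  ord <- integer(0)
  deg <- indeg
  queue <- which(deg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (e in g$out[[v]]) {
      w <- g$eTo[e]
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  g$topo <- ord
  g$topo_ok <- length(ord) == n
  src <- which(indeg == 0L)
  snk <- which(outdeg == 0L)
  g$v0 <- if (length(src) == 1L) ids[src] else NA_character_
  g$vM <- if (length(snk) == 1L) ids[snk] else NA_character_
  g$cache <- new.env(parent = emptyenv())
  g
}

psg_vi <- function(g, id) {
  i <- match(id, g$ids)
  if (anyNA(i)) stop("unknown vertex id: ", paste(id[is.na(i)], collapse = ", "))
  i
}

psg_renormalize <- function(g) {
  w <- g$edges$weight
  for (i in seq_along(g$ids)) {
    e <- g$out[[i]]
    if (length(e)) w[e] <- w[e] / sum(w[e])
  }
  g$edges$weight <- w
  g$cache <- new.env(parent = emptyenv())
  g
}

#' Replace the edge weights of a PSG
#'
#' Returns a new graph whose edge weights (aligned with `g$edges` rows) are
#' `weights`; per-vertex simplex normalization is re-checked.
#'
#' @param g A `splice_graph`.
#' @param weights Numeric vector, one value per edge row.
#' @export
set_edge_weights <- function(g, weights) {
  stopifnot(length(weights) == nrow(g$edges), all(weights >= 0))
  g$edges$weight <- as.numeric(weights)
  for (i in seq_along(g$ids)) {
    e <- g$out[[i]]
    if (!length(e)) next
    s <- sum(weights[e])
    if (abs(s - 1) > 1e-6) stop("out-edge weights of '", g$ids[i],
                                "' sum to ", format(s), ", not 1")
  }
  psg_renormalize(g)
}

#' Validate a probabilistic splice graph
#'
#' Checks every structural invariant of a PSG and returns a character vector
#' describing each violation (empty when the graph is valid): DAG-ness, unique
#' source `v0` and sink `vM`, reachability of every vertex from `v0` and
#' co-reachability to `vM`, per-vertex out-edge probability simplexes (within
#' `1e-9`), empty terminal sequences and non-empty internal sequences.
#'
#' @param g A `splice_graph` (possibly built with `validate = FALSE`).
#' @return Character vector of violations; `character(0)` iff valid.
#' @export
validate_graph <- function(g) {
  rep <- character(0)
  n <- length(g$ids)
  indeg <- lengths(g$inn); outdeg <- lengths(g$out)
  if (!g$topo_ok) rep <- c(rep, "graph contains a cycle (not a DAG)")
  if (sum(indeg == 0L) != 1L)
    rep <- c(rep, sprintf("expected exactly one vertex with in-degree 0, found %d",
                          sum(indeg == 0L)))
  if (sum(outdeg == 0L) != 1L)
    rep <- c(rep, sprintf("expected exactly one vertex with out-degree 0, found %d",
                          sum(outdeg == 0L)))
  dup <- g$edges[duplicated(g$edges[c("from", "to")]), , drop = FALSE]
  if (nrow(dup)) rep <- c(rep, "duplicated edges")
  ## simplex
  for (i in seq_len(n)) {
    e <- g$out[[i]]
    if (!length(e)) next
    w <- g$edges$weight[e]
    if (any(w < 0 | w > 1))
      rep <- c(rep, sprintf("vertex '%s' has out-edge weight outside [0,1]", g$ids[i]))
    else if (abs(sum(w) - 1) > SIMPLEX_TOL)
      rep <- c(rep, sprintf("out-edge weights of vertex '%s' sum to %.12g, not 1",
                            g$ids[i], sum(w)))
  }
  if (any(g$edges$beta <= 0)) rep <- c(rep, "Dirichlet beta values must be positive")
  ## sequences
  if (!is.na(g$v0) && nzchar(g$seq[g$v0]))
    rep <- c(rep, "start vertex must have an empty sequence")
  if (!is.na(g$vM) && nzchar(g$seq[g$vM]))
    rep <- c(rep, "end vertex must have an empty sequence")
  internal <- setdiff(g$ids, c(g$v0, g$vM))
  bad <- internal[!nzchar(g$seq[internal])]
  if (length(bad))
    rep <- c(rep, paste0("internal vertex with empty sequence: ",
                         paste(bad, collapse = ", ")))
  ## reachability (structural, ignores weights)
  if (g$topo_ok && !is.na(g$v0) && !is.na(g$vM)) {
    fw <- rep(FALSE, n); fw[psg_vi(g, g$v0)] <- TRUE
    for (v in g$topo) if (fw[v]) for (e in g$out[[v]]) fw[g$eTo[e]] <- TRUE
    bw <- rep(FALSE, n); bw[psg_vi(g, g$vM)] <- TRUE
    for (v in rev(g$topo)) if (bw[v]) for (e in g$inn[[v]]) bw[g$eFrom[e]] <- TRUE
    off <- g$ids[!(fw & bw)]
    if (length(off))
      rep <- c(rep, paste0("vertex not on any v0->vM path: ",
                           paste(off, collapse = ", ")))
  }
  rep
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph '%s': %d vertices (%d internal), %d edges, %d free parameters\n",
              x$gene_id, length(x$ids), length(x$ids) - 2L, nrow(x$edges),
              free_parameter_count(x)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## DAG dynamic programming: inclusion probabilities and expected lengths
## ---------------------------------------------------------------------------

## F(i, .) for all vertices, by one forward sweep from source i (memoized).
psg_inclusion_from <- function(g, i) {
  key <- paste0("F", i)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(g$ids)
  r <- numeric(n)
  r[i] <- 1
  pos <- match(i, g$topo)
  w <- g$edges$weight
  for (v in g$topo[seq(pos, length(g$topo))]) {
    rv <- r[v]
    if (rv == 0) next
    for (e in g$out[[v]]) r[g$eTo[e]] <- r[g$eTo[e]] + rv * w[e]
  }
  g$cache[[key]] <- r
  r
}

#' Vertex inclusion probability F(i, j)
#'
#' The conditional probability that vertex `j` occurs on an isoform path given
#' that vertex `i` does, computed by the DAG recurrence
#' `F(i, j) = sum over out-edges (i, x) of weight(i, x) * F(x, j)` with
#' `F(i, i) = 1`, in one dynamic-programming sweep per source vertex
#' (memoized).  `F(i, j) = 0` when `j` is not reachable from `i`.
#'
#' @param g A valid `splice_graph`.
#' @param i,j Vertex ids.  If `j` is missing, the vector `F(i, .)` over all
#'   vertices is returned (named).
#' @return A probability, or a named probability vector.
#' @export
inclusion_probability <- function(g, i, j) {
  vi <- psg_vi(g, i)
  r <- psg_inclusion_from(g, vi)
  if (missing(j)) return(setNames(r, g$ids))
  unname(r[psg_vi(g, j)])
}

#' Expected prefix/suffix and transcript lengths
#'
#' For each vertex the expected prefix length (expected length of the subpath
#' from `v0` through the vertex, given the vertex is on the path) and expected
#' suffix length (from the vertex through `vM`), via one topological sweep in
#' each direction; and the expected transcript length
#' `mu = lambda_suf(v0) = lambda_pre(vM)`.
#'
#' @param g A valid `splice_graph`.
#' @return A list with named vectors `lambda_pre`, `lambda_suf` and scalar `mu`.
#' @export
expected_lengths <- function(g) {
  hit <- g$cache[["lengths"]]
  if (!is.null(hit)) return(hit)
  n <- length(g$ids)
  w <- g$edges$weight
  len <- as.numeric(g$len)
  ## suffix: backward
  suf <- numeric(n)
  for (v in rev(g$topo)) {
    s <- 0
    for (e in g$out[[v]]) s <- s + w[e] * suf[g$eTo[e]]
    suf[v] <- len[v] + s
  }
  ## prefix: forward, weighting predecessors by P(u on path | v on path)
  Fv0 <- psg_inclusion_from(g, psg_vi(g, g$v0))
  pre <- numeric(n)
  for (v in g$topo) {
    s <- 0
    if (Fv0[v] > 0) {
      for (e in g$inn[[v]]) {
        u <- g$eFrom[e]
        s <- s + (Fv0[u] * w[e] / Fv0[v]) * pre[u]
      }
    }
    pre[v] <- len[v] + s
  }
  out <- list(lambda_pre = setNames(pre, g$ids),
              lambda_suf = setNames(suf, g$ids),
              mu = suf[psg_vi(g, g$v0)])
  g$cache[["lengths"]] <- out
  out
}

#' Weight of a subpath
#'
#' The product of the edge weights along a connected vertex chain; a
#' single-vertex subpath has weight 1 (empty product).
#'
#' @param g A `splice_graph`.
#' @param path Character vector of vertex ids forming a connected path.
#' @export
subpath_weight <- function(g, path) {
  vs <- psg_vi(g, path)
  if (length(vs) < 2L) return(1)
  e <- psg_edge_ids(g, vs)
  prod(g$edges$weight[e])
}

## edge row indices for consecutive pairs of a vertex-index chain
psg_edge_ids <- function(g, vs) {
  k <- length(vs) - 1L
  ek <- paste(g$eFrom, g$eTo)
  e <- match(paste(vs[-length(vs)], vs[-1L]), ek)
  if (anyNA(e)) {
    bad <- which(is.na(e))[1L]
    stop(sprintf("no edge %s -> %s in graph '%s'",
                 g$ids[vs[bad]], g$ids[vs[bad + 1L]], g$gene_id))
  }
  e
}

#' Number of v0 -> vM paths
#'
#' Path count by dynamic programming (no enumeration).
#' @param g A valid `splice_graph`.
#' @export
count_isoforms <- function(g) {
  n <- length(g$ids)
  cnt <- numeric(n)
  cnt[psg_vi(g, g$vM)] <- 1
  for (v in rev(g$topo)) {
    if (cnt[v] > 0) next
    s <- 0
    for (e in g$out[[v]]) s <- s + cnt[g$eTo[e]]
    cnt[v] <- s
  }
  cnt[psg_vi(g, g$v0)]
}

#' Enumerate all isoforms of a PSG
#'
#' All complete `v0 -> vM` paths together with their probabilities (products
#' of edge weights).  Because the number of paths can grow exponentially with
#' the number of alternative processing events, enumeration refuses to run
#' when the path count (computed first by dynamic programming) exceeds
#' `max_count`.
#'
#' @param g A valid `splice_graph`.
#' @param max_count Refusal bound on the number of paths.
#' @return A data frame with columns `path` (comma-joined internal vertex
#'   ids), `prob` and `length` (total sequence length).
#' @export
enumerate_isoforms <- function(g, max_count = 10000L) {
  np <- count_isoforms(g)
  if (np > max_count)
    stop(sprintf("graph '%s' has %s complete paths, exceeding max_count = %s; %s",
                 g$gene_id, format(np, big.mark = ","), format(max_count, big.mark = ","),
                 "use the dynamic-programming quantities instead of enumeration"))
  v0 <- psg_vi(g, g$v0); vM <- psg_vi(g, g$vM)
  w <- g$edges$weight
  paths <- list(); probs <- numeric(0); lens <- numeric(0)
  rec <- function(v, chain, p, l) {
    if (v == vM) {
      paths[[length(paths) + 1L]] <<- chain
      probs[length(probs) + 1L] <<- p
      lens[length(lens) + 1L] <<- l
      return(invisible())
    }
    for (e in g$out[[v]]) rec(g$eTo[e], c(chain, g$eTo[e]), p * w[e], l + g$len[g$eTo[e]])
  }
  rec(v0, integer(0), 1, 0)
  data.frame(
    path = vapply(paths, function(ch) paste(g$ids[ch[-length(ch)]], collapse = ","), ""),
    prob = probs,
    length = lens,
    stringsAsFactors = FALSE)
}

#' Number of free parameters of a PSG
#'
#' The sum over vertices of (out-degree - 1): each vertex's out-edge simplex
#' contributes one fewer free parameter than it has edges.  This is the
#' degrees of freedom of the gene-level differential-processing test.
#'
#' @param g A `splice_graph`.
#' @export
free_parameter_count <- function(g) {
  sum(pmax(lengths(g$out) - 1L, 0L))
}

## internal vertex ids (everything but v0/vM)
psg_internal <- function(g) setdiff(g$ids, c(g$v0, g$vM))

## named out-edge weight vectors per branch vertex (out-degree >= 2)
psg_branch_weights <- function(g) {
  br <- which(lengths(g$out) >= 2L)
  setNames(lapply(br, function(i) {
    e <- g$out[[i]]
    setNames(g$edges$weight[e], g$ids[g$eTo[e]])
  }), g$ids[br])
}
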