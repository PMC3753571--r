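## ---------------------------------------------------------------------------
## Building PSGs from transcript annotations.  Transcripts are held in a flat
## data frame (one row per exon) with 0-based half-open genomic coordinates;
## minus-strand genes are normalized at parse time into transcription
## orientation via negated coordinates (tstart = -end, tend = -start), so all
## graph logic sees coordinates that increase 5' -> 3'.
## ---------------------------------------------------------------------------

#' Assemble a transcript table
#'
#' @param transcript_id,gene_id,strand,start,end Vectors (one element per
#'   exon) with 0-based half-open genomic coordinates.
#' @param chrom Chromosome (default `"chr"`).
#' @return Data frame of class `transcript_models` in transcription order,
#'   with internal transcription-oriented columns `tstart`/`tend`.
#' @export
transcript_models <- function(transcript_id, gene_id, strand, start, end,
                              chrom = "chr") {
  df <- data.frame(transcript_id = as.character(transcript_id),
                   gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("exon with end <= start")
  bad <- tapply(df$strand, df$transcript_id, function(s) length(unique(s)) > 1L)
  if (any(bad)) stop("transcript on mixed strands: ",
                     paste(names(bad)[bad], collapse = ", "))
  df$tstart <- ifelse(df$strand == "+", df$start, -df$end)
  df$tend <- ifelse(df$strand == "+", df$end, -df$start)
  df <- df[order(df$transcript_id, df$tstart), ]
  ## overlapping exons within a transcript
  for (tid in unique(df$transcript_id)) {
    e <- df[df$transcript_id == tid, ]
    if (nrow(e) > 1L && any(e$tstart[-1L] < e$tend[-nrow(e)]))
      stop("overlapping exons within transcript ", tid)
  }
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Project exon boundaries onto maximal segments
#'
#' The union of all exon start/end positions of a gene's transcripts cuts the
#' exonic footprint into maximal segments; every transcript's exon chain is
#' then exactly a concatenation of segments.  These segments are the vertices
#' of the line-graph flavor.
#'
#' @param transcripts A `transcript_models` table for one gene (one strand).
#' @return A list with `segments` (data frame `seg_id`, `tstart`, `tend`,
#'   `length`) and `chains` (named list: transcript -> ordered `seg_id`s).
#' @export
project_segments <- function(transcripts) {
  stopifnot(length(unique(transcripts$gene_id)) == 1L,
            length(unique(transcripts$strand)) == 1L)
  bounds <- sort(unique(c(transcripts$tstart, transcripts$tend)))
  cand <- data.frame(tstart = bounds[-length(bounds)], tend = bounds[-1L])
  inside <- vapply(seq_len(nrow(cand)), function(i)
    any(transcripts$tstart <= cand$tstart[i] & transcripts$tend >= cand$tend[i]), NA)
  seg <- cand[inside, , drop = FALSE]
  rownames(seg) <- NULL
  seg$seg_id <- sprintf("s%d", seq_len(nrow(seg)))
  seg$length <- seg$tend - seg$tstart
  chains <- lapply(split(transcripts, transcripts$transcript_id), function(e) {
    e <- e[order(e$tstart), ]
    unlist(lapply(seq_len(nrow(e)), function(i) {
      hit <- seg$seg_id[seg$tstart >= e$tstart[i] & seg$tend <= e$tend[i]]
      hit
    }), use.names = FALSE)
  })
  list(segments = seg[c("seg_id", "tstart", "tend", "length")], chains = chains)
}

## fetch the transcription-oriented sequence for a [tstart, tend) interval
interval_seq <- function(chrom, tstart, tend, strand, genome) {
  if (is.null(genome)) return(strrep("N", tend - tstart))
  gs <- if (strand == "+") c(tstart, tend) else c(-tend, -tstart)
  s <- substr(as.character(genome[[chrom]]), gs[1L] + 1L, gs[2L])
  if (nchar(s) != tend - tstart)
    stop("interval outside genome sequence for ", chrom)
  if (strand == "+") toupper(s) else revcomp(toupper(s))
}

#' Build a PSG from transcript annotations
#'
#' Flavors:
#' \describe{
#'   \item{`line`}{One vertex per projected segment; edge `u -> v` iff `u`
#'     immediately precedes `v` in some transcript.  Assumes independence
#'     between all compatible processing events.}
#'   \item{`exon` (order 1)}{One vertex per distinct annotated exon
#'     (identical coordinates merged); allows dependencies between the events
#'     at an exon's two ends.}
#'   \item{`exon` (order h > 1)}{Vertices are exons annotated with their
#'     (h-1)-exon left context, duplicated as needed — the analogue of a
#'     higher-order Markov chain.}
#'   \item{`unfactorized`}{One disjoint path per annotated transcript
#'     (identical exon chains deduplicated); statistically equivalent to a
#'     full-length isoform model.}
#' }
#' All flavors receive start-vertex edges to every transcription start and
#' end-vertex edges from every transcript end; edge weights start uniform
#' per vertex.  Construction is deterministic: vertices are ordered by
#' transcription coordinate, then context.
#'
#' @param transcripts A `transcript_models` table for one gene.
#' @param flavor `"line"`, `"exon"` or `"unfactorized"`.
#' @param order Markov order for `exon` graphs (>= 1); ignored otherwise.
#' @param genome Named list / `DNAStringSet`-like of chromosome sequences
#'   (optional; `N` placeholder sequences otherwise).
#' @return A valid `splice_graph`.
#' @export
build_graph <- function(transcripts, flavor = c("exon", "line", "unfactorized"),
                        order = 1L, genome = NULL) {
  flavor <- match.arg(flavor)
  if (nrow(transcripts) == 0L) stop("empty transcript set")
  if (flavor == "exon" && order < 1L) stop("order must be >= 1")
  gene <- unique(transcripts$gene_id)
  stopifnot(length(gene) == 1L)
  strand <- unique(transcripts$strand)
  chrom <- unique(transcripts$chrom)
  stopifnot(length(strand) == 1L)

  tr_exons <- lapply(split(transcripts, transcripts$transcript_id),
                     function(e) e[order(e$tstart), c("tstart", "tend")])
  ## deduplicate identical exon chains
  sig <- vapply(tr_exons, function(e) paste(e$tstart, e$tend, collapse = ";"), "")
  tr_exons <- tr_exons[!duplicated(sig)]

  if (flavor == "line") {
    proj <- project_segments(transcripts)
    seg <- proj$segments
    key <- paste(seg$tstart, seg$tend)
    ord <- order(seg$tstart, seg$tend)
    seg <- seg[ord, ]
    vid <- sprintf("s%d", seq_len(nrow(seg)))
    names(vid) <- paste(seg$tstart, seg$tend)
    chains <- lapply(proj$chains[!duplicated(sig)], function(ch) {
      m <- proj$segments[match(ch, proj$segments$seg_id), ]
      unname(vid[paste(m$tstart, m$tend)])
    })
    vseq <- vapply(seq_len(nrow(seg)), function(i)
      interval_seq(chrom, seg$tstart[i], seg$tend[i], strand, genome), "")
    vdf <- data.frame(id = vid, seq = vseq,
                      chrom = chrom,
                      start = if (strand == "+") seg$tstart else -seg$tend,
                      end = if (strand == "+") seg$tend else -seg$tstart,
                      strand = strand, stringsAsFactors = FALSE)
  } else if (flavor == "exon") {
    ## distinct exon occurrences with (order-1)-exon left context
    occ <- list()
    chains <- lapply(tr_exons, function(e) {
      n <- nrow(e)
      keys <- character(n)
      for (i in seq_len(n)) {
        ctx <- if (order > 1L && i > 1L) {
          j <- seq.int(max(1L, i - order + 1L), i - 1L)
          paste(e$tstart[j], e$tend[j], sep = ".", collapse = ";")
        } else ""
        keys[i] <- paste0(e$tstart[i], ".", e$tend[i], "|", ctx)
        occ[[keys[i]]] <<- c(e$tstart[i], e$tend[i])
      }
      keys
    })
    keys <- names(occ)
    st <- vapply(occ, `[`, 0, 1L); en <- vapply(occ, `[`, 0, 2L)
    ord <- order(st, en, keys)
    keys <- keys[ord]; st <- st[ord]; en <- en[ord]
    vid <- sprintf("e%d", seq_along(keys))
    names(vid) <- keys
    chains <- lapply(chains, function(k) unname(vid[k]))
    vseq <- vapply(seq_along(keys), function(i)
      interval_seq(chrom, st[i], en[i], strand, genome), "")
    vdf <- data.frame(id = vid, seq = vseq,
                      chrom = chrom,
                      start = if (strand == "+") st else -en,
                      end = if (strand == "+") en else -st,
                      strand = strand, stringsAsFactors = FALSE)
  } else {  ## unfactorized
    vdf <- NULL; chains <- list()
    tnames <- names(tr_exons)
    for (k in seq_along(tr_exons)) {
      e <- tr_exons[[k]]
      vid <- sprintf("t%d.%d", k, seq_len(nrow(e)))
      vseq <- vapply(seq_len(nrow(e)), function(i)
        interval_seq(chrom, e$tstart[i], e$tend[i], strand, genome), "")
      vdf <- rbind(vdf, data.frame(
        id = vid, seq = vseq, chrom = chrom,
        start = if (strand == "+") e$tstart else -e$tend,
        end = if (strand == "+") e$tend else -e$tstart,
        strand = strand, stringsAsFactors = FALSE))
      chains[[tnames[k]]] <- vid
    }
  }

  ## edges from within-transcript adjacency
  ef <- character(0); et <- character(0)
  for (ch in chains) {
    ef <- c(ef, "v0", ch)
    et <- c(et, ch, "vM")
  }
  keep <- !duplicated(paste(ef, et))
  edges <- data.frame(from = ef[keep], to = et[keep], weight = 0,
                      stringsAsFactors = FALSE)
  ## deterministic edge order: by source vertex order, then target
  vorder <- c("v0", vdf$id, "vM")
  edges <- edges[order(match(edges$from, vorder), match(edges$to, vorder)), ]
  for (v in unique(edges$from))
    edges$weight[edges$from == v] <- 1 / sum(edges$from == v)
  vertices <- rbind(
    data.frame(id = "v0", seq = "", chrom = chrom, start = NA_real_,
               end = NA_real_, strand = strand, stringsAsFactors = FALSE),
    vdf,
    data.frame(id = "vM", seq = "", chrom = chrom, start = NA_real_,
               end = NA_real_, strand = strand, stringsAsFactors = FALSE))
  g <- splice_graph(gene, vertices, edges)
  g$annotated_paths <- chains
  g
}

## ---------------------------------------------------------------------------
## Reference window extraction
## ---------------------------------------------------------------------------

## Enumerate all junction chains [c1, ..., ck] (k >= 2) such that a length-L
## read can touch both c1 and ck: inner length sum(l(c2..c_{k-1})) <= L - 2.
## Chains may end at vM, which acts as a poly(A) pseudo-vertex of length L-1.
enum_junction_chains <- function(g, L) {
  vM <- psg_vi(g, g$vM)
  v0 <- psg_vi(g, g$v0)
  res <- list()
  emit <- function(ch) res[[length(res) + 1L]] <<- ch
  dfs <- function(chain, inner_len) {
    last <- chain[length(chain)]
    for (e in g$out[[last]]) {
      nv <- g$eTo[e]
      emit(c(chain, nv))
      if (nv != vM && inner_len + g$len[nv] <= L - 2L)
        dfs(c(chain, nv), inner_len + g$len[nv])
    }
  }
  for (v in seq_along(g$ids)) {
    if (v == v0 || v == vM) next
    dfs(v, 0L)
  }
  res
}

#' Extract alignment reference sequences for a PSG
#'
#' Emits every window needed so that any length-`L` read derivable from any
#' subpath (including reads overhanging into the poly(A) tail) aligns
#' contiguously to at least one emitted sequence: one record per internal
#' vertex, plus one junction record per junction chain, consisting of up to
#' `L - 1` terminal bases of the first vertex, the full inner vertices
#' (recursively included while shorter than `L - 1`), and up to `L - 1`
#' initial bases of the last vertex (the end vertex contributing `L - 1`
#' poly(A) bases).  Record names are `gene|v1,v2,...|offset`, with `offset`
#' the 0-based position of the window start within the first vertex, so
#' alignment positions convert directly to subpath placements.
#'
#' @param g A valid `splice_graph`.
#' @param read_length Read length `L` (>= 1).
#' @return Data frame with columns `name`, `chain`, `offset`, `seq`.
#' @export
extract_reference_sequences <- function(g, read_length) {
  stopifnot(read_length >= 1L)
  L <- as.integer(read_length)
  vM <- psg_vi(g, g$vM)
  internal <- setdiff(seq_along(g$ids), psg_vi(g, c(g$v0, g$vM)))
  recs <- data.frame(name = sprintf("%s|%s|0", g$gene_id, g$ids[internal]),
                     chain = g$ids[internal], offset = 0L,
                     seq = unname(g$seq[internal]), stringsAsFactors = FALSE)
  if (L >= 2L) {
    jc <- enum_junction_chains(g, L)
    if (length(jc)) {
      rows <- lapply(jc, function(ch) {
        first <- ch[1L]; last <- ch[length(ch)]
        flank1 <- min(L - 1L, g$len[first])
        off <- g$len[first] - flank1
        parts <- substr(g$seq[first], off + 1L, g$len[first])
        if (length(ch) > 2L)
          parts <- c(parts, g$seq[ch[seq.int(2L, length(ch) - 1L)]])
        lastseq <- if (last == vM) strrep("A", L - 1L) else
          substr(g$seq[last], 1L, min(L - 1L, g$len[last]))
        cstr <- paste(g$ids[ch], collapse = ",")
        data.frame(name = sprintf("%s|%s|%d", g$gene_id, cstr, off),
                   chain = cstr, offset = off,
                   seq = paste(c(parts, lastseq), collapse = ""),
                   stringsAsFactors = FALSE)
      })
      recs <- rbind(recs, do.call(rbind, rows))
    }
  }
  rownames(recs) <- NULL
  recs
}
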