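## ---------------------------------------------------------------------------
## Readers/writers: GTF annotations (rtracklayer), FASTA/FASTQ (Biostrings),
## SAM alignments against graph reference windows (Rsamtools), the package's
## plain-text PSG serialization, and results tables.  All writers use stable
## orderings so identical inputs give byte-identical outputs.
## ---------------------------------------------------------------------------

#' Read transcript models from a GTF file
#'
#' Keeps `exon` features, requires `gene_id` and `transcript_id` attributes,
#' converts 1-based inclusive coordinates to the internal 0-based half-open
#' convention, and normalizes strand so exons are in transcription order.
#'
#' @param path GTF file.
#' @return A `transcript_models` data frame (see [transcript_models()]).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id))
    stop("GTF exon records must carry gene_id and transcript_id attributes")
  transcript_models(
    transcript_id = md$transcript_id,
    gene_id = md$gene_id,
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)))
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' @param reads Data frame from [simulate_fragments()] (`id`, `seq1`,
#'   optionally `seq2`).
#' @param path Output FASTQ for single-end data or mate 1.
#' @param path2 Output FASTQ for mate 2 (required for paired data).
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  wr <- function(ids, seqs, p) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, p, format = "fastq")
  }
  wr(reads$id, reads$seq1, path)
  if (!is.null(reads$seq2)) {
    if (is.null(path2)) stop("paired reads need path2")
    wr(reads$id, reads$seq2, path2)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return Data frame with `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## PSG serialization: a tab-separated dialect
##   G <gene_id>
##   V <id> <length> [chrom:start-end:strand]
##   E <from> <to> <weight> [beta]
## with vertex sequences in a companion FASTA keyed "geneID:vertexID".
## ---------------------------------------------------------------------------

#' Write PSGs to the package's serialization format
#'
#' @param graphs A `splice_graph` or list of them.
#' @param path Output graph file.
#' @param fasta_path Companion FASTA of vertex sequences (default
#'   `paste0(path, ".fa")`; `NULL` to skip).
#' @export
write_psg <- function(graphs, path, fasta_path = paste0(path, ".fa")) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  lines <- character(0)
  seqs <- character(0)
  for (g in graphs) {
    lines <- c(lines, paste0("G\t", g$gene_id))
    prov <- g$provenance
    for (i in seq_along(g$ids)) {
      id <- g$ids[i]
      pv <- ""
      if (!is.null(prov)) {
        r <- prov[prov$id == id, , drop = FALSE]
        if (nrow(r) == 1L && !is.na(r$start))
          pv <- sprintf("\t%s:%d-%d:%s", r$chrom, as.integer(r$start),
                        as.integer(r$end), r$strand)
      }
      lines <- c(lines, sprintf("V\t%s\t%d%s", id, g$len[i], pv))
      if (g$len[i] > 0L)
        seqs[paste0(g$gene_id, ":", id)] <- unname(g$seq[id])
    }
    anybeta <- any(g$edges$beta != 1)
    for (j in seq_len(nrow(g$edges))) {
      lines <- c(lines, sprintf("E\t%s\t%s\t%.12g%s", g$edges$from[j],
                                g$edges$to[j], g$edges$weight[j],
                                if (anybeta) sprintf("\t%.12g", g$edges$beta[j]) else ""))
    }
  }
  writeLines(lines, path)
  if (!is.null(fasta_path) && length(seqs)) write_fasta(seqs, fasta_path)
  invisible(path)
}

#' Read PSGs from the package's serialization format
#'
#' @param path Graph file written by [write_psg()].
#' @param fasta_path Companion FASTA (default `paste0(path, ".fa")` when it
#'   exists; without it, placeholder `N` sequences of the recorded lengths
#'   are used).
#' @return A named list of `splice_graph`s.
#' @export
read_psg <- function(path, fasta_path = paste0(path, ".fa")) {
  lines <- readLines(path)
  seqs <- if (!is.null(fasta_path) && file.exists(fasta_path))
    read_fasta(fasta_path) else character(0)
  graphs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    vs <- cur$vertices
    vs$seq <- vapply(seq_len(nrow(vs)), function(i) {
      if (vs$len[i] == 0L) return("")
      key <- paste0(cur$gene, ":", vs$id[i])
      if (key %in% names(seqs)) seqs[[key]] else strrep("N", vs$len[i])
    }, "")
    g <- splice_graph(cur$gene, vs[c("id", "seq", "chrom", "start", "end", "strand")],
                      cur$edges, beta = cur$edges$beta)
    g
  }
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (!length(f) || !nzchar(f[1L])) next
    if (f[1L] == "G") {
      if (!is.null(cur)) graphs[[cur$gene]] <- flush(cur)
      if (length(f) != 2L) stop("malformed G line at line ", ln)
      cur <- list(gene = f[2L],
                  vertices = data.frame(id = character(0), len = integer(0),
                                        chrom = character(0), start = numeric(0),
                                        end = numeric(0), strand = character(0),
                                        stringsAsFactors = FALSE),
                  edges = data.frame(from = character(0), to = character(0),
                                     weight = numeric(0), beta = numeric(0),
                                     stringsAsFactors = FALSE))
    } else if (f[1L] == "V") {
      if (is.null(cur) || length(f) < 3L) stop("malformed V line at line ", ln)
      prov <- c(NA_character_, NA_real_, NA_real_, NA_character_)
      if (length(f) >= 4L && nzchar(f[4L])) {
        m <- regmatches(f[4L], regexec("^(.+):(-?\\d+)-(-?\\d+):([+-])$", f[4L]))[[1L]]
        if (length(m) != 5L) stop("malformed provenance at line ", ln)
        prov <- c(m[2L], as.numeric(m[3L]), as.numeric(m[4L]), m[5L])
      }
      cur$vertices <- rbind(cur$vertices, data.frame(
        id = f[2L], len = as.integer(f[3L]), chrom = prov[1L],
        start = as.numeric(prov[2L]), end = as.numeric(prov[3L]),
        strand = prov[4L], stringsAsFactors = FALSE))
    } else if (f[1L] == "E") {
      if (is.null(cur) || length(f) < 4L) stop("malformed E line at line ", ln)
      w <- suppressWarnings(as.numeric(f[4L]))
      if (is.na(w)) stop("malformed edge weight at line ", ln)
      b <- if (length(f) >= 5L) as.numeric(f[5L]) else 1
      if (!all(c(f[2L], f[3L]) %in% cur$vertices$id))
        stop("edge references unknown vertex at line ", ln)
      cur$edges <- rbind(cur$edges, data.frame(
        from = f[2L], to = f[3L], weight = w, beta = b, stringsAsFactors = FALSE))
    } else stop("unrecognized record '", f[1L], "' at line ", ln)
  }
  if (!is.null(cur)) graphs[[cur$gene]] <- flush(cur)
  graphs
}

## ---------------------------------------------------------------------------
## SAM alignments against reference windows
## ---------------------------------------------------------------------------

## decode a window hit: reference "gene|v1,v2,...|offset" + 1-based pos +
## read length -> minimal SubpathAlignment (chain, b, polya)
decode_window_hit <- function(g, chain_ids, win_offset, pos, read_len) {
  vs <- psg_vi(g, chain_ids)
  lens <- as.numeric(g$len[vs])
  isM <- chain_ids == g$vM
  lens[isM] <- Inf  # poly(A) region
  cum <- cumsum(c(0, lens))
  start0 <- win_offset + pos - 1L          # position within first vertex coords
  end0 <- start0 + read_len - 1L
  i1 <- findInterval(start0, cum[-length(cum)])
  i2 <- findInterval(end0, cum[-length(cum)])
  if (i1 < 1L || i2 > length(vs)) return(NULL)
  keep <- seq.int(i1, i2)
  real <- keep[!isM[keep]]
  if (!length(real)) return(NULL)
  polya <- if (any(isM[keep])) as.integer(end0 - (cum[max(real) + 1L] - 1L)) else 0L
  ids <- chain_ids[real]
  if (polya > 0L) ids <- c(ids, g$vM)
  list(chain = paste(ids, collapse = ","),
       b = as.integer(start0 - cum[i1]), polya = polya)
}

#' Read SAM/BAM alignments against graph reference windows
#'
#' Converts records aligned to the reference sequences of
#' [extract_reference_sequences()] (names `gene|v1,v2,...|offset`) into
#' subpath placements and per-gene collapsed datasets.  Non-primary and
#' supplementary records are ignored; unmapped records are counted; mates
#' are paired by name, and a pair with one unmapped mate is treated as
#' single-end.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param graphs Named list of `splice_graph`s the reference was built from.
#' @return Named list of [psg_dataset()]s (one per gene with alignments),
#'   with attribute `n_unmapped`.
#' @export
read_alignments <- function(path, graphs) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  keep <- !unmapped & !secondary
  n_unmapped <- sum(unmapped & !secondary)
  plc <- list()
  if (any(keep)) {
    rn <- as.character(b$rname)[keep]
    parts <- strsplit(rn, "|", fixed = TRUE)
    gene <- vapply(parts, `[`, "", 1L)
    chain <- vapply(parts, `[`, "", 2L)
    woff <- as.integer(vapply(parts, `[`, "", 3L))
    qname <- b$qname[keep]; pos <- b$pos[keep]; qw <- b$qwidth[keep]
    for (i in seq_along(rn)) {
      g <- graphs[[gene[i]]]
      if (is.null(g)) stop("reference name not decodable: ", rn[i])
      hit <- decode_window_hit(g, chain_split(chain[i])[[1L]], woff[i],
                               pos[i], qw[i])
      if (is.null(hit)) next
      plc[[length(plc) + 1L]] <- data.frame(
        gene = gene[i], read = qname[i], chain = hit$chain, b = hit$b,
        polya = hit$polya, stringsAsFactors = FALSE)
    }
  }
  if (!length(plc)) {
    out <- list()
    attr(out, "n_unmapped") <- n_unmapped
    return(out)
  }
  df <- do.call(rbind, plc)
  df <- unique(df)
  out <- lapply(split(df, df$gene), function(d)
    psg_dataset(graphs[[d$gene[1L]]],
                data.frame(read = d$read, chain = d$chain,
                           stringsAsFactors = FALSE)))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

## ---------------------------------------------------------------------------
## Results tables
## ---------------------------------------------------------------------------

#' Write edge-weight estimates (with expected counts) as TSV
#'
#' @param fits Named list of `psg_fit` objects (names = genes).
#' @param path Output TSV (`gene`, `from`, `to`, `weight`, `expected_count`).
#' @param datasets Optional named list of datasets to recompute expected
#'   counts at the fitted weights.
#' @export
write_estimates <- function(fits, path, datasets = NULL) {
  rows <- lapply(sort(names(fits)), function(gene) {
    f <- fits[[gene]]
    g <- f$graph
    cnt <- rep(NA_real_, nrow(g$edges))
    if (!is.null(datasets[[gene]]))
      cnt <- e_step(g, datasets[[gene]])$counts
    data.frame(gene = gene, from = g$edges$from, to = g$edges$to,
               weight = sprintf("%.12g", g$edges$weight),
               expected_count = sprintf("%.6g", cnt), stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write differential-processing results as TSV
#'
#' @param dp Result table of [run_dp_analysis()].
#' @param path Output TSV.
#' @export
write_dp_results <- function(dp, path) {
  write.table(dp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth table from [simulate_fragments()].
#' @param path Output TSV (`fragment_id`, `gene`, `vertex_chain`, `offset`).
#' @export
write_truth <- function(truth, path) {
  write.table(data.frame(fragment_id = truth$fragment_id, gene = truth$gene,
                         vertex_chain = truth$chain, offset = truth$b_chain),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write identifiability reports as TSV
#'
#' @param reports List of [check_identifiability()] results.
#' @param path Output TSV (`gene`, `edge`, `condition`, `certified`).
#' @export
write_identifiability <- function(reports, path) {
  rows <- lapply(reports, function(r)
    cbind(r$table, certified = r$certified))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
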