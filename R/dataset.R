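## ---------------------------------------------------------------------------
## Aligned datasets.  A read's placement on a PSG is a SubpathAlignment:
## (minimal vertex chain s, offset b in the first vertex, mismatches,
## poly(A) overhang).  For inference only the chain and the read-specific
## extra log-weight (error/fragment-length factors) matter, so datasets are
## collapsed: reads sharing an identical placement set form a group, and the
## EM machinery works on distinct chains.  Cost per iteration is linear in
## the number of placements plus the graph size, never per-isoform.
## ---------------------------------------------------------------------------

chain_split <- function(chain) strsplit(chain, ",", fixed = TRUE)

#' Build a collapsed aligned dataset for one gene
#'
#' @param g A valid `splice_graph`.
#' @param placements Data frame with columns `read` (read identifier; all
#'   placements of one read share it), `chain` (comma-joined vertex ids of
#'   the minimal subpath) and optionally `extra` (additional log-weight of
#'   the placement, e.g. sequencing-error and fragment-length terms;
#'   default 0).
#' @param n_unaligned Count of reads that had no placement (excluded from the
#'   likelihood but reported).
#' @return An object of class `psg_dataset`.
#' @export
psg_dataset <- function(g, placements, n_unaligned = 0L) {
  placements <- as.data.frame(placements, stringsAsFactors = FALSE)
  stopifnot(all(c("read", "chain") %in% names(placements)))
  if (is.null(placements$extra)) placements$extra <- rep(0, nrow(placements))
  chains <- unique(placements$chain)
  ci <- match(placements$chain, chains)
  ## resolve chains to vertex/edge indices once
  parts <- chain_split(chains)
  vidx <- lapply(parts, function(p) psg_vi(g, p))
  eidx <- lapply(vidx, function(v) if (length(v) > 1L) psg_edge_ids(g, v) else integer(0))
  first <- vapply(vidx, `[`, 0L, 1L)
  last <- vapply(vidx, function(v) v[length(v)], 0L)

  nplc_per_read <- table(placements$read)
  if (all(nplc_per_read == 1L)) {
    ## unique-placement fast path: group reads by (chain, extra)
    key <- paste(ci, signif(placements$extra, 12))
    ukey <- !duplicated(key)
    grp <- match(key, key[ukey])
    plc <- data.frame(group = seq_len(sum(ukey)),
                      chain = ci[ukey], extra = placements$extra[ukey])
    group_n <- as.numeric(tabulate(grp, nbins = nrow(plc)))
  } else {
    sig <- vapply(split(paste(ci, signif(placements$extra, 12)), placements$read),
                  function(s) paste(sort(s), collapse = ";"), "")
    read_sig <- sig[as.character(placements$read)]
    usig <- unique(read_sig)
    grp <- match(read_sig, usig)
    reads_per_group <- tapply(placements$read, grp, function(r) length(unique(r)))
    group_n <- as.numeric(reads_per_group[as.character(seq_along(usig))])
    ## placements repeated within a read (same chain, e.g. two offsets in one
    ## vertex) keep their multiplicity as a log-weight term
    combo <- paste(grp, ci, signif(placements$extra, 12))
    keep <- !duplicated(combo)
    mult <- as.numeric(table(combo)[combo[keep]]) / group_n[grp[keep]]
    plc <- data.frame(group = grp[keep], chain = ci[keep],
                      extra = placements$extra[keep] + log(mult))
  }

  structure(list(
    gene_id = g$gene_id,
    chains = chains, chain_vidx = vidx, chain_eidx = eidx,
    chain_first = first, chain_last = last,
    flat_chain = rep.int(seq_along(chains), lengths(eidx)),
    flat_edge = unlist(eidx, use.names = FALSE),
    plc = plc, group_n = group_n,
    n_total = sum(group_n), n_unaligned = as.integer(n_unaligned)),
    class = "psg_dataset")
}

#' @export
print.psg_dataset <- function(x, ...) {
  cat(sprintf("psg_dataset '%s': %.0f fragments, %d placement groups, %d distinct chains (%d unaligned)\n",
              x$gene_id, x$n_total, length(x$group_n), length(x$chains), x$n_unaligned))
  invisible(x)
}

## Pool several datasets for the same graph (e.g. the combined fit of the
## likelihood-ratio test).  Groups are kept disjoint across inputs.
pool_datasets <- function(g, ...) {
  dss <- list(...)
  stopifnot(length(dss) >= 1L)
  chains <- unique(unlist(lapply(dss, `[[`, "chains")))
  parts <- chain_split(chains)
  vidx <- lapply(parts, function(p) psg_vi(g, p))
  eidx <- lapply(vidx, function(v) if (length(v) > 1L) psg_edge_ids(g, v) else integer(0))
  plc <- NULL; group_n <- numeric(0)
  goff <- 0L
  for (ds in dss) {
    map <- match(ds$chains, chains)
    p <- ds$plc
    p$chain <- map[p$chain]
    p$group <- p$group + goff
    plc <- rbind(plc, p)
    group_n <- c(group_n, ds$group_n)
    goff <- goff + length(ds$group_n)
  }
  structure(list(
    gene_id = g$gene_id,
    chains = chains, chain_vidx = vidx, chain_eidx = eidx,
    chain_first = vapply(vidx, `[`, 0L, 1L),
    chain_last = vapply(vidx, function(v) v[length(v)], 0L),
    flat_chain = rep.int(seq_along(chains), lengths(eidx)),
    flat_edge = unlist(eidx, use.names = FALSE),
    plc = plc, group_n = group_n,
    n_total = sum(group_n),
    n_unaligned = sum(vapply(dss, `[[`, 0L, "n_unaligned"))),
    class = "psg_dataset")
}

## per-chain probability F(v0, first) * w(chain) under g's current weights
chain_weights <- function(g, ds) {
  w <- g$edges$weight
  lw <- numeric(length(ds$chains))
  if (length(ds$flat_edge)) {
    cs <- rowsum(log(w[ds$flat_edge]), ds$flat_chain)
    lw[as.integer(rownames(cs))] <- cs[, 1L]
  }
  Fv0 <- psg_inclusion_from(g, psg_vi(g, g$v0))
  Fv0[ds$chain_first] * exp(lw)
}
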