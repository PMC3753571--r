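## ---------------------------------------------------------------------------
## Differential processing (DP) between two samples: likelihood-ratio tests
## against chi-square references.  Gene level: all edge weights free vs. tied
## across samples (dof = number of free parameters).  Vertex level: only the
## chosen vertex's out-edge simplex tied, everything else sample-specific
## (dof = out-degree - 1).  ML fits use beta = 1 and the exact M-step.
## ---------------------------------------------------------------------------

#' Set the Dirichlet prior concentration of a PSG
#'
#' Replaces the per-edge `beta` values (recycled).  `beta = 1` makes MAP
#' estimation coincide with maximum likelihood and is used by all
#' likelihood-ratio tests.
#'
#' @param g A `splice_graph`.
#' @param beta Positive concentration value(s).
#' @return The graph with updated prior.
#' @export
psg_set_beta <- function(g, beta) {
  g$edges$beta <- rep(beta, length.out = nrow(g$edges))
  g$cache <- new.env(parent = emptyenv())
  g
}

#' Gene-level likelihood-ratio test for differential processing
#'
#' Fits maximum-likelihood edge weights separately on each sample and on the
#' pooled reads, and forms `2 * [l1(a1) + l2(a2) - (l1(a) + l2(a))]`, referred
#' to a chi-square distribution with as many degrees of freedom as the PSG
#' has free parameters.  Negative statistics from incomplete EM convergence
#' trigger a refit at a tighter tolerance and are then clipped at zero.
#'
#' @param g A valid `splice_graph`.
#' @param dataset1,dataset2 [psg_dataset()]s aligned to `g`.
#' @param tol,max_iter EM settings for the ML fits.
#' @param fit1,fit2 Optional precomputed ML fits of the two samples (reused
#'   across sample pairings; recomputed at tighter tolerance on a retry).
#' @return A list of class `psg_dp_gene`: `gene_id`, `statistic`, `dof`,
#'   `pvalue`, `n1`, `n2`, `testable`, and the three fits.
#' @export
gene_lrt <- function(g, dataset1, dataset2, tol = 1e-8, max_iter = 1000L,
                     fit1 = NULL, fit2 = NULL) {
  gml <- psg_set_beta(g, 1)
  k <- free_parameter_count(g)
  if (k == 0L) {
    return(structure(list(gene_id = g$gene_id, statistic = 0, dof = 0L,
                          pvalue = 1, n1 = dataset1$n_total, n2 = dataset2$n_total,
                          testable = FALSE), class = "psg_dp_gene"))
  }
  pooled <- pool_datasets(g, dataset1, dataset2)
  fit <- function(tl, f1 = NULL, f2 = NULL) {
    if (is.null(f1)) f1 <- run_em(gml, dataset1, tol = tl, max_iter = max_iter)
    if (is.null(f2)) f2 <- run_em(gml, dataset2, tol = tl, max_iter = max_iter)
    f0 <- run_em(gml, pooled, tol = tl, max_iter = max_iter)
    list(f1 = f1, f2 = f2, f0 = f0,
         stat = 2 * (f1$loglik + f2$loglik - f0$loglik))
  }
  r <- fit(tol, fit1, fit2)
  if (r$stat < -1e-6) r <- fit(tol / 100)
  stat <- max(r$stat, 0)
  structure(list(gene_id = g$gene_id, statistic = stat, dof = k,
                 pvalue = stats::pchisq(stat, df = k, lower.tail = FALSE),
                 n1 = dataset1$n_total, n2 = dataset2$n_total, testable = TRUE,
                 fit1 = r$f1, fit2 = r$f2, fit_null = r$f0),
            class = "psg_dp_gene")
}

## EM with one vertex's out-edge simplex tied across two samples and all
## other simplexes sample-specific (the null model of the vertex-level test).
## Returns the maximized total log-likelihood.
run_em_tied <- function(g, dataset1, dataset2, tie_vertex,
                        tol = 1e-8, max_iter = 1000L) {
  vtie <- psg_vi(g, tie_vertex)
  g1 <- set_edge_weights(g, psg_uniform_weights(g))
  g2 <- g1
  dss <- list(dataset1, dataset2)
  Ns <- c(dataset1$n_total, dataset2$n_total)
  total_ll <- function(ga, gb)
    dataset_log_likelihood(ga, dataset1) + dataset_log_likelihood(gb, dataset2)
  obj_prev <- -Inf
  for (it in seq_len(max_iter)) {
    es <- list(e_step(g1, dataset1), e_step(g2, dataset2))
    obj_cur <- es[[1L]]$loglik + es[[2L]]$loglik
    gs <- list(g1, g2)
    wnew <- lapply(gs, function(gg) gg$edges$weight)
    ## per-sample DP quantities at current weights
    els <- lapply(gs, expected_lengths)
    Fv0s <- lapply(gs, function(gg) psg_inclusion_from(gg, psg_vi(gg, gg$v0)))
    for (i in seq_along(g$ids)) {
      e <- g$out[[i]]
      if (length(e) < 2L) next
      tv <- g$eTo[e]
      if (i == vtie) {
        gamma <- es[[1L]]$counts[e] + es[[2L]]$counts[e]
        coefs <- do.call(rbind, lapply(1:2, function(s)
          Fv0s[[s]][i] * (els[[s]]$lambda_pre[i] + els[[s]]$lambda_suf[tv])))
        a0s <- vapply(1:2, function(s)
          els[[s]]$mu - sum(coefs[s, ] * gs[[s]]$edges$weight[e]), 0)
        new <- solve_vertex(gamma, coefs, a0s, Ns, gs[[1L]]$edges$weight[e])
        wnew[[1L]][e] <- new; wnew[[2L]][e] <- new
      } else {
        for (s in 1:2) {
          gamma <- es[[s]]$counts[e]
          coef <- Fv0s[[s]][i] * (els[[s]]$lambda_pre[i] + els[[s]]$lambda_suf[tv])
          a0 <- els[[s]]$mu - sum(coef * gs[[s]]$edges$weight[e])
          wnew[[s]][e] <- solve_vertex(gamma, matrix(coef, nrow = 1L), a0,
                                       Ns[s], gs[[s]]$edges$weight[e])
        }
      }
    }
    g1n <- set_edge_weights(g1, wnew[[1L]])
    g2n <- set_edge_weights(g2, wnew[[2L]])
    obj_new <- total_ll(g1n, g2n)
    tries <- 0L
    while (obj_new < obj_cur - 1e-12 && tries < 40L) {
      wnew[[1L]] <- (wnew[[1L]] + g1$edges$weight) / 2
      wnew[[2L]] <- (wnew[[2L]] + g2$edges$weight) / 2
      g1n <- set_edge_weights(g1, wnew[[1L]])
      g2n <- set_edge_weights(g2, wnew[[2L]])
      obj_new <- total_ll(g1n, g2n)
      tries <- tries + 1L
    }
    g1 <- g1n; g2 <- g2n
    if (is.finite(obj_prev) && abs(obj_new - obj_cur) / (abs(obj_cur) + 1) < tol)
      break
    obj_prev <- obj_new
  }
  list(loglik = total_ll(g1, g2), g1 = g1, g2 = g2)
}

#' Vertex-level likelihood-ratio test for differential processing
#'
#' Tests the null hypothesis that the out-edge weights of vertex `v` are
#' identical between the two samples while all other edge weights may
#' differ: the null is fitted by a tied EM (the vertex's expected counts are
#' pooled across samples in the M-step), the alternative by fully separate
#' fits; degrees of freedom = out-degree(v) - 1.
#'
#' @param g A valid `splice_graph`.
#' @param v Vertex id with out-degree >= 2.
#' @param dataset1,dataset2 [psg_dataset()]s aligned to `g`.
#' @param tol,max_iter EM settings.
#' @return A list of class `psg_dp_vertex` with `statistic`, `dof`, `pvalue`.
#' @export
vertex_lrt <- function(g, v, dataset1, dataset2, tol = 1e-8, max_iter = 1000L) {
  vi <- psg_vi(g, v)
  if (length(g$out[[vi]]) < 2L) stop("vertex '", v, "' has out-degree < 2")
  gml <- psg_set_beta(g, 1)
  f1 <- run_em(gml, dataset1, tol = tol, max_iter = max_iter)
  f2 <- run_em(gml, dataset2, tol = tol, max_iter = max_iter)
  alt <- f1$loglik + f2$loglik
  null <- run_em_tied(gml, dataset1, dataset2, v, tol = tol, max_iter = max_iter)
  stat <- 2 * (alt - null$loglik)
  if (stat < -1e-6) {
    null <- run_em_tied(gml, dataset1, dataset2, v, tol = tol / 100,
                        max_iter = max_iter)
    stat <- 2 * (alt - null$loglik)
  }
  stat <- max(stat, 0)
  dof <- length(g$out[[vi]]) - 1L
  structure(list(gene_id = g$gene_id, vertex = v, statistic = stat, dof = dof,
                 pvalue = stats::pchisq(stat, df = dof, lower.tail = FALSE)),
            class = "psg_dp_vertex")
}

#' Benjamini-Hochberg step-up procedure
#'
#' Monotone q-values and calls at a target false discovery rate.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param target_fdr Target FDR in `(0, 1)`.
#' @return List with `q_values` and logical `calls` (`q <= target_fdr`).
#' @export
benjamini_hochberg <- function(p_values, target_fdr = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  if (target_fdr <= 0 || target_fdr >= 1) stop("target_fdr must be in (0, 1)")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, calls = !is.na(q) & q <= target_fdr)
}

#' Genome-wide differential-processing analysis between two samples
#'
#' Runs the gene-level likelihood-ratio test on every gene with at least one
#' free parameter and `min_fragments` aligned fragments in both samples,
#' applies Benjamini-Hochberg across the tested genes, and returns the table
#' sorted by q-value.  Genes excluded from testing are listed in the
#' `excluded` attribute.
#'
#' @param graphs Named list of valid `splice_graph`s.
#' @param sample1,sample2 Named lists of [psg_dataset()]s (names = gene ids).
#' @param target_fdr Target FDR (default 0.05).
#' @param min_fragments Minimum aligned fragments per sample for a gene to
#'   enter the test universe (default 20).
#' @param tol,max_iter EM settings.
#' @param fits1,fits2 Optional named lists of precomputed per-gene ML fits
#'   for the two samples (an optimization when several sample pairings reuse
#'   the same samples).
#' @return Data frame with columns `gene`, `statistic`, `dof`, `pvalue`,
#'   `qvalue`, `called`, `n1`, `n2`, sorted by `qvalue`.
#' @export
run_dp_analysis <- function(graphs, sample1, sample2, target_fdr = 0.05,
                            min_fragments = 20L, tol = 1e-8, max_iter = 1000L,
                            fits1 = NULL, fits2 = NULL) {
  rows <- list(); excluded <- character(0)
  for (gene in names(graphs)) {
    g <- graphs[[gene]]
    d1 <- sample1[[gene]]; d2 <- sample2[[gene]]
    n1 <- if (is.null(d1)) 0 else d1$n_total
    n2 <- if (is.null(d2)) 0 else d2$n_total
    if (free_parameter_count(g) == 0L || n1 < min_fragments || n2 < min_fragments) {
      excluded <- c(excluded, gene)
      next
    }
    r <- gene_lrt(g, d1, d2, tol = tol, max_iter = max_iter,
                  fit1 = fits1[[gene]], fit2 = fits2[[gene]])
    rows[[gene]] <- data.frame(gene = gene, statistic = r$statistic,
                               dof = r$dof, pvalue = r$pvalue,
                               n1 = n1, n2 = n2, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    res <- data.frame(gene = character(0), statistic = numeric(0),
                      dof = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), called = logical(0),
                      n1 = numeric(0), n2 = numeric(0))
    attr(res, "excluded") <- excluded
    return(res)
  }
  res <- do.call(rbind, rows)
  bh <- benjamini_hochberg(res$pvalue, target_fdr)
  res$qvalue <- bh$q_values
  res$called <- bh$calls
  res <- res[order(res$qvalue, res$pvalue), c("gene", "statistic", "dof",
                                              "pvalue", "qvalue", "called",
                                              "n1", "n2")]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}
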