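## ---------------------------------------------------------------------------
## MAP/ML estimation of PSG edge weights by EM.  The complete-data likelihood
## of a fragment is w(t)/mu(alpha) (transcript-length factors cancel), so the
## E-step reduces to posterior expected edge-usage counts, computed from the
## placement chains with one forward and one backward sweep over the DAG, and
## the M-step maximizes sum c_e log alpha_e - N log mu(alpha) + log prior.
## ---------------------------------------------------------------------------

ALPHA_FLOOR <- 1e-12

#' E-step: posterior expected edge-usage counts
#'
#' For each fragment the posterior over its placements is proportional to
#' `F(v0, first(s)) w(s) P(r | s, b)`.  Expected edge counts decompose into
#' edges inside the placement chain (its posterior mass), upstream edges
#' `(u, x)` receiving `mass * F(v0, u) alpha(u, x) F(x, first) / F(v0, first)`
#' and downstream edges receiving `mass * F(last, u) alpha(u, x)`.  The
#' implementation aggregates posterior mass onto the chain's first/last
#' anchor vertices and resolves all edge expectations with one backward and
#' one forward sweep, so the cost is linear in the number of placements plus
#' the graph size — never per-isoform.
#'
#' @param g A valid `splice_graph` (current weights are the E-step
#'   parameters).
#' @param dataset A [psg_dataset()].
#' @return A list of class `psg_suffstats`: `edge_counts` (named by
#'   `from->to`), `counts` (aligned with `g$edges` rows), `n` total
#'   fragments, `loglik` at the parameters that produced the stats.
#' @export
e_step <- function(g, dataset) {
  nE <- nrow(g$edges)
  nV <- length(g$ids)
  w <- g$edges$weight
  counts <- numeric(nE)
  loglik <- 0
  if (dataset$n_total > 0) {
    cw <- chain_weights(g, dataset)
    pv <- cw[dataset$plc$chain] * exp(dataset$plc$extra)
    denom <- rowsum(pv, dataset$plc$group)
    dv <- numeric(length(dataset$group_n))
    dv[as.integer(rownames(denom))] <- denom[, 1L]
    if (any(dv <= 0))
      stop("fragment group with zero total placement probability")
    mu <- expected_lengths(g)$mu
    loglik <- sum(dataset$group_n * (log(dv) - log(mu)))
    mass <- dataset$group_n[dataset$plc$group] * pv / dv[dataset$plc$group]
    ## per-chain mass
    cm <- numeric(length(dataset$chains))
    agg <- rowsum(mass, dataset$plc$chain)
    cm[as.integer(rownames(agg))] <- agg[, 1L]
    ## edges inside chains
    if (length(dataset$flat_edge)) {
      inner <- rowsum(cm[dataset$flat_chain], dataset$flat_edge)
      counts[as.integer(rownames(inner))] <-
        counts[as.integer(rownames(inner))] + inner[, 1L]
    }
    ## anchor masses
    m_first <- numeric(nV); m_last <- numeric(nV)
    a1 <- rowsum(cm, dataset$chain_first)
    m_first[as.integer(rownames(a1))] <- a1[, 1L]
    a2 <- rowsum(cm, dataset$chain_last)
    m_last[as.integer(rownames(a2))] <- a2[, 1L]
    Fv0 <- psg_inclusion_from(g, psg_vi(g, g$v0))
    ## upstream sweep (backward): h(x) = m_first(x)/F(v0,x) + sum alpha h(next)
    h <- numeric(nV)
    for (v in rev(g$topo)) {
      s <- if (m_first[v] > 0) m_first[v] / Fv0[v] else 0
      for (e in g$out[[v]]) s <- s + w[e] * h[g$eTo[e]]
      h[v] <- s
    }
    ## downstream sweep (forward): d(u) = m_last(u) + sum alpha(w,u) d(w)
    d <- numeric(nV)
    for (v in g$topo) {
      s <- m_last[v]
      for (e in g$inn[[v]]) s <- s + w[e] * d[g$eFrom[e]]
      d[v] <- s
    }
    counts <- counts + Fv0[g$eFrom] * w * h[g$eTo] + d[g$eFrom] * w
  }
  structure(list(
    edge_counts = setNames(counts, paste0(g$edges$from, "->", g$edges$to)),
    counts = counts,
    n = dataset$n_total,
    loglik = loglik),
    class = "psg_suffstats")
}

## per-vertex exact M-step solve: maximize
##   sum_x gamma_x log a_x - sum_s Nmu_s log(a0_s + sum_x coef_sx a_x)
## over the simplex; coef rows are per-sample linear coefficients of mu.
solve_vertex <- function(gamma, coefs, a0s, Ns, alpha0) {
  k <- length(gamma)
  if (all(gamma <= 0)) return(alpha0)
  alpha <- alpha0
  for (it in 1:30) {
    mus_cur <- a0s + as.numeric(coefs %*% alpha)
    bx <- as.numeric(as.numeric(Ns / mus_cur) %*% coefs)  # sum_s N_s coef_sx / mu_s
    fn <- function(lam) sum(gamma / (lam + bx)) - 1
    lo <- max(-bx) + 1e-12
    hi <- sum(gamma) + max(bx) + 1
    lam <- if (fn(lo) < 0) lo else
      stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
    new <- pmax(gamma / (lam + bx), ALPHA_FLOOR)
    new <- new / sum(new)
    if (max(abs(new - alpha)) < 1e-11) { alpha <- new; break }
    alpha <- new
  }
  alpha
}

#' M-step: maximize the expected complete-data log-posterior
#'
#' `variant = "multinomial"` sets each out-edge weight to
#' `(c + beta - 1) / sum(c + beta - 1)` over the vertex — exact whenever all
#' complete paths have equal length and the conventional approximation
#' otherwise.  `variant = "exact"` additionally accounts for the
#' `- N log mu(alpha)` term: because `mu` is linear in any single vertex's
#' out-edge simplex, each vertex is solved by a monotone fixed point on its
#' KKT conditions, cycled over vertices.  Monotonicity of the overall EM
#' objective is enforced by the caller's step-halving guard (generalized EM).
#'
#' @param g A valid `splice_graph` (weights = current iterate).
#' @param stats A `psg_suffstats` from [e_step()].
#' @param variant `"exact"` (default) or `"multinomial"`.
#' @return New edge-weight vector aligned with `g$edges` rows.
#' @export
m_step <- function(g, stats, variant = c("exact", "multinomial")) {
  variant <- match.arg(variant)
  counts <- stats$counts
  beta <- g$edges$beta
  num <- counts + beta - 1
  if (any(num < 0))
    stop("negative numerator in M-step (beta < 1 with small counts): degenerate prior")
  w <- g$edges$weight
  if (variant == "multinomial") {
    for (i in seq_along(g$ids)) {
      e <- g$out[[i]]
      if (length(e) < 2L) { if (length(e)) w[e] <- 1; next }
      tot <- sum(num[e])
      if (tot <= 0)
        stop("all M-step numerators zero for vertex '", g$ids[i], "'")
      w[e] <- pmax(num[e] / tot, ALPHA_FLOOR)
      w[e] <- w[e] / sum(w[e])
    }
    return(w)
  }
  ## exact variant: one cyclic pass over branch vertices per M-step (the EM
  ## outer loop supplies further passes; generalized EM only needs ascent)
  N <- stats$n
  gw <- g
  for (cycle in 1L) {
    el <- expected_lengths(gw)
    Fv0 <- psg_inclusion_from(gw, psg_vi(gw, gw$v0))
    mu <- el$mu
    for (i in seq_along(g$ids)) {
      e <- gw$out[[i]]
      if (length(e) < 2L) next
      if (sum(num[e]) <= 0)
        stop("all M-step numerators zero for vertex '", g$ids[i], "'")
      tv <- gw$eTo[e]
      coef <- Fv0[i] * (el$lambda_pre[i] + el$lambda_suf[tv])
      a0 <- mu - sum(coef * gw$edges$weight[e])
      new <- solve_vertex(num[e], matrix(coef, nrow = 1L), a0, N,
                          gw$edges$weight[e])
      gw$edges$weight[e] <- new
      gw$cache <- new.env(parent = emptyenv())
      el <- expected_lengths(gw)
      Fv0 <- psg_inclusion_from(gw, psg_vi(gw, gw$v0))
      mu <- el$mu
    }
  }
  gw$edges$weight
}

psg_uniform_weights <- function(g) {
  w <- numeric(nrow(g$edges))
  for (i in seq_along(g$ids)) {
    e <- g$out[[i]]
    if (length(e)) w[e] <- 1 / length(e)
  }
  w
}

log_prior <- function(g) sum((g$edges$beta - 1) * log(pmax(g$edges$weight, 1e-300)))

#' Fit PSG edge weights by EM
#'
#' Alternates [e_step()] and [m_step()] from a uniform initialization until
#' the relative change in the log-posterior falls below `tol` or `max_iter`
#' iterations.  A step-halving guard (generalized EM) keeps the trace
#' non-decreasing for both M-step variants.  With all `beta = 1` the result
#' is a maximum-likelihood stationary point.
#'
#' @param g A valid `splice_graph` (its `beta` values define the prior).
#' @param dataset A [psg_dataset()].
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative log-posterior change.
#' @param variant M-step variant; see [m_step()].
#' @return A list of class `psg_fit`: `alpha` fitted edge weights (named),
#'   `graph` the refitted graph, `trace` per-iteration log-posterior,
#'   `iterations`, `converged`, `loglik` (data term only),
#'   `vertex_freqs` per-branch-vertex out-edge simplexes, and `n`.
#' @export
run_em <- function(g, dataset, max_iter = 1000L, tol = 1e-8,
                   variant = c("exact", "multinomial")) {
  variant <- match.arg(variant)
  g <- set_edge_weights(g, psg_uniform_weights(g))
  if (dataset$n_total == 0) {
    ## MAP of the Dirichlet prior alone: its mode for beta >= 1
    w <- numeric(nrow(g$edges))
    for (i in seq_along(g$ids)) {
      e <- g$out[[i]]
      if (!length(e)) next
      b <- g$edges$beta[e]
      w[e] <- if (all(b >= 1) && sum(b - 1) > 0) (b - 1) / sum(b - 1) else 1 / length(e)
    }
    g <- set_edge_weights(g, w)
    return(structure(list(alpha = setNames(w, paste0(g$edges$from, "->", g$edges$to)),
                          graph = g, trace = log_prior(g), iterations = 0L,
                          converged = TRUE, loglik = 0,
                          vertex_freqs = psg_branch_weights(g), n = 0),
                     class = "psg_fit"))
  }
  trace <- numeric(0)
  obj <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- e_step(g, dataset)
    obj_cur <- es$loglik + log_prior(g)
    trace <- c(trace, obj_cur)
    wnew <- m_step(g, es, variant = variant)
    gnew <- set_edge_weights(g, wnew)
    obj_new <- dataset_log_likelihood(gnew, dataset, include_prior = TRUE)
    tries <- 0L
    while (obj_new < obj_cur - 1e-12 && tries < 40L) {
      wnew <- (wnew + g$edges$weight) / 2
      gnew <- set_edge_weights(g, wnew)
      obj_new <- dataset_log_likelihood(gnew, dataset, include_prior = TRUE)
      tries <- tries + 1L
    }
    g <- gnew
    if (is.finite(obj) && abs(obj_new - obj_cur) / (abs(obj_cur) + 1) < tol) {
      converged <- TRUE
      trace <- c(trace, obj_new)
      break
    }
    obj <- obj_new
  }
  structure(list(
    alpha = setNames(g$edges$weight, paste0(g$edges$from, "->", g$edges$to)),
    graph = g,
    trace = trace,
    iterations = it,
    converged = converged,
    loglik = dataset_log_likelihood(g, dataset, include_prior = FALSE),
    vertex_freqs = psg_branch_weights(g),
    n = dataset$n_total), class = "psg_fit")
}

#' @export
print.psg_fit <- function(x, ...) {
  cat(sprintf("psg_fit: %d iterations (%s), log-likelihood %.4f on %.0f fragments\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$loglik, x$n))
  invisible(x)
}

#' Annotated-isoform frequencies implied by a fit
#'
#' Product of fitted edge weights along each complete path (enumeration
#' bounded).
#' @param fit A `psg_fit`.
#' @param max_count Enumeration refusal bound.
#' @export
isoform_frequencies <- function(fit, max_count = 10000L) {
  enumerate_isoforms(fit$graph, max_count = max_count)
}

## ---------------------------------------------------------------------------
## Junction-read baseline
## ---------------------------------------------------------------------------

#' Junction-read (JR) estimator of PSG edge weights
#'
#' Considers only reads whose best placements span splice-graph edges: each
#' such placement increments every edge its minimal subpath contains
#' (multi-placement junction reads are split equally across their junction
#' placements); out-edge weights are then
#' `(count + pseudocount) / sum(count + pseudocount)` per vertex.  Start
#' (`v0`) out-edges — alternative transcription starts — involve no junction
#' and are left at the prior mean and flagged.  Consistent but less
#' statistically efficient than EM.
#'
#' @param g A valid `splice_graph`.
#' @param dataset A [psg_dataset()].
#' @param pseudocount Non-negative pseudocount (default 1).
#' @return A `psg_fit`-like list with `alpha`, `vertex_freqs`,
#'   `junction_counts` and `no_junction_vertices` (flagged vertices whose
#'   out-simplex kept the prior mean).
#' @export
junction_read_estimator <- function(g, dataset, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  counts <- numeric(nrow(g$edges))
  if (dataset$n_total > 0) {
    spans <- lengths(dataset$chain_eidx) > 0L
    ## best placements per group: maximal extra log-weight
    p <- dataset$plc
    best <- tapply(p$extra, p$group, max)
    is_best <- p$extra >= best[as.character(p$group)] - 1e-12
    keep <- is_best & spans[p$chain]
    if (any(keep)) {
      pj <- p[keep, , drop = FALSE]
      share <- 1 / as.numeric(table(pj$group))[match(pj$group, sort(unique(pj$group)))]
      wt <- dataset$group_n[pj$group] * share
      fe <- unlist(dataset$chain_eidx[pj$chain], use.names = FALSE)
      fw <- rep.int(wt, lengths(dataset$chain_eidx[pj$chain]))
      agg <- rowsum(fw, fe)
      counts[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  w <- numeric(nrow(g$edges))
  v0 <- psg_vi(g, g$v0)
  flagged <- character(0)
  for (i in seq_along(g$ids)) {
    e <- g$out[[i]]
    if (!length(e)) next
    if (length(e) == 1L) { w[e] <- 1; next }
    if (i == v0) {
      b <- g$edges$beta[e]
      w[e] <- b / sum(b)
      flagged <- c(flagged, g$ids[i])
    } else {
      w[e] <- (counts[e] + pseudocount) / sum(counts[e] + pseudocount)
    }
  }
  g2 <- set_edge_weights(g, w)
  structure(list(
    alpha = setNames(w, paste0(g$edges$from, "->", g$edges$to)),
    graph = g2,
    junction_counts = setNames(counts, paste0(g$edges$from, "->", g$edges$to)),
    no_junction_vertices = flagged,
    vertex_freqs = psg_branch_weights(g2),
    n = dataset$n_total), class = "psg_fit")
}

## ---------------------------------------------------------------------------
## Estimate comparison and bootstrap convergence
## ---------------------------------------------------------------------------

fit_alpha <- function(x) if (inherits(x, "psg_fit")) unname(x$alpha) else as.numeric(x)

#' Per-vertex infinity-norm distance between two estimates
#'
#' For each branch vertex (out-degree >= 2), the maximum absolute difference
#' between the two estimates' out-edge weights.
#'
#' @param g A `splice_graph` giving the shared topology.
#' @param alpha1,alpha2 Edge-weight vectors aligned with `g$edges`, or
#'   `psg_fit` objects.
#' @return Named numeric vector (one entry per branch vertex).
#' @export
vertex_distance <- function(g, alpha1, alpha2) {
  a1 <- fit_alpha(alpha1); a2 <- fit_alpha(alpha2)
  stopifnot(length(a1) == nrow(g$edges), length(a2) == nrow(g$edges))
  br <- which(lengths(g$out) >= 2L)
  setNames(vapply(br, function(i) max(abs(a1[g$out[[i]]] - a2[g$out[[i]]])), 0),
           g$ids[br])
}

resample_dataset <- function(ds, size) {
  k <- stats::rmultinom(1L, size, ds$group_n)[, 1L]
  ds$group_n <- as.numeric(k)
  ds$n_total <- sum(k)
  ds
}

#' Bootstrap convergence of an estimator
#'
#' Resamples reads with replacement at each size, re-estimates, and records
#' the mean (over replicates and branch vertices) infinity-norm distance to
#' the full-data estimate.
#'
#' @param g A valid `splice_graph`.
#' @param dataset A [psg_dataset()].
#' @param sizes Bootstrap sample sizes.
#' @param replicates Replicates per size.
#' @param estimator `"em"` or `"jr"`.
#' @param seed Seed.
#' @param ... Passed to [run_em()] / [junction_read_estimator()].
#' @return Data frame with columns `size` and `mean_distance`.
#' @export
bootstrap_convergence <- function(g, dataset, sizes, replicates = 100L,
                                  estimator = c("em", "jr"), seed = 1L, ...) {
  estimator <- match.arg(estimator)
  est <- function(ds) switch(estimator,
    em = run_em(g, ds, ...),
    jr = junction_read_estimator(g, ds, ...))
  full <- est(dataset)
  withr::with_seed(seed, {
    md <- vapply(sizes, function(sz) {
      mean(vapply(seq_len(replicates), function(r) {
        ds <- resample_dataset(dataset, sz)
        mean(vertex_distance(g, est(ds), full))
      }, 0))
    }, 0)
  })
  data.frame(size = sizes, mean_distance = md)
}
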