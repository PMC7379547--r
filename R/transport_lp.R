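# Transportation linear program
#
#   minimize    sum_{b,g} cost[b,g] * x[b,g]
#   subject to  sum_g x[b,g] = supply[b]   (every breed's demand is shipped)
#               sum_b x[b,g] <= cap[g]     (bank capacity)
#               x >= 0
#
# Solved exactly by successive shortest augmenting paths on the bipartite
# residual network with Johnson node potentials: reduced arc costs stay
# nonnegative, so each augmenting path is found by Dijkstra (multi-source
# over all unsatisfied breeds, stopping at the nearest bank with residual
# capacity) and the predecessor tree is always consistent. Costs must be
# nonnegative; Inf marks disallowed pairs. A warm start resumes from a
# partial flow: feasible potentials for it are recovered by a Bellman-Ford
# fixpoint on the bank graph contracted over the flow-carrying arcs (valid
# whenever the start flow is optimal for its own value, e.g. a parent node's
# optimum with one arc emptied). Cross-checked against a dense-simplex LP
# oracle in the test suite.
transport_lp <- function(cost, supply, cap, eps = 1e-7, init = NULL) {
  nb <- nrow(cost); ng <- ncol(cost)
  stopifnot(length(supply) == nb, length(cap) == ng)
  x <- if (is.null(init)) matrix(0, nb, ng) else init
  rs <- as.numeric(supply) - rowSums(x)
  rc <- as.numeric(cap) - colSums(x)
  if (any(rs < -eps) || any(rc < -eps))
    stop("transport_lp: infeasible warm start", call. = FALSE)

  # feasible potentials for the starting flow: bank potentials from the
  # Bellman-Ford fixpoint of the contracted residual graph (a virtual source
  # at 0 to every bank), breed potentials tight on their used arcs
  pig <- numeric(ng)
  if (!is.null(init) && any(x > eps)) {
    for (round in seq_len(ng + 1L)) {
      improved <- FALSE
      for (g in seq_len(ng)) {
        idx <- which(x[, g] > eps)
        if (length(idx) == 0L) next
        w <- apply(cost[idx, , drop = FALSE] - cost[idx, g], 2, min)
        nd <- pig[g] + w
        upd <- which(nd < pig - 1e-12)
        if (length(upd) > 0L) { pig[upd] <- nd[upd]; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  pib <- numeric(nb)
  for (b in seq_len(nb)) {
    used <- which(x[b, ] > eps)
    fin <- which(is.finite(cost[b, ]))
    pib[b] <- if (length(used) > 0L) min(pig[used] - cost[b, used])
              else if (length(fin) > 0L) max(pig[fin] - cost[b, fin])
              else 0
  }

  n <- nb + ng
  max_aug <- 100L * n + 1000L
  aug <- 0L
  while (TRUE) {
    src <- which(rs > eps)
    if (length(src) == 0L) break
    aug <- aug + 1L
    if (aug > max_aug)
      stop("transport_lp: iteration limit exceeded", call. = FALSE)

    dist <- rep(Inf, n)
    prev <- integer(n)
    done <- rep(FALSE, n)
    dist[src] <- 0
    done[src] <- TRUE   # batch-relax all sources up front (all at distance 0)
    rf <- cost[src, , drop = FALSE] + pib[src] -
      matrix(pig, length(src), ng, byrow = TRUE)
    rf[rf < 0] <- 0
    rf[is.na(rf)] <- Inf
    w0 <- apply(rf, 2, min)
    a0 <- src[apply(rf, 2, which.min)]
    fin <- which(is.finite(w0))
    dist[nb + fin] <- w0[fin]
    prev[nb + fin] <- a0[fin]
    sink <- 0L
    repeat {
      cand <- dist
      cand[done] <- Inf
      u <- which.min(cand)
      if (!is.finite(cand[u])) break
      if (u > nb && rc[u - nb] > eps) { sink <- u; break }
      done[u] <- TRUE
      if (u <= nb) {
        w <- dist[u] + pmax(0, cost[u, ] + pib[u] - pig)
        tgt <- nb + seq_len(ng)
        upd <- which(!done[tgt] & w < dist[tgt] - 1e-12)
        if (length(upd) > 0L) { dist[tgt[upd]] <- w[upd]; prev[tgt[upd]] <- u }
      } else {
        g <- u - nb
        idx <- which(x[, g] > eps)
        if (length(idx) > 0L) {
          w <- dist[u] + pmax(0, pig[g] - cost[idx, g] - pib[idx])
          upd <- which(!done[idx] & w < dist[idx] - 1e-12)
          if (length(upd) > 0L) { dist[idx[upd]] <- w[upd]; prev[idx[upd]] <- u }
        }
      }
    }
    if (sink == 0L)
      return(list(flow = x, objective = NA_real_, status = "infeasible"))

    dt <- dist[sink]
    pib <- pib + pmin(dist[seq_len(nb)], dt)
    pig <- pig + pmin(dist[nb + seq_len(ng)], dt)

    path <- integer(0)
    v <- sink
    while (v != 0L) { path <- c(v, path); v <- prev[v] }
    amt <- min(rs[path[1]], rc[sink - nb])
    if (length(path) > 2L) {
      for (i in seq(2L, length(path) - 1L))
        if (path[i] > nb)                       # backward arc g -> b follows
          amt <- min(amt, x[path[i + 1L], path[i] - nb])
    }
    for (i in seq_len(length(path) - 1L)) {
      u <- path[i]; v <- path[i + 1L]
      if (u <= nb) x[u, v - nb] <- x[u, v - nb] + amt
      else x[v, u - nb] <- x[v, u - nb] - amt
    }
    rs[path[1]] <- rs[path[1]] - amt
    rc[sink - nb] <- rc[sink - nb] - amt
  }

  pos <- which(x > eps & is.finite(cost))
  list(flow = x, objective = sum(cost[pos] * x[pos]), status = "optimal")
}
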