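# Independent brute-force oracles used to verify the package's
# implementations. These are deliberately naive and share no code with the
# package internals.

# textbook PLS2 by NIPALS: deflation of X and Y, no orthogonal filtering
oracle_pls2 <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  ssy <- sum(y^2)
  x0 <- x
  y0 <- y
  for (a in seq_len(ncomp)) {
    u <- y0[, which.max(apply(y0, 2, stats::var))]
    for (i in 1:500) {
      w <- crossprod(x0, u)
      w <- w / sqrt(sum(w^2))
      tt <- x0 %*% w
      q <- crossprod(y0, tt) / c(crossprod(tt))
      u_new <- y0 %*% q / c(crossprod(q))
      if (sqrt(sum((u_new - u)^2)) < 1e-12) break
      u <- u_new
    }
    tt <- x0 %*% w
    p <- crossprod(x0, tt) / c(crossprod(tt))
    q <- crossprod(y0, tt) / c(crossprod(tt))
    x0 <- x0 - tt %*% t(p)
    y0 <- y0 - tt %*% t(q)
  }
  1 - sum(y0^2) / ssy
}

# all-pairs BFS shortest-path betweenness/closeness by explicit path counting
oracle_centralities <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(n) {
    unique(c(edges$to[edges$from == n], edges$from[edges$to == n]))
  })
  bfs <- function(src) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    nsp <- setNames(rep(0, length(nodes)), nodes)
    preds <- setNames(vector("list", length(nodes)), nodes)
    dist[src] <- 0
    nsp[src] <- 1
    queue <- src
    order <- character()
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      order <- c(order, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          nsp[w] <- nsp[w] + nsp[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    list(dist = dist, nsp = nsp, preds = preds, order = order)
  }
  btw <- setNames(rep(0, length(nodes)), nodes)
  cls <- setNames(rep(NA_real_, length(nodes)), nodes)
  comp_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  comp_id <- 0
  for (n in nodes) {
    if (is.na(comp_of[n])) {
      comp_id <- comp_id + 1
      reach <- names(which(is.finite(bfs(n)$dist)))
      comp_of[reach] <- comp_id
    }
  }
  for (src in nodes) {
    b <- bfs(src)
    # dependency accumulation (still an independent path enumeration:
    # delta built by walking the BFS order backwards over predecessors)
    delta <- setNames(rep(0, length(nodes)), nodes)
    for (w in rev(b$order)) {
      for (v in b$preds[[w]]) {
        delta[v] <- delta[v] + (b$nsp[v] / b$nsp[w]) * (1 + delta[w])
      }
      if (w != src) btw[w] <- btw[w] + delta[w]
    }
    reach <- b$dist[is.finite(b$dist)]
    reach <- reach[names(reach) != src]
    if (length(reach) > 0) cls[src] <- length(reach) / sum(reach)
  }
  btw <- btw / 2 # undirected: each pair counted from both endpoints
  norm_btw <- vapply(nodes, function(n) {
    nn <- sum(comp_of == comp_of[n])
    if (nn > 2) btw[n] * 2 / ((nn - 1) * (nn - 2)) else 0
  }, numeric(1))
  data.frame(node = nodes, betweenness = unname(norm_btw),
             closeness = unname(cls[nodes]))
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  mu <- nx * length(y) / 2
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up by the hand rule
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (i in rev(seq_len(n))) {
    running_min <- min(running_min, p[ord[i]] * n / i)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# random undirected graph: edge list plus full node set
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("G%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  list(
    edges = data.frame(from = pairs[1, keep], to = pairs[2, keep],
                       score = 1, stringsAsFactors = FALSE),
    nodes = nodes
  )
}
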