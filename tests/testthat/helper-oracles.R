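# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most literal definition of
# each quantity, not the package's code paths.

# upper-tail hypergeometric by direct combinatorial summation
oracle_hyper_upper <- function(x, N, K, M) {
  if (x == 0) return(1)
  j <- x:min(K, M)
  sum(choose(K, j) * choose(N - K, M - j)) / choose(N, M)
}

# naive O(n^2) step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (k in seq_len(n)) {
    adj[k] <- min(1, min(ps[k:n] * n / (k:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# literal running-sum walk: +|metric|^w / sum at hits, -1/(N-m) at misses
oracle_walk <- function(metric, hit, weight = 0) {
  n <- length(metric)
  m <- sum(hit)
  w <- abs(metric)^weight
  sw <- sum(w[hit])
  walk <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {
    run <- if (hit[i]) run + (if (sw > 0) w[i] / sw else 1 / m)
    else run - 1 / (n - m)
    walk[i] <- run
  }
  # same tie rule as the package: positive extremum wins magnitude ties
  es <- if (max(walk) + min(walk) >= -1e-12) max(walk) else min(walk)
  list(walk = walk, es = es)
}

# Mann-Whitney AUC by explicit all-pairs counting
oracle_auc_pairs <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# all six topology metrics from an adjacency matrix, via Floyd-Warshall
# distances and per-source BFS shortest-path counts
oracle_topology <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)

  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }

  # sigma[s, t]: number of shortest s-t paths (BFS layer DP per source)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    finite <- which(is.finite(D[s, ]))
    for (dist in sort(unique(D[s, finite]))) {
      if (dist == 0) next
      for (v in finite[D[s, finite] == dist]) {
        preds <- which(A[, v] == 1 & D[s, ] == dist - 1)
        sig[v] <- sum(sig[preds])
      }
    }
    sigma[s, ] <- sig
  }

  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    btw[v] <- tot
  }

  clo <- aspl <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    clo[v] <- if (length(d)) length(d) / sum(d) else 0
    aspl[v] <- if (length(d)) mean(d) else 0
  }

  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    cc[v] <- if (k < 2) 0 else sum(A[nb, nb]) / (k * (k - 1))
  }

  tc <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    js <- c()
    for (u in seq_len(n)) {
      if (u == v) next
      shared <- sum(A[v, ] == 1 & A[u, ] == 1)
      if (shared >= 1) js <- c(js, shared + A[v, u])
    }
    tc[v] <- if (length(js)) mean(js) / deg[v] else 0
  }

  list(degree = deg, betweenness = btw, closeness = clo, clustering = cc,
       avg_shortest_path = aspl, topological_coefficient = tc)
}
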