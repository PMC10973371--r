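# Independent brute-force oracles, written from the definitions only; they
# never call the package code paths they check.

# product-limit survival: returns S() evaluated after each unique event time
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# two-group log-rank chi-square from the at-risk table
oracle_logrank_chi2 <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n1 <- sum(times >= t & grp == 1)
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# step-up BH from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact upper-tail hypergeometric by term-wise enumeration (N small)
oracle_hyper_upper <- function(k, n_a, n_b, N) {
  if (k == 0) return(1)
  j <- k:min(n_a, n_b)
  sum(choose(n_a, j) * choose(N - n_a, n_b - j)) / choose(N, n_b)
}

# exact betweenness by exhaustive simple-path enumeration on an adjacency
# matrix (pair counted once, fractional credit over shortest paths)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    # enumerate all simple paths s -> t by DFS
    res <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { res[[length(res) + 1]] <<- path; return(invisible()) }
      for (nb in which(adj[last, ] == 1)) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(s)
    res
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, 1L)
    shortest <- ps[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / sigma
    }
  }
  btw
}

# BFS distances from an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in 1:n) {
    frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# radiality from the definition, per connected component
oracle_radiality <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  rad <- numeric(n)
  comp_of <- rep(NA_integer_, n); ci <- 0
  for (s in 1:n) {
    if (is.na(comp_of[s])) { ci <- ci + 1; comp_of[is.finite(d[s, ])] <- ci }
  }
  for (c_id in unique(comp_of)) {
    mem <- which(comp_of == c_id)
    m <- length(mem)
    if (m < 2) next
    dd <- d[mem, mem, drop = FALSE]
    diam <- max(dd)
    for (i in seq_along(mem)) {
      rad[mem[i]] <- sum(diam + 1 - dd[i, -i]) / (m - 1)
    }
  }
  rad
}

# triple-loop TOM from the definition
oracle_tom <- function(adj) {
  diag(adj) <- 0
  n <- nrow(adj)
  k <- rowSums(adj)
  tom <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

# plain rank AUC of cases vs controls by pair counting
oracle_pair_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (a in case_scores) for (b in control_scores) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(case_scores) * length(control_scores))
}

# weighted KS running-sum ES from the definition (explicit loop)
oracle_es <- function(metric_sorted, in_set, weight_p) {
  n <- length(metric_sorted)
  nh <- sum(in_set)
  wsum <- sum(abs(metric_sorted[in_set])^weight_p)
  rs <- 0; best <- 0
  for (i in 1:n) {
    if (in_set[i]) rs <- rs + abs(unname(metric_sorted[i]))^weight_p / wsum
    else rs <- rs - 1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# igraph-free random adjacency matrix (symmetric, no self loops)
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

adjacency_to_edge_list <- function(adj, genes = sprintf("g%02d", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edge_list(data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                       confidence = 900, stringsAsFactors = FALSE))
}
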