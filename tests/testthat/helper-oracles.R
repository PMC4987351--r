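# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths.

# all-pairs shortest path lengths by repeated BFS on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] == 1)) {
          if (is.infinite(d[s, u])) {
            d[s, u] <- depth
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# number of shortest paths between all pairs, by induction on distance
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (dist in seq_len(max(d[s, is.finite(d[s, ])]))) {
      for (v in which(d[s, ] == dist)) {
        pred <- which(adj[v, ] == 1 & d[s, ] == dist - 1)
        sigma[s, v] <- sum(sigma[s, pred])
      }
    }
  }
  sigma
}

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  deg <- rowSums(adj)
  eg <- vapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    mean(inv)
  }, numeric(1))
  btw <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (j == i || k == i || is.infinite(d[j, k])) next
        through <- if (d[j, i] + d[i, k] == d[j, k]) {
          sigma[j, i] * sigma[i, k]
        } else {
          0
        }
        acc <- acc + through / sigma[j, k]
      }
    }
    btw[i] <- acc
  }
  el <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- oracle_distances(sub)
    inv <- 1 / ds
    diag(inv) <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    tri <- sum(adj[nb, nb]) / 2
    2 * tri / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(D = deg, Eg = eg, B = btw, El = el, C = cc)
}

# maximum total |r| over all spanning trees, by exhaustive enumeration
oracle_best_tree_weight <- function(absmat) {
  n <- nrow(absmat)
  pairs <- which(upper.tri(absmat), arr.ind = TRUE)
  best <- -Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    adj <- matrix(0, n, n)
    adj[pairs[sel, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    d <- oracle_distances(adj)
    if (any(is.infinite(d))) next
    w <- sum(absmat[pairs[sel, , drop = FALSE]])
    best <- max(best, w)
  }
  best
}

# random connected graph: random spanning tree plus Bernoulli extras
random_connected_adj <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    adj[u, v] <- adj[v, u] <- 1L
  }
  extra <- which(upper.tri(adj) & adj == 0L)
  on <- extra[runif(length(extra)) < p]
  adj[on] <- 1L
  adj <- pmax(adj, t(adj))
  storage.mode(adj) <- "integer"
  adj
}

# least-squares residuals by explicit normal equations
oracle_residual <- function(y, design) {
  beta <- solve(t(design) %*% design) %*% t(design) %*% y
  as.numeric(y - design %*% beta)
}

# one-way ANOVA mean squares via aov()
oracle_icc <- function(values) {
  df <- data.frame(
    value = as.numeric(values),
    subject = factor(rep(seq_len(nrow(values)), ncol(values)))
  )
  tab <- summary(stats::aov(value ~ subject, data = df))[[1]]
  msb <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(values)
  (msb - msw) / (msb + (k - 1) * msw)
}
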