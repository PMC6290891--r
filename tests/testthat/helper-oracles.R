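# Independent reference implementations used as oracles. These are kept
# deliberately naive (enumeration / brute force) and separate from the
# package's algorithms.

# Flood-fill connected-component labeling on a 3D mask.
ref_flood_fill <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1), ,
               drop = FALSE]
  lab <- array(0L, dims)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v]) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      c0 <- arrayInd(u, dims)
      for (k in seq_len(nrow(offs))) {
        cc <- c0 + offs[k, ]
        if (any(cc < 1) || any(cc > dims)) next
        w <- (cc[3] - 1) * dims[1] * dims[2] + (cc[2] - 1) * dims[1] + cc[1]
        if (mask[w] && !lab[w]) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Betweenness by explicit enumeration of every shortest path between
# every unordered node pair (feasible for N <= 12): each pair adds, for
# each intermediate node, the fraction of that pair's shortest paths
# passing through it.
ref_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    d <- bfs_dist(adj, s)
    if (is.infinite(d[t])) next
    paths <- list()
    expand <- function(path) {
      u <- path[1]
      if (u == s) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (v in which(adj[u, ] > 0)) if (d[v] == d[u] - 1) expand(c(v, path))
    }
    expand(t)
    np <- length(paths)
    inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
    if (length(inner)) {
      tab <- table(inner)
      ix <- as.integer(names(tab))
      bc[ix] <- bc[ix] + as.numeric(tab) / np
    }
  }
  bc
}

bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in which(adj[u, ] > 0))
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        nxt <- c(nxt, v)
      }
    frontier <- unique(nxt)
  }
  dist
}

# Random connected-ish symmetric binary adjacency matrix.
random_binary_graph <- function(n, p = 0.35) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Random symmetric weight matrix with zero diagonal, distinct weights.
random_weight_matrix <- function(n, positive = TRUE) {
  w <- matrix(0, n, n)
  vals <- runif(n * (n - 1) / 2, if (positive) 0.01 else -1, 1)
  w[upper.tri(w)] <- vals
  w + t(w)
}

# Reference proportional thresholding: explicit sort-and-take-top-E.
ref_threshold <- function(w, delta, binary) {
  n <- nrow(w)
  e <- round(delta * n * (n - 1) / 2)
  ut <- which(upper.tri(w))
  keep <- ut[order(-w[ut], ut)][seq_len(e)]
  out <- matrix(0, n, n)
  out[keep] <- if (binary) 1 else w[keep]
  out + t(out)
}

# Default two-group design of size n per group.
make_design <- function(n) group_design(rep(c("A", "B"), each = n))

# FFT amplitude at a target frequency.
fft_amp <- function(x, freq_hz, tr) {
  n <- length(x)
  bin <- round(freq_hz * n * tr) + 1L
  abs(fft(x))[bin] * 2 / n
}
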