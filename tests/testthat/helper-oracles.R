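# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (literal summations, BFS) rather than
# calling the package's own code paths.

# Literal evaluation of the normalised absolute cross-correlation at lag 0:
# gamma = |sum x_t y_t| / sqrt(sum x^2 * sum y^2), via explicit loops.
oracle_gamma <- function(x, y) {
  num <- 0
  for (t in seq_along(x)) num <- num + x[t] * y[t]
  ex <- 0
  ey <- 0
  for (t in seq_along(x)) {
    ex <- ex + x[t]^2
    ey <- ey + y[t]^2
  }
  abs(num) / sqrt(ex * ey)
}

# Full connectivity matrix by the double loop over channel pairs.
oracle_connectivity <- function(window) {
  nc <- nrow(window)
  m <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i != j) m[i, j] <- oracle_gamma(window[i, ], window[j, ])
    }
  }
  m
}

# Plain breadth-first search connectivity on a 0/1 adjacency matrix.
oracle_bfs_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# All-pairs shortest path lengths by repeated BFS (Inf when unreachable).
oracle_bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (u in which(adj[v, ] > 0)) {
        if (is.infinite(d[s, u])) {
          d[s, u] <- d[s, v] + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  d
}

# Characteristic path length and global efficiency from the BFS distances,
# over unordered distinct pairs.
oracle_path_metrics <- function(adj) {
  d <- oracle_bfs_distances(adj)
  up <- d[upper.tri(d)]
  list(cpl = mean(up), eff = mean(1 / up))
}

# Random symmetric weight matrix with zero diagonal, weights in (0, 1).
random_connectivity <- function(n, min_w = 0.05, max_w = 0.95) {
  m <- matrix(0, n, n)
  w <- stats::runif(n * (n - 1) / 2, min_w, max_w)
  m[upper.tri(m)] <- w
  m + t(m)
}

# Random connected binary graph: Erdos-Renyi draws until connected.
random_connected_adjacency <- function(n, p) {
  repeat {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
    a <- a + t(a)
    if (oracle_bfs_connected(a)) return(a)
  }
}

# Small deterministic synthetic recording for mid-weight tests.
small_synth <- function(seed = 42L, duration_s = 120, events = c(40, 80)) {
  generate_recording(synth_spec(duration_s = duration_s,
                                event_times_s = events, seed = seed))
}
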