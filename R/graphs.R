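# Connectedness-based binarisation and the four classical comparison
# metrics. Binarisation: starting from T = 1 the threshold is lowered on a
# grid of step `step` until the binary graph (edge iff weight > T, strictly)
# is connected, as judged by the second-smallest eigenvalue of the graph
# Laplacian L = D - A (the algebraic connectivity / Fiedler value). If no
# grid point down to 0 connects the graph, the step is refined by factors of
# 10 down to `min_step`.

LAMBDA2_TOL <- 1e-9

#' Algebraic connectivity (Fiedler value)
#'
#' Second-smallest eigenvalue of the combinatorial Laplacian `L = D - A` of
#' an undirected binary graph. Positive iff the graph is connected; tiny
#' negative eigenvalues from floating point are clamped to zero.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal, at least 2
#'   nodes.
#' @return the second-smallest Laplacian eigenvalue (>= 0).
#' @export
laplacian_lambda2 <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) < 2L || nrow(a) != ncol(a)) stop("adjacency must be square with >= 2 nodes")
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  lap <- diag(rowSums(a)) - a
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  l2 <- sort(ev)[2L]
  max(l2, 0)
}

binarize_at <- function(f, threshold) {
  a <- (f > threshold) * 1
  diag(a) <- 0
  a
}

#' Connectedness-based binarisation threshold search
#'
#' Finds the largest threshold T on the grid `{1, 1-step, 1-2*step, ..., 0}`
#' at which the binarised graph (edges where the weight strictly exceeds T)
#' is connected, i.e. its algebraic connectivity is positive. If no grid
#' point connects the graph the step is divided by 10 and the search
#' repeated, down to `min_step`; a graph that stays disconnected even then
#' (e.g. block-diagonal with zero cross-block weights) raises an error.
#'
#' @param f symmetric connectivity matrix, zero diagonal, weights in
#'   `[0, 1]`.
#' @param step initial grid step (default 0.01, the binarisation precision).
#' @param min_step smallest step tried (default 1e-4).
#' @return object of class `binary_graph`: list with `adjacency`,
#'   `threshold_T`, `step_used`, `lambda2`.
#' @export
find_threshold <- function(f, step = 0.01, min_step = 1e-4) {
  f <- as.matrix(f)
  stopifnot(step > 0, min_step > 0, min_step <= step)
  s <- step
  repeat {
    grid <- seq(1, 0, by = -s)
    for (T in grid) {
      a <- binarize_at(f, T)
      l2 <- laplacian_lambda2(a)
      if (l2 > LAMBDA2_TOL) {
        return(structure(
          list(adjacency = a, threshold_T = T, step_used = s, lambda2 = l2),
          class = "binary_graph"
        ))
      }
    }
    if (s <= min_step) {
      stop("graph cannot be connected at any threshold (down to step ",
           s, ")")
    }
    s <- max(s / 10, min_step)
  }
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf(
    "<binary_graph> %d nodes, %d edges, T=%g (step %g), lambda2=%.4g\n",
    nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold_T, x$step_used,
    x$lambda2
  ))
  invisible(x)
}

as_igraph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Classical graph metrics of a connected binary graph
#'
#' Computes the four comparison metrics on a binarised network:
#' * clustering: mean local clustering coefficient
#'   `2 * triangles_i / (k_i * (k_i - 1))`, taken as 0 for degree < 2;
#' * characteristic path length: mean shortest-path length over unordered
#'   node pairs;
#' * global efficiency: mean inverse shortest-path length over unordered
#'   node pairs;
#' * vulnerability: `max_i (E - E^(-i)) / E`, the largest relative drop of
#'   global efficiency when a single node (and its edges) is removed. The
#'   efficiency of the reduced graph is computed over the remaining pairs,
#'   with unreachable pairs contributing 0, and is 0 when fewer than two
#'   nodes remain.
#'
#' @param g a `binary_graph` from [find_threshold()], or a symmetric 0/1
#'   adjacency matrix of a connected graph.
#' @return named list with `clustering`, `char_path_length`,
#'   `global_efficiency`, `vulnerability`.
#' @export
compute_metrics <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else as.matrix(g)
  ig <- as_igraph(adj)
  if (!igraph::is_connected(ig)) stop("graph must be connected")
  n <- nrow(adj)
  local_cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0  # degree-1 nodes
  eff_of <- function(graph) {
    if (igraph::vcount(graph) < 2L) return(0)
    igraph::global_efficiency(graph)
  }
  e_glob <- eff_of(ig)
  drops <- vapply(seq_len(n), function(i) {
    e_glob - eff_of(igraph::delete_vertices(ig, i))
  }, numeric(1))
  list(
    clustering = mean(local_cc),
    char_path_length = igraph::mean_distance(ig, directed = FALSE),
    global_efficiency = e_glob,
    vulnerability = max(drops) / e_glob
  )
}

#' Per-epoch classical metrics of an FCGB sequence
#'
#' Runs [find_threshold()] and [compute_metrics()] on every epoch. Epochs
#' whose graph cannot be connected at any threshold are kept as rows of
#' `NA` metrics (with a message) rather than aborting the series.
#'
#' @param seq an `fcgb_sequence`.
#' @param step initial binarisation step (default 0.01).
#' @param min_step smallest step (default 1e-4).
#' @return data.frame with one row per epoch: `epoch_time_s`, `clustering`,
#'   `char_path_length`, `global_efficiency`, `vulnerability`,
#'   `threshold_T`.
#' @export
metrics_series <- function(seq, step = 0.01, min_step = 1e-4) {
  stopifnot(inherits(seq, "fcgb_sequence"))
  K <- dim(seq$values)[3]
  rows <- lapply(seq_len(K), function(k) {
    bg <- tryCatch(find_threshold(seq$values[, , k], step, min_step),
                   error = function(e) NULL)
    if (is.null(bg)) {
      message("epoch ", k, ": unconnectable graph, metrics set to NA")
      return(data.frame(epoch_time_s = seq$epoch_times[k], clustering = NA_real_,
                        char_path_length = NA_real_, global_efficiency = NA_real_,
                        vulnerability = NA_real_, threshold_T = NA_real_))
    }
    m <- compute_metrics(bg)
    data.frame(epoch_time_s = seq$epoch_times[k], clustering = m$clustering,
               char_path_length = m$char_path_length,
               global_efficiency = m$global_efficiency,
               vulnerability = m$vulnerability, threshold_T = bg$threshold_T)
  })
  do.call(rbind, rows)
}
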