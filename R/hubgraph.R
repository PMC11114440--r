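#' Weighted functional graph from a PLI matrix
#'
#' The graph is complete except where PLI is exactly 0 (no edge); the length
#' of the edge between two electrodes is the inverse of their PLI, so
#' stronger phase coupling means a shorter path. Disconnected graphs are
#' permitted: unreachable pairs simply contribute no shortest paths.
#'
#' @param conn a [connectivity_matrix()].
#' @return A `functional_graph`: list with `lengths` (matrix, `Inf` for
#'   absent edges), `labels`, `subject_id`, `band`.
#' @export
graph_from_pli <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  v <- unclass(conn)
  attributes(v) <- attributes(v)["dim"]
  len <- ifelse(v > 0, 1 / v, Inf)
  diag(len) <- Inf
  dimnames(len) <- dimnames(conn)
  structure(list(lengths = len, labels = rownames(conn),
                 subject_id = attr(conn, "subject_id"),
                 band = attr(conn, "band")),
            class = "functional_graph")
}

#' Normalized betweenness centrality per electrode
#'
#' For node i, `b_i = sum over ordered pairs (h, j) of rho_hj(i) / rho_hj`,
#' divided by `(n - 1)(n - 2)`, where `rho_hj` counts shortest paths from h
#' to j and `rho_hj(i)` those passing through i. Shortest paths are taken by
#' total inverse-PLI length (Brandes accumulation); co-minimal paths split
#' credit by path counting, with a relative tolerance of 1e-12 when
#' comparing floating-point lengths. The normalized value lies in \[0, 1],
#' reaching 1 only for a node on every shortest path between every other
#' ordered pair. BC is computed on the whole weighted graph -- no minimum
#' spanning tree or other backbone pruning.
#'
#' @param g a `functional_graph` from [graph_from_pli()], or a
#'   [connectivity_matrix()] (converted internally).
#' @return A `hub_profile`: named numeric vector of normalized BC values
#'   with attributes `subject_id` and `band`.
#' @examples
#' m <- matrix(0.5, 4, 4); diag(m) <- 0
#' m[1, 3] <- m[3, 1] <- 0; m[2, 4] <- m[4, 2] <- 0  # 4-cycle
#' conn <- connectivity_matrix(m, labels = c("a", "b", "c", "d"))
#' betweenness_profile(conn)  # each node 1/6
#' @export
betweenness_profile <- function(g) {
  if (inherits(g, "connectivity_matrix")) g <- graph_from_pli(g)
  stopifnot(inherits(g, "functional_graph"))
  n <- nrow(g$lengths)
  if (n < 3) stop("betweenness normalization needs at least 3 nodes")
  raw <- cpp_brandes_bc(g$lengths, 1e-12)
  bc <- as.numeric(raw) / ((n - 1) * (n - 2))
  names(bc) <- g$labels
  structure(bc, class = "hub_profile", subject_id = g$subject_id,
            band = g$band)
}

#' @export
print.hub_profile <- function(x, ...) {
  cat("<hub_profile> ", attr(x, "subject_id"), " / ", attr(x, "band"),
      "; top: ", names(x)[which.max(x)], " = ",
      signif(max(x), 3), "\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
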