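# Independent oracles used across the suite. Each re-implements the target
# quantity from its definition, by a route different from the package code
# (scalar loops, exhaustive enumeration, closed-form sums of squares).

# literal re-coding of the phase lag index definition: scalar loop,
# wrap to (-pi, pi], sign(0) = 0, absolute value of the mean sign
pli_oracle <- function(phase_a, phase_b) {
  stopifnot(length(phase_a) == length(phase_b))
  total <- 0
  for (k in seq_along(phase_a)) {
    d <- phase_a[k] - phase_b[k]
    w <- d %% (2 * pi)
    if (w > pi) w <- w - 2 * pi
    total <- total + sign(w)
  }
  abs(total / length(phase_a))
}

# analytic signal via R's fft (independent of the compiled kernel)
analytic_oracle <- function(x) {
  S <- length(x)
  f <- stats::fft(x)
  m <- if (S %% 2 == 0) {
    c(1, rep(2, S / 2 - 1), 1, rep(0, S / 2 - 1))
  } else {
    c(1, rep(2, (S - 1) / 2), rep(0, (S - 1) / 2))
  }
  stats::fft(f * m, inverse = TRUE) / S
}

# exhaustive-enumeration betweenness: all simple paths between every
# ordered pair, minimum total length with tolerance, fractional credit
bc_enum_oracle <- function(len, tol = 1e-9) {
  n <- nrow(len)
  paths_between <- function(h, j) {
    out <- list()
    walk <- function(node, visited, dist) {
      if (node == j) {
        out[[length(out) + 1]] <<- list(nodes = visited, dist = dist)
        return()
      }
      for (v in seq_len(n)) {
        if (v %in% visited) next
        w <- len[node, v]
        if (!is.finite(w)) next
        walk(v, c(visited, v), dist + w)
      }
    }
    walk(h, h, 0)
    out
  }
  bc <- numeric(n)
  for (h in seq_len(n)) {
    for (j in seq_len(n)) {
      if (h == j) next
      ps <- paths_between(h, j)
      if (length(ps) == 0) next
      d <- vapply(ps, function(p) p$dist, 0)
      dmin <- min(d)
      minimal <- ps[d <= dmin * (1 + tol) + tol]
      rho <- length(minimal)
      for (i in seq_len(n)) {
        if (i == h || i == j) next
        through <- sum(vapply(minimal, function(p) i %in% p$nodes, TRUE))
        bc[i] <- bc[i] + through / rho
      }
    }
  }
  bc / ((n - 1) * (n - 2))
}

# random connected graph with inverse-PLI edge lengths
random_pli_graph <- function(n, p_edge = 0.6) {
  repeat {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_edge) {
          m[i, j] <- m[j, i] <- stats::runif(1, 0.05, 1)
        }
      }
    }
    # connectivity check by reachability over present edges
    reach <- c(1)
    repeat {
      nxt <- unique(c(reach, which(colSums(m[reach, , drop = FALSE] > 0) > 0)))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (length(reach) == n) return(m)
  }
}

# closed-form split-plot (one between, one within factor) sums of squares
split_plot_oracle <- function(Y, groups) {
  groups <- droplevels(as.factor(groups))
  N <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  M <- rowMeans(Y)
  ng <- table(groups)
  Mg <- tapply(M, groups, mean)
  ss_between <- k * sum((M - gm)^2)
  ss_group <- k * sum(ng * (Mg - gm)^2)
  ss_serr <- ss_between - ss_group
  ss_node <- N * sum((colMeans(Y) - gm)^2)
  C <- do.call(rbind, lapply(levels(groups), function(g) {
    colMeans(Y[groups == g, , drop = FALSE])
  }))
  ss_cells <- sum(rep(ng, k) * (C - gm)^2)
  ss_gn <- ss_cells - ss_group - ss_node
  ss_err <- sum((Y - gm)^2) - ss_cells - ss_serr
  G <- nlevels(groups)
  list(
    F_group = (ss_group / (G - 1)) / (ss_serr / (N - G)),
    F_node = (ss_node / (k - 1)) / (ss_err / ((N - G) * (k - 1))),
    F_gn = (ss_gn / ((G - 1) * (k - 1))) / (ss_err / ((N - G) * (k - 1))))
}

# Greenhouse-Geisser epsilon from the textbook mean-based formula
gg_oracle <- function(S) {
  k <- nrow(S)
  sbar <- mean(diag(S))          # mean of diagonal entries
  mbar <- mean(S)                # grand mean
  rowm <- rowMeans(S)
  num <- (k * (sbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mbar^2)
  num / den
}

# small helper: tiny cohort configuration for fast unit tests
tiny_config <- function(..., seed = 11) {
  cohort_config(n_per_group = c(control = 2, patient = 2),
                duration_s = 30, seed = seed, ...)
}
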