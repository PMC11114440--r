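# Post hoc and auxiliary statistics: BH-FDR control, electrode-level t
# tests gated on the ANOVA, Pearson correlations, the paired score t-test,
# and top-fraction edge reporting.

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH procedure: adjusted values come from [stats::p.adjust()]
#' (monotonicity enforced); the rejection set is `q <= q_threshold`, which
#' reproduces the classical step-up comparison `p_(i) <= i * q / m`.
#'
#' @param p vector of p-values in \[0, 1].
#' @param q_threshold FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `reject` (logical).
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.2))$reject  # first four
#' @export
bh_fdr <- function(p, q_threshold = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q <= q_threshold)
}

# two-sample / paired t with explicit zero-variance handling:
# equal constants -> t = 0; a nonzero constant difference is an error.
safe_t2 <- function(x, y, var_equal = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("zero within-group variance with unequal means: t undefined")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Electrode-wise post hoc t-tests with FDR control
#'
#' Runs one t-test per electrode (independent two-sample for group
#' contrasts, paired for pre/post) and feeds the electrode family of
#' p-values to [bh_fdr()]. The tests are gated: they may only run for bands
#' whose ANOVA showed a significant main or interaction effect, so `gate`
#' must be either the band's ANOVA table (checked here) or `TRUE` when the
#' caller has already applied the gating rule; anything else is an error.
#'
#' @param x subjects x electrodes BC matrix (group mode), or the pre-
#'   session matrix (paired mode).
#' @param groups factor (`control`/`patient`) for group mode.
#' @param y post-session matrix for paired mode (same subjects and order
#'   as `x`).
#' @param gate ANOVA result from [rm_anova_mixed()] /
#'   [rm_anova_prepost()], or `TRUE`.
#' @param band band label for the output.
#' @param q_threshold FDR level across the electrode family.
#' @param var_equal pooled-variance t (classical post hoc) or Welch.
#' @return data.frame: `band`, `electrode`, `t`, `df`, `p_raw`, `q_bh`,
#'   `significant`, `direction` (sign of patient - control, or post - pre).
#' @export
posthoc_ttests <- function(x, groups = NULL, y = NULL, gate,
                           band = NA, q_threshold = 0.05,
                           var_equal = TRUE) {
  if (missing(gate)) stop("gating violated: supply the band's ANOVA table")
  if (is.data.frame(gate)) {
    if (!any(gate$significant)) {
      stop("gating violated: no significant ANOVA effect in this band")
    }
  } else if (!isTRUE(gate)) {
    stop("gating violated: gate must be an ANOVA table or TRUE")
  }
  x <- as.matrix(x)
  k <- ncol(x)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("ch", seq_len(k))
  # an electrode whose values are constant within condition but differ
  # between conditions (possible with exact betweenness ties in very small
  # cohorts) separates the conditions perfectly: reported as infinite t
  # with p = 0 rather than aborting the electrode family
  if (!is.null(y)) {                      # paired pre/post
    y <- as.matrix(y)
    if (!identical(dim(x), dim(y))) stop("paired tables differ in shape")
    res <- lapply(seq_len(k), function(j) {
      d <- y[, j] - x[, j]
      r <- tryCatch(paired_ttest(x[, j], y[, j]), error = function(e) {
        list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0)
      })
      data.frame(t = r$t, df = r$df, p_raw = r$p,
                 direction = sign(mean(d)))
    })
  } else {
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) != 2) stop("group contrast needs exactly 2 groups")
    a <- levels(groups)[1]; b <- levels(groups)[2]  # control, patient
    res <- lapply(seq_len(k), function(j) {
      dm <- mean(x[groups == b, j]) - mean(x[groups == a, j])
      r <- tryCatch(
        safe_t2(x[groups == b, j], x[groups == a, j],
                var_equal = var_equal),
        error = function(e) {
          list(t = sign(dm) * Inf, df = length(groups) - 2, p = 0)
        })
      data.frame(t = r$t, df = r$df, p_raw = r$p, direction = sign(dm))
    })
  }
  out <- do.call(rbind, res)
  fdr <- bh_fdr(out$p_raw, q_threshold)
  data.frame(band = band, electrode = labs, t = out$t, df = out$df,
             p_raw = out$p_raw, q_bh = fdr$q, significant = fdr$reject,
             direction = out$direction)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @param label description of the pair (e.g. "BC@O1-gamma vs BPRS").
#' @return data.frame: `pair`, `n`, `r`, `p`, `significant` (p < 0.05).
#' @export
pearson_corr <- function(x, y, label = "x vs y") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with >= 3 complete pairs")
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  data.frame(pair = label, n = length(x), r = unname(ct$estimate),
             p = ct$p.value, significant = ct$p.value < 0.05)
}

#' Paired t-test
#'
#' Classical paired t on `post - pre` with `n - 1` degrees of freedom and a
#' two-sided p. Identical vectors give t = 0, p = 1; a constant nonzero
#' difference (zero variance, undefined t) is an error.
#'
#' @param pre,post paired numeric vectors, n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) stop("paired vectors differ in length")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    stop("differences are a nonzero constant: t statistic undefined")
  }
  tt <- t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Strongest connectivity edges
#'
#' The `ceiling(fraction * n(n-1)/2)` strongest unordered electrode pairs
#' of a PLI matrix (the "top 20%" rendering rule of connectivity figures).
#' Pairs are written with lexicographically ordered labels; ties at the cut
#' are broken by lexicographic electrode order, so the selection is
#' deterministic.
#'
#' @param conn a [connectivity_matrix()].
#' @param fraction fraction of edges to keep, in (0, 1].
#' @return data.frame: `electrode_a`, `electrode_b`, `pli`, sorted by
#'   decreasing strength.
#' @export
top_edges <- function(conn, fraction = 0.2) {
  if (!(is.numeric(fraction) && fraction > 0 && fraction <= 1)) {
    stop("fraction must lie in (0, 1]")
  }
  labs <- rownames(conn)
  ij <- which(upper.tri(conn), arr.ind = TRUE)
  a <- labs[ij[, 1]]; b <- labs[ij[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  v <- conn[ij]
  ord <- order(-v, a, b, method = "radix")
  m <- ceiling(fraction * length(v))
  sel <- ord[seq_len(m)]
  data.frame(electrode_a = a[sel], electrode_b = b[sel], pli = v[sel])
}
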