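# Repeated-measures ANOVA layer. Sums of squares come from the standard
# split-plot decomposition (stats::aov with an Error stratum); the
# Greenhouse-Geisser epsilon is computed here from the (pooled) within-
# subject covariance via orthonormal effect contrasts and applied to the
# within-effect degrees of freedom. Effect sizes are partial eta squared.

orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor for a k-level within-subject
#' factor: `eps = tr(E)^2 / (df * tr(E %*% E))` where `E = t(M) S M` for an
#' orthonormal contrast matrix `M` (df columns) and `S` the within-subject
#' covariance (pooled across groups in mixed designs). Equals 1 exactly
#' under compound symmetry; clipped to `[1/df, 1]`.
#'
#' @param S symmetric positive semi-definite k x k covariance matrix.
#' @param M optional orthonormal contrast matrix (k x df); defaults to a
#'   full set of normalized Helmert contrasts (df = k - 1).
#' @return epsilon in `[1/df, 1]`.
#' @examples
#' gg_epsilon(diag(4))  # spherical: 1
#' @export
gg_epsilon <- function(S, M = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("within-subject covariance must be a symmetric square matrix")
  }
  k <- nrow(S)
  if (k < 2) stop("need at least a 2-level within factor")
  if (is.null(M)) M <- orthonormal_contrasts(k)
  df <- ncol(M)
  E <- t(M) %*% S %*% M
  eps <- sum(diag(E))^2 / (df * sum(E * E))
  if (!is.finite(eps)) return(1)  # degenerate zero-variance contrasts
  min(max(eps, 1 / df), 1)
}

pooled_within_cov <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  parts <- lapply(levels(groups), function(g) {
    xg <- x[groups == g, , drop = FALSE]
    (nrow(xg) - 1) * stats::cov(xg)
  })
  Reduce(`+`, parts) / (nrow(x) - nlevels(groups))
}

# F with explicit handling of (numerically) zero sums of squares, as arise
# when the two sessions of a paired design are identical
anova_f <- function(ss, df, ss_err, df_err, scale = 1) {
  tol <- 1e-12 * max(scale, 1e-300)
  if (ss < tol) ss <- 0
  if (ss_err < tol) ss_err <- 0
  if (ss_err == 0) return(if (ss == 0) 0 else Inf)
  (ss / df) / (ss_err / df_err)
}

extract_stratum <- function(summ, name) {
  tab <- summ[[name]][[1]]
  rn <- trimws(rownames(tab))
  list(ss = setNames(tab[["Sum Sq"]], rn), df = setNames(tab[["Df"]], rn))
}

#' Mixed repeated-measures ANOVA on betweenness profiles
#'
#' Split-plot design with one between-subjects factor (group) and one
#' within-subjects factor (the 16 electrodes): per-band comparison of BC
#' values between groups. Within-subject effects (node, group x node) get
#' Greenhouse-Geisser corrected p-values with epsilon estimated from the
#' pooled within-group covariance; the between effect is tested against the
#' subject-within-group stratum with uncorrected df, per standard mixed
#' practice. Effect size is partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`).
#'
#' @param bc numeric subjects x nodes matrix of BC values (no missing
#'   cells; a complete, balanced node set per subject).
#' @param groups factor of length `nrow(bc)` with >= 2 subjects per level.
#' @param band optional band label carried into the output.
#' @param alpha two-sided significance level (0.05).
#' @return data.frame with one row per effect (`group`, `node`,
#'   `group:node`): `F`, `df1`, `df2` (uncorrected), `epsilon`, `p`
#'   (uncorrected), `p_gg`, `eta_p_sq`, `significant`.
#' @export
rm_anova_mixed <- function(bc, groups, band = NA, alpha = 0.05) {
  bc <- as.matrix(bc)
  if (anyNA(bc)) stop("missing cells in BC table")
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(bc)) stop("groups must match rows of bc")
  if (any(table(groups) < 2)) stop("need >= 2 subjects per group")
  n <- nrow(bc); k <- ncol(bc); g <- nlevels(groups)
  long <- data.frame(
    y = as.vector(bc),
    subject = factor(rep(seq_len(n), times = k)),
    group = rep(groups, times = k),
    node = factor(rep(seq_len(k), each = n)))
  fit <- aov(y ~ group * node + Error(subject), data = long)
  summ <- summary(fit)
  bw <- extract_stratum(summ, "Error: subject")
  wi <- extract_stratum(summ, "Error: Within")
  eps <- gg_epsilon(pooled_within_cov(bc, groups))
  sstot <- sum((bc - mean(bc))^2)
  mk <- function(effect, ss, df, ss_err, df_err, e) {
    Fv <- anova_f(ss, df, ss_err, df_err, scale = sstot)
    data.frame(band = band, effect = effect, F = Fv, df1 = df, df2 = df_err,
               epsilon = e,
               p = pf(Fv, df, df_err, lower.tail = FALSE),
               p_gg = pf(Fv, ifelse(is.na(e), 1, e) * df,
                         ifelse(is.na(e), 1, e) * df_err,
                         lower.tail = FALSE),
               eta_p_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
  }
  out <- rbind(
    mk("group", bw$ss[["group"]], bw$df[["group"]],
       bw$ss[["Residuals"]], bw$df[["Residuals"]], NA_real_),
    mk("node", wi$ss[["node"]], wi$df[["node"]],
       wi$ss[["Residuals"]], wi$df[["Residuals"]], eps),
    mk("group:node", wi$ss[["group:node"]], wi$df[["group:node"]],
       wi$ss[["Residuals"]], wi$df[["Residuals"]], eps))
  out$p_gg[out$effect == "group"] <- out$p[out$effect == "group"]
  out$significant <- out$p_gg < alpha
  rownames(out) <- NULL
  out
}

#' Within-subject pre/post treatment ANOVA
#'
#' Two within-subject factors: treatment condition (pre vs post) and node
#' (electrodes), on paired subjects. Each within effect is tested against
#' its own subject-interaction stratum; Greenhouse-Geisser epsilon is
#' computed per effect from the covariance of the 2k cell scores using the
#' effect's orthonormal contrasts (epsilon is identically 1 for the 2-level
#' treatment factor).
#'
#' @param bc_pre,bc_post subjects x nodes matrices with matching rownames
#'   (subject ids); an unpaired subject is an error.
#' @inheritParams rm_anova_mixed
#' @return data.frame as in [rm_anova_mixed()] with effects `treatment`,
#'   `node`, `treatment:node`.
#' @export
rm_anova_prepost <- function(bc_pre, bc_post, band = NA, alpha = 0.05) {
  bc_pre <- as.matrix(bc_pre); bc_post <- as.matrix(bc_post)
  if (anyNA(bc_pre) || anyNA(bc_post)) stop("missing cells in BC table")
  if (!identical(dim(bc_pre), dim(bc_post))) {
    stop("pre and post tables must have identical dimensions")
  }
  if (!is.null(rownames(bc_pre)) || !is.null(rownames(bc_post))) {
    if (!identical(rownames(bc_pre), rownames(bc_post))) {
      stop("unpaired subjects: pre/post rownames differ")
    }
  }
  n <- nrow(bc_pre); k <- ncol(bc_pre)
  if (n < 2) stop("need >= 2 paired subjects")
  long <- data.frame(
    y = c(as.vector(bc_pre), as.vector(bc_post)),
    subject = factor(rep(rep(seq_len(n), times = k), 2)),
    treat = factor(rep(c("pre", "post"), each = n * k),
                   levels = c("pre", "post")),
    node = factor(rep(rep(seq_len(k), each = n), 2)))
  fit <- aov(y ~ treat * node + Error(subject / (treat * node)), data = long)
  summ <- summary(fit)
  st <- extract_stratum(summ, "Error: subject:treat")
  sn <- extract_stratum(summ, "Error: subject:node")
  stn <- extract_stratum(summ, "Error: subject:treat:node")
  # cell scores: columns 1..k are pre, k+1..2k post (matches kronecker order)
  D <- cbind(bc_pre, bc_post)
  S <- stats::cov(D)
  Uk <- orthonormal_contrasts(k)
  ut <- matrix(c(1, -1) / sqrt(2), 2)
  ones <- function(m) matrix(1 / sqrt(m), m)
  M_node <- kronecker(ones(2), Uk)   # columns ordered pre block then post
  M_tn <- kronecker(ut, Uk)
  eps_node <- gg_epsilon(S, M_node)
  eps_tn <- gg_epsilon(S, M_tn)
  sstot <- sum((long$y - mean(long$y))^2)
  mk <- function(effect, ss, df, ss_err, df_err, e) {
    Fv <- anova_f(ss, df, ss_err, df_err, scale = sstot)
    data.frame(band = band, effect = effect, F = Fv, df1 = df, df2 = df_err,
               epsilon = e, p = pf(Fv, df, df_err, lower.tail = FALSE),
               p_gg = pf(Fv, e * df, e * df_err, lower.tail = FALSE),
               eta_p_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
  }
  out <- rbind(
    mk("treatment", st$ss[["treat"]], st$df[["treat"]],
       st$ss[["Residuals"]], st$df[["Residuals"]], 1),
    mk("node", sn$ss[["node"]], sn$df[["node"]],
       sn$ss[["Residuals"]], sn$df[["Residuals"]], eps_node),
    mk("treatment:node", stn$ss[["treat:node"]], stn$df[["treat:node"]],
       stn$ss[["Residuals"]], stn$df[["Residuals"]], eps_tn))
  out$significant <- out$p_gg < alpha
  rownames(out) <- NULL
  out
}
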