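test_that("Greenhouse-Geisser epsilon is 1 under compound symmetry", {
  k <- 5
  S <- matrix(0.3, k, k); diag(S) <- 1
  expect_equal(gg_epsilon(S), 1)
  expect_equal(gg_epsilon(diag(4)), 1)
  expect_equal(gg_epsilon(matrix(c(2, 0.1, 0.1, 5), 2, 2)), 1)  # k = 2
  expect_error(gg_epsilon(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("epsilon matches the textbook formula on skewed covariances", {
  set.seed(30)
  A <- matrix(rnorm(9), 3, 3)
  S <- A %*% t(A) %*% diag(c(5, 1, 0.2))
  S <- (S + t(S)) / 2
  S <- S + diag(3) * (abs(min(eigen(S)$values)) + 0.1)
  expect_equal(gg_epsilon(S), gg_oracle(S), tolerance = 1e-10)
  for (r in 1:10) {
    A <- matrix(rnorm(25), 5, 5)
    S <- A %*% t(A)
    eps <- gg_epsilon(S)
    expect_equal(eps, max(min(gg_oracle(S), 1), 1 / 4), tolerance = 1e-10)
    expect_gte(eps, 1 / 4)
    expect_lte(eps, 1)
  }
})

test_that("mixed ANOVA F matches the closed-form split-plot oracle", {
  set.seed(31)
  for (r in 1:6) {
    n1 <- sample(4:9, 1); n2 <- sample(3:8, 1); k <- sample(3:6, 1)
    g <- factor(rep(c("control", "patient"), c(n1, n2)),
                levels = c("control", "patient"))
    Y <- matrix(rnorm((n1 + n2) * k), n1 + n2, k) +
      outer(as.numeric(g) - 1, seq_len(k)) * 0.4
    res <- rm_anova_mixed(Y, g)
    o <- split_plot_oracle(Y, g)
    expect_equal(res$F, c(o$F_group, o$F_node, o$F_gn), tolerance = 1e-8)
    expect_equal(res$df1, c(1, k - 1, k - 1))
    expect_equal(res$df2, c(n1 + n2 - 2, (n1 + n2 - 2) * (k - 1),
                            (n1 + n2 - 2) * (k - 1)))
    # location invariance
    res2 <- rm_anova_mixed(Y + 13.7, g)
    expect_equal(res2$F, res$F, tolerance = 1e-8)
    expect_true(all(res$eta_p_sq >= 0 & res$eta_p_sq <= 1))
  }
  expect_error(rm_anova_mixed(matrix(c(1, NA, 2, 3), 2, 2),
                              factor(c("a", "b"))), "missing")
  expect_error(rm_anova_mixed(matrix(rnorm(8), 4, 2),
                              factor(c("a", "a", "a", "b"))), ">= 2 subjects")
})

test_that("group effect, interaction and epsilon agree with car::Anova", {
  skip_if_not_installed("car")
  set.seed(32)
  n1 <- 9; n2 <- 6; k <- 5
  g <- factor(rep(c("control", "patient"), c(n1, n2)),
              levels = c("control", "patient"))
  Y <- matrix(rnorm((n1 + n2) * k), n1 + n2, k) +
    outer(as.numeric(g) - 1, sqrt(seq_len(k)))
  res <- rm_anova_mixed(Y, g)
  mlm <- stats::lm(Y ~ g)
  A <- car::Anova(mlm, idata = data.frame(node = factor(seq_len(k))),
                  idesign = ~node, type = 3)
  s <- summary(A, multivariate = FALSE)
  ut <- s$univariate.tests
  expect_equal(res$F[res$effect == "group"], unname(ut["g", "F value"]),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:node"],
               unname(ut["g:node", "F value"]), tolerance = 1e-8)
  expect_equal(res$epsilon[res$effect == "group:node"],
               unname(s$pval.adjustments["g:node", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(res$p_gg[res$effect == "group:node"],
               unname(s$pval.adjustments["g:node", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("pre/post ANOVA handles identity, permutation and car cross-check", {
  set.seed(33)
  n <- 8; k <- 4
  pre <- matrix(rnorm(n * k), n, k,
                dimnames = list(paste0("s", 1:n), NULL))
  # post == pre: treatment sum of squares is exactly zero
  res0 <- rm_anova_prepost(pre, pre)
  expect_equal(res0$F[res0$effect == "treatment"], 0)
  expect_equal(res0$F[res0$effect == "treatment:node"], 0)
  post <- pre + 0.6 + matrix(rnorm(n * k, sd = 0.5), n, k)
  res <- rm_anova_prepost(pre, post)
  expect_equal(res$epsilon[res$effect == "treatment"], 1)  # k = 2 level factor
  # consistent node relabeling leaves F unchanged
  perm <- sample(k)
  res_p <- rm_anova_prepost(pre[, perm], post[, perm])
  expect_equal(res_p$F, res$F, tolerance = 1e-10)
  expect_error(rm_anova_prepost(pre, post[n:1, ]), "unpaired")

  skip_if_not_installed("car")
  D <- cbind(pre, post)
  id <- expand.grid(node = factor(seq_len(k)),
                    treat = factor(c("pre", "post"), c("pre", "post")))
  A <- car::Anova(stats::lm(D ~ 1), idata = id, idesign = ~treat * node,
                  type = 3)
  s <- suppressWarnings(summary(A, multivariate = FALSE))  # HF eps > 1 note
  ut <- s$univariate.tests
  expect_equal(res$F[res$effect == "treatment"],
               unname(ut["treat", "F value"]), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "node"], unname(ut["node", "F value"]),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "treatment:node"],
               unname(ut["treat:node", "F value"]), tolerance = 1e-8)
  expect_equal(res$epsilon[res$effect == "node"],
               unname(s$pval.adjustments["node", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(res$epsilon[res$effect == "treatment:node"],
               unname(s$pval.adjustments["treat:node", "GG eps"]),
               tolerance = 1e-10)
})

test_that("an injected treatment effect is detected with high power", {
  # paired design, n = 14 completers, moderate uniform BC shift
  set.seed(34)
  hits <- 0
  for (r in 1:20) {
    n <- 14; k <- 16
    subj <- matrix(rnorm(n * k, sd = 0.05), n, k) + 0.2
    pre <- subj + matrix(rnorm(n * k, sd = 0.03), n, k)
    post <- subj + 0.05 + matrix(rnorm(n * k, sd = 0.03), n, k)
    rownames(pre) <- rownames(post) <- paste0("s", 1:n)
    res <- rm_anova_prepost(pre, post)
    hits <- hits + (res$p_gg[res$effect == "treatment"] < 0.05)
  }
  expect_gte(hits / 20, 0.8)
})
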