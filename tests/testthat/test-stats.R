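test_that("BH step-up rejects exactly the classical set", {
  r <- bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.2))
  expect_identical(r$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$q, p.adjust(c(0.001, 0.01, 0.02, 0.04, 0.2), "BH"))
  expect_false(any(bh_fdr(rep(0.5, 10))$reject))
  expect_true(bh_fdr(0.04)$reject)            # m = 1: q equals p
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.1, NA)), "0, 1")
  # rejection set shrinks monotonically as the threshold decreases
  set.seed(40)
  p <- runif(30)^2
  sets <- lapply(c(0.1, 0.05, 0.01), function(q) which(bh_fdr(p, q)$reject))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("post hoc t-tests respect the gating rule", {
  set.seed(41)
  x <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, letters[1:4]))
  g <- factor(rep(c("control", "patient"), each = 6),
              levels = c("control", "patient"))
  expect_error(posthoc_ttests(x, g, band = "beta"), "gating")
  ns_anova <- data.frame(effect = "group", significant = FALSE)
  expect_error(posthoc_ttests(x, g, gate = ns_anova), "gating")
  sig_anova <- data.frame(effect = "group", significant = TRUE)
  expect_s3_class(posthoc_ttests(x, g, gate = sig_anova, band = "beta"),
                  "data.frame")
})

test_that("group-contrast t-tests report direction patient minus control", {
  set.seed(42)
  n <- 20
  g <- factor(rep(c("control", "patient"), each = n),
              levels = c("control", "patient"))
  x <- matrix(rnorm(2 * n * 3, sd = 0.2), 2 * n, 3,
              dimnames = list(NULL, c("up", "down", "null")))
  x[g == "patient", "up"] <- x[g == "patient", "up"] + 2
  x[g == "patient", "down"] <- x[g == "patient", "down"] - 2
  r <- posthoc_ttests(x, g, gate = TRUE, band = "beta")
  expect_identical(r$direction[r$electrode == "up"], 1)
  expect_identical(r$direction[r$electrode == "down"], -1)
  expect_true(all(r$significant[r$electrode != "null"]))
  expect_false(r$significant[r$electrode == "null"])
  expect_true(all(r$q_bh >= r$p_raw))
  # classical pooled-variance t: cross-check one electrode against t.test
  tt <- t.test(x[g == "patient", 1], x[g == "control", 1], var.equal = TRUE)
  expect_equal(r$t[1], unname(tt$statistic), tolerance = 1e-12)
  # two constant equal groups: t = 0, never significant
  cx <- matrix(0.5, 2 * n, 1, dimnames = list(NULL, "flat"))
  rc <- posthoc_ttests(cx, g, gate = TRUE)
  expect_identical(rc$t, 0)
  expect_identical(rc$p_raw, 1)
})

test_that("paired post hoc tests use post minus pre", {
  set.seed(43)
  pre <- matrix(rnorm(10 * 2, sd = 0.1), 10, 2,
                dimnames = list(NULL, c("e1", "e2")))
  post <- pre + matrix(rnorm(20, sd = 0.02), 10, 2)
  post[, 1] <- post[, 1] + 1
  r <- posthoc_ttests(pre, y = post, gate = TRUE, band = "gamma")
  expect_identical(r$direction[1], 1)
  expect_true(r$significant[1])
  expect_false(r$significant[2])
  tt <- t.test(post[, 1], pre[, 1], paired = TRUE)
  expect_equal(r$t[1], unname(tt$statistic), tolerance = 1e-12)
})

test_that("Pearson correlation matches its covariance-formula oracle", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  set.seed(44)
  x <- rnorm(10); y <- rnorm(10)
  r <- pearson_corr(x, y, label = "fixed")
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(r$p, 2 * pt(-abs(t_oracle), 8), tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), ">= 3")
})

test_that("paired t-test handles identity, degeneracy and matches theory", {
  r0 <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r0$t, 0)
  expect_identical(r0$p, 1)
  expect_identical(r0$df, 2)
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "constant")
  expect_error(paired_ttest(1:3, 1:4), "length")
  set.seed(45)
  pre <- rnorm(14); post <- pre + rnorm(14, 0.5, 1)
  r <- paired_ttest(pre, post)
  d <- post - pre
  t_oracle <- mean(d) / (sd(d) / sqrt(14))
  expect_equal(r$t, t_oracle, tolerance = 1e-10)
  expect_equal(r$df, 13)
  expect_equal(r$p, 2 * pt(-abs(t_oracle), 13), tolerance = 1e-10)
})

test_that("top-edge selection is deterministic with lexicographic ties", {
  set.seed(46)
  m <- matrix(runif(256), 16, 16)
  m <- (m + t(m)) / 2; diag(m) <- 0
  conn <- connectivity_matrix(m, labels = as.character(default_montage()))
  te <- top_edges(conn, 0.2)
  expect_equal(nrow(te), 24)                         # ceiling(0.2 * 120)
  expect_equal(nrow(top_edges(conn, 1)), 120)
  expect_true(all(diff(te$pli) <= 0))
  expect_true(all(te$electrode_a < te$electrode_b))
  # all-equal PLI: the first 24 edges in lexicographic order
  eq <- matrix(0.5, 16, 16); diag(eq) <- 0
  conn_eq <- connectivity_matrix(eq, labels = as.character(default_montage()))
  te_eq <- top_edges(conn_eq, 0.2)
  labs <- as.character(default_montage())
  ij <- which(upper.tri(eq), arr.ind = TRUE)
  all_keys <- paste(pmin(labs[ij[, 1]], labs[ij[, 2]]),
                    pmax(labs[ij[, 1]], labs[ij[, 2]]))
  expect_identical(paste(te_eq$electrode_a, te_eq$electrode_b),
                   sort(all_keys, method = "radix")[seq_len(24)])
  expect_error(top_edges(conn, 0), "fraction")
})
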