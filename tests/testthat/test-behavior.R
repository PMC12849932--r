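test_that("factor_scores recovers a rank-2 noiseless block structure exactly", {
  fs <- factor_scores(coherent_ratings())
  expect_equal(fs$variance_explained, 1.0)
  expect_equal(unname(fs$loadings[c("care", "gratitude", "guilt"), "communal"]),
               rep(1, 3))
  expect_equal(unname(fs$loadings[c("second_order_belief", "obligation"), "obligation"]),
               rep(1, 2))
  expect_equal(unname(fs$loadings[c("care", "gratitude", "guilt"), "obligation"]),
               rep(0, 3))
  # standardized scores
  expect_equal(sd(fs$scores$pc_communal), 1)
  # identical profiles get identical scores
  r2 <- coherent_ratings()
  r2[2, c("care", "gratitude", "guilt", "second_order_belief", "obligation")] <-
    r2[1, c("care", "gratitude", "guilt", "second_order_belief", "obligation")]
  fs2 <- factor_scores(r2)
  expect_equal(fs2$scores$pc_communal[1], fs2$scores$pc_communal[2])
})

test_that("factor_scores is scale-equivariant and rejects degenerate input", {
  r <- simulate_ratings(agent_params(), sprintf("s%02d", 1:10), seed = 21)
  fs1 <- factor_scores(r)
  r2 <- r
  for (v in c("care", "gratitude", "guilt", "second_order_belief", "obligation"))
    r2[[v]] <- 3.7 * r2[[v]] + 11
  fs2 <- factor_scores(r2)
  expect_equal(fs2$scores$pc_communal, fs1$scores$pc_communal)
  expect_equal(fs2$scores$pc_obligation, fs1$scores$pc_obligation)
  # recovery: loadings all positive on the designated factor
  expect_true(all(fs1$loadings[c("care", "gratitude", "guilt"), "communal"] > 0))
  expect_true(all(fs1$loadings[c("second_order_belief", "obligation"), "obligation"] > 0))
  r$care <- 50
  expect_error(factor_scores(r), "care")
})

test_that("relative_weight applies the absolute-value trade-off formula", {
  expect_equal(relative_weight(0.3, 0.1), 0.75)
  expect_equal(relative_weight(-0.2, 0.2), 0.5)
  expect_true(is.na(relative_weight(0, 0)))
  # bounds and the equal-magnitude point, over a grid of signed betas
  g <- expand.grid(bc = c(-2, -0.5, 0.1, 1), bo = c(-1, -0.1, 0.4, 3))
  rw <- relative_weight(g$bc, g$bo)
  expect_true(all(rw >= 0 & rw <= 1))
  expect_equal(relative_weight(-5, 5), 0.5)
})

test_that("relative_weights recovers planted condition-wise weight ratios", {
  agent <- agent_params()  # planted communal:obligation increases across conditions
  d <- build_design(3, seed = 31)
  fs <- factor_scores(simulate_ratings(agent, sprintf("s%02d", 1:30), seed = 32))
  tr <- simulate_choices(agent, d, fs$scores, seed = 33)
  rw <- relative_weights(tr)
  expect_equal(nrow(rw), 30 * 3)
  m <- tapply(rw$relative_weight, rw$condition, mean)[condition_levels()]
  expect_true(all(diff(m) > 0))
  planted <- agent$w_communal / (agent$w_communal + agent$w_obligation)
  expect_equal(cor(m, planted, method = "spearman"), 1)
  # the independent per-participant mode agrees on the ordering
  rwi <- relative_weights(tr, method = "independent")
  mi <- tapply(rwi$relative_weight, rwi$condition, mean)[condition_levels()]
  expect_true(all(diff(mi) > 0))
  expect_error(relative_weights(tr[tr$participant_id == "s01", ]), "participants")
})

test_that("rm_anova_gg matches an independently coded textbook oracle", {
  # independent oracle: explicit sums of squares + epsilon from orthonormal
  # polynomial contrasts of the sample covariance
  gg_oracle <- function(X) {
    n <- nrow(X); k <- ncol(X)
    gm <- mean(X)
    ss_cond <- n * sum((colMeans(X) - gm)^2)
    ss_subj <- k * sum((rowMeans(X) - gm)^2)
    ss_tot <- sum((X - gm)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
    M <- cbind(stats::contr.poly(k))
    W <- t(M) %*% stats::cov(X) %*% M
    eps <- sum(diag(W))^2 / ((k - 1) * sum(W^2))
    p <- stats::pf(f, eps * (k - 1), eps * (k - 1) * (n - 1), lower.tail = FALSE)
    list(f = f, eps = eps, p = p)
  }
  set.seed(7)
  X <- matrix(rnorm(12, mean = rep(c(0, 0.5, 1.5), each = 4)), nrow = 4)
  res <- rm_anova_gg(X)
  ora <- gg_oracle(X)
  expect_equal(res$statistic, ora$f)
  expect_equal(res$epsilon, ora$eps)
  expect_equal(res$p, ora$p)

  # identical columns: no effect at all
  same <- matrix(rep(rnorm(5), 3), ncol = 3)
  expect_equal(rm_anova_gg(same)$statistic, 0)
  expect_error(rm_anova_gg(matrix(c(1, NA, 3, 4, 5, 6), ncol = 3)), "complete")
})

test_that("GG epsilon is bounded and approaches 1 under sphericity", {
  set.seed(8)
  for (k in c(3, 4)) {
    X <- matrix(rnorm(12 * k), ncol = k)
    eps <- rm_anova_gg(X)$epsilon
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
  # exchangeable (compound-symmetric) data at large n: epsilon near 1,
  # and the GG-corrected p can never undercut the uncorrected p
  subj <- rnorm(400)
  X <- matrix(rnorm(400 * 3, mean = c(0, 0.1, 0.2)), ncol = 3, byrow = TRUE) + subj
  res <- rm_anova_gg(X)
  expect_gt(res$epsilon, 0.97)
  p_unc <- as.numeric(sub("p_uncorrected=", "", res$note))
  expect_gte(res$p, p_unc)
})

test_that("linear_trend isolates the within-participant linear component", {
  exact <- matrix(rep(c(0.2, 0.5, 0.8), each = 6), ncol = 3)
  res <- linear_trend(exact)
  expect_equal(res$estimate, 0.3)   # slope per condition step
  expect_true(is.infinite(res$statistic))
  expect_equal(res$p, 0)
  expect_match(res$note, "exact trend")

  sym <- cbind(rnorm(8), rnorm(8), 0)
  sym[, 3] <- sym[, 1]              # (x, y, x): no linear component
  res2 <- linear_trend(sym)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  set.seed(9)
  X <- matrix(rnorm(30, mean = rep(c(0, 1, 2), each = 10)), nrow = 10)
  # one-sample t oracle on the contrast scores
  tt <- t.test(X[, 3] - X[, 1])
  res3 <- linear_trend(X)
  expect_equal(res3$statistic, unname(tt$statistic)^2)
  expect_equal(res3$p, tt$p.value)
  expect_error(linear_trend(X[, 1:2]), "3 ordered levels")
})

test_that("pairwise_comparisons reproduces paired-t intervals", {
  set.seed(10)
  X <- matrix(rnorm(24), ncol = 3, dimnames = list(NULL, c("A1S3", "A1S1", "A3S1")))
  res <- pairwise_comparisons(X)
  expect_equal(nrow(res), 3)
  tt <- t.test(X[, 3], X[, 1], paired = TRUE)
  row <- res[res$effect_name == "A3S1 - A1S3", ]
  expect_equal(row$estimate, unname(tt$estimate))
  expect_equal(row$p, tt$p.value)
  expect_equal(c(row$ci_low, row$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-12)

  # constant shift: exact difference, zero SE
  Y <- cbind(a = rnorm(6), b = 0)
  Y[, "b"] <- Y[, "a"] + 0.1
  shift <- pairwise_comparisons(Y)
  expect_equal(shift$estimate, 0.1)
  expect_lt(shift$se, 1e-12)
  # two identical columns: difference 0, CI straddles 0 degenerately
  same <- cbind(a = rnorm(6), b = 0); same[, "b"] <- same[, "a"]
  expect_equal(pairwise_comparisons(same)$p, 1)
})

test_that("mann_whitney exact p equals exhaustive enumeration for small n", {
  set.seed(12)
  cases <- list(
    list(x = rnorm(4), y = rnorm(5)),
    list(x = rnorm(6), y = rnorm(3)),
    list(x = rnorm(8), y = rnorm(8)),
    list(x = rnorm(5) + 2, y = rnorm(5))
  )
  for (cs in cases) {
    res <- mann_whitney(cs$x, cs$y)
    expect_match(res$note, "exact")
    expect_equal(res$p, mw_exact_enum(cs$x, cs$y))
  }
})

test_that("mann_whitney handles ties, separation and degenerate input", {
  x <- c(1, 2, 2, 3, 5)
  res <- mann_whitney(x, x)   # identical multisets: dead-center U
  expect_equal(res$estimate, 0)
  expect_equal(res$p, 1)
  sep <- mann_whitney(11:15, 1:5)  # complete separation: U at maximum
  expect_equal(sep$statistic, 25)
  expect_equal(sep$effect_size, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("self_payoff_comparison contrasts participant-level means, unpaired", {
  # constant generosity: the efficiency term alone forces lower self-payoff
  # in the condition where the chosen benefactor has efficiency 3
  agent <- agent_params(w_communal = c(A1S3 = 0, A1S1 = 0, A3S1 = 0),
                        w_obligation = c(A1S3 = 0, A1S1 = 0, A3S1 = 0))
  d <- build_design(3, seed = 41)
  fs <- factor_scores(simulate_ratings(agent, sprintf("s%02d", 1:12), seed = 42))
  tr <- simulate_choices(agent, d, fs$scores, seed = 43)
  res <- self_payoff_comparison(tr, "strategic", cond_hi = "A1S3", cond_ref = "A1S1")
  s <- attr(res, "samples")
  expect_gt(mean(s$ref), mean(s$hi))
  expect_gt(res$estimate, 0)  # Z positive: self-payoff decreased with efficiency

  # all-zero allocations: every relative self-payoff is 1, Z collapses
  tr0 <- tr; tr0$allocation <- 0L
  res0 <- self_payoff_comparison(tr0, "strategic", "A1S3", "A1S1")
  expect_equal(res0$estimate, 0)

  # participant with qualifying trials in only one condition stays in that sample
  tr1 <- tr[!(tr$participant_id == "s01" & tr$condition == "A1S3" &
                !is.na(tr$choice) & tr$choice == "strategic"), ]
  res1 <- self_payoff_comparison(tr1, "strategic", "A1S3", "A1S1")
  s1 <- attr(res1, "samples")
  expect_equal(length(s1$hi), length(s$hi) - 1)
  expect_equal(length(s1$ref), length(s$ref))

  tr2 <- tr[!(tr$choice == "strategic" & tr$condition == "A1S3"), ]
  expect_error(self_payoff_comparison(tr2, "strategic", "A1S3", "A1S1"),
               "qualifying")
})
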