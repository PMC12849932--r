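test_that("cognitive RDMs encode the four condition codings", {
  lin <- cognitive_rdm("linear")
  gen <- cognitive_rdm("general")
  grid <- condition_grid()
  i_a1s3 <- which(grid$condition == "A1S3")[1]
  i_a1s1 <- which(grid$condition == "A1S1")[1]
  i_a3s1 <- which(grid$condition == "A3S1")[5]
  expect_equal(lin[i_a1s3, i_a3s1], 2)
  expect_equal(lin[i_a1s3, i_a1s1], 1)
  expect_equal(gen[i_a1s3, i_a3s1], 0)  # both "high efficiency"
  expect_equal(gen[i_a1s3, i_a1s1], 2)
  # cells sharing a condition are 0-dissimilar for every model (cost not coded)
  for (m in names(cognitive_models())) {
    D <- cognitive_rdm(m)
    for (cc in condition_levels()) {
      idx <- which(grid$condition == cc)
      expect_true(all(D[idx, idx] == 0))
    }
  }
  expect_error(cognitive_rdm(c(A1S3 = 1, A1S1 = 2)), "cover all conditions")
})

test_that("binary mode is proportional for two-valued codings and distinct for linear", {
  for (m in c("general", "altruistic", "strategic")) {
    D <- cognitive_rdm(m); B <- cognitive_rdm(m, binary = TRUE)
    expect_equal(D, 2 * B, ignore_attr = TRUE)
  }
  vl <- vectorize_lower(cognitive_rdm("linear"))
  vb <- vectorize_lower(cognitive_rdm("linear", binary = TRUE))
  expect_gt(max(abs(vl / max(vl) - vb)), 0)
})

test_that("the four cognitive dissimilarity patterns are mutually distinguishable", {
  vs <- lapply(names(cognitive_models()), function(m)
    vectorize_lower(cognitive_rdm(m)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(cor(vs[[i]], vs[[j]]), 1 - 1e-6)
})

test_that("parcel_rdm computes correlation distance with its invariances", {
  set.seed(16)
  X <- matrix(rnorm(27 * 10), nrow = 27)
  lab <- rep(1L, 10)
  D <- parcel_rdm(X, lab, 1L)
  expect_equal(diag(D), rep(0, 27), ignore_attr = TRUE)
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 2))
  # identical and anti-correlated patterns hit the bounds
  X2 <- X; X2[2, ] <- X2[1, ]
  expect_equal(parcel_rdm(X2, lab, 1L)[1, 2], 0)
  X3 <- X; X3[2, ] <- -scale(X3[1, ], scale = FALSE) + mean(X3[1, ])
  expect_equal(parcel_rdm(X3, lab, 1L)[1, 2], 2)
  # Pearson invariances: per-condition scalar shifts and positive scaling
  shift <- matrix(rep(rnorm(27), times = 10), nrow = 27)
  expect_equal(unclass(parcel_rdm(X + shift, lab, 1L)), unclass(D),
               tolerance = 1e-10)
  expect_equal(unclass(parcel_rdm(3.5 * X + 2, lab, 1L)), unclass(D),
               tolerance = 1e-10)
  # degenerate condition pattern: warn and skip
  X4 <- X; X4[5, ] <- 2
  expect_warning(out <- parcel_rdm(X4, lab, 1L), "degenerate")
  expect_null(out)
  expect_error(parcel_rdm(X, lab, 2L), "not present")
  expect_error(parcel_rdm(X, rep(c(1L, 2L), c(8, 2)), 2L), "fewer than 3")
})

test_that("vectorize_lower uses the canonical pair order and round-trips", {
  D <- cognitive_rdm("linear")
  v <- vectorize_lower(D)
  expect_length(v, 27 * 26 / 2)
  expect_equal(v[1], D[2, 1])  # pair (2,1) precedes
  expect_equal(v[2], D[3, 1])  # pair (3,1)
  expect_equal(rdm_from_vector(v), unclass(D), ignore_attr = TRUE)
  # constant off-diagonal RDM flattens to a constant vector
  C <- matrix(0.7, 5, 5); diag(C) <- 0
  expect_equal(vectorize_lower(C), rep(0.7, 10))
  A <- D; A[1, 2] <- 9
  expect_error(vectorize_lower(A), "symmetric")
})

test_that("mixed_rsa solves exactly on noiseless constructions", {
  x <- vectorize_lower(cognitive_rdm("general"))
  Y <- rbind(x, x, x, x)
  res <- mixed_rsa(Y, x)
  expect_equal(res$coefficient, 1)
  expect_equal(res$se, 0)
  # participant-specific constants are absorbed by the random intercepts
  Y2 <- 2 * Y + c(1, -3, 0.5, 10)
  res2 <- mixed_rsa(Y2, x)
  expect_equal(res2$coefficient, 2)
  expect_equal(res2$se, 0)
  expect_error(mixed_rsa(Y, rep(1, length(x))), "constant model")
  expect_error(mixed_rsa(Y[1:2, ], x), "at least 3")
})

test_that("closed-form engine agrees with the lme4 route", {
  set.seed(17)
  x <- vectorize_lower(cognitive_rdm("linear"))
  n <- 8
  Y <- t(replicate(n, 0.05 * x + rnorm(length(x), sd = 0.3))) + rnorm(n)
  a <- mixed_rsa(Y, x, engine = "auto")
  l <- mixed_rsa(Y, x, engine = "lmer")
  expect_equal(a$coefficient, l$coefficient, tolerance = 1e-6)
  expect_equal(a$se, l$se, tolerance = 1e-4)
  f <- mixed_rsa(Y, x, engine = "fixed")
  expect_equal(a$coefficient, f$coefficient, tolerance = 1e-10)
})

test_that("fdr_correct implements the BH step-up procedure", {
  res <- data.frame(p_raw = c(0.01, 0.02, 0.03, 0.5))
  out <- fdr_correct(res)
  expect_equal(out$p_fdr, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  # hand-coded step-up oracle on a random vector
  set.seed(18)
  p <- runif(50)
  m <- length(p); o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(fdr_correct(data.frame(p_raw = p))$p_fdr[o], pmin(adj, 1))
  expect_equal(fdr_correct(data.frame(p_raw = 0.03))$p_fdr, 0.03)  # m = 1
  expect_true(all(fdr_correct(data.frame(p_raw = rep(0.001, 200)))$significant))
  expect_error(fdr_correct(data.frame(p_raw = c(0.5, 1.2))), "0, 1")
})

test_that("rsa_parcelwise recovers planted parcels and FDRs per model", {
  # constant motive loadings: at this small voxel count the per-parcel
  # footprint of condition-varying motive maps is itself detectable signal
  nb <- simulate_condition_maps(
    small_neural_spec(a = c(A1S3 = 1, A1S1 = 1, A3S1 = 1),
                      b = c(A1S3 = 1, A1S1 = 1, A3S1 = 1)), 15, seed = 19)
  pr <- rsa_parcelwise(nb$maps, nb$parcellation)
  sp <- small_neural_spec()$signal_parcels
  for (m in names(sp)) {
    d <- pr[pr$model == m, ]
    expect_true(all(d$significant[d$parcel_id %in% sp[[m]]]), info = m)
    expect_true(all(d$p_fdr >= d$p_raw))
  }
  # noise parcels stay quiet
  noise_sig <- pr$significant[!pr$parcel_id %in% unlist(sp)]
  expect_lte(mean(noise_sig), 0.05)
})

test_that("roi_rsa treats masks as parcels, consistent with the whole-brain route", {
  spec <- small_neural_spec(a = c(A1S3 = 0, A1S1 = 0, A3S1 = 0),
                            b = c(A1S3 = 0, A1S1 = 0, A3S1 = 0))
  nb <- simulate_condition_maps(spec, 10, seed = 20)
  pr <- rsa_parcelwise(nb$maps, nb$parcellation, models = "strategic")
  # an ROI identical to a parcel reproduces that parcel's coefficient and Z
  roi <- list(one_parcel = nb$parcellation == 5L)
  rr <- roi_rsa(nb$maps, roi, "strategic")
  ref <- pr[pr$parcel_id == 5L & pr$model == "strategic", ]
  expect_equal(rr$coefficient, ref$coefficient)
  expect_equal(rr$z, ref$z)
  # planted-signal recovery: a synthetic "ventral striatum" mask over the
  # strategic-model parcels lights up; a noise-parcel mask does not
  masks <- list(ventral_striatum = nb$parcellation %in% spec$signal_parcels$strategic,
                control_region = nb$parcellation %in% 15:16)
  rs <- roi_rsa(nb$maps, masks, "strategic")
  expect_true(rs$significant[rs$roi == "ventral_striatum"])
  expect_false(rs$significant[rs$roi == "control_region"])
  expect_error(roi_rsa(nb$maps, list(tiny = c(1L, 2L)), "strategic"),
               "fewer than 3")
  expect_error(roi_rsa(nb$maps, list(nb$parcellation == 1L), "strategic"),
               "named")
})
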