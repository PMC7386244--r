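test_that("count filtering is gene-first and order-dependent", {
  # gene totals 0, 5, 100: threshold 1 keeps two genes
  m <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  m["g2", ] <- c(2, 2, 1)
  m["g3", ] <- c(40, 50, 10)
  expect_identical(filter_counts(m, 0, 0), structure(m, kept_spots = 1:3))
  f <- filter_counts(m, 1, 0)
  expect_equal(rownames(f), c("g2", "g3"))

  # spot s3 only survives through g1; removing g1 drops it
  m2 <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  m2["g1", ] <- c(0, 0, 4)
  m2["g2", ] <- c(10, 10, 1)
  f2 <- filter_counts(m2, min_counts_gene = 5, min_counts_spot = 5)
  expect_equal(colnames(f2), c("s1", "s2"))

  expect_error(filter_counts(m2, 5, 100), "all spots removed")
})

test_that("Pearson residuals match the closed form and its Poisson limit", {
  cnt <- matrix(c(3, 0, 2, 1, 5, 0, 4, 2, 7), 3, 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  theta <- 100
  gt <- rowSums(cnt); st <- colSums(cnt); tot <- sum(cnt)
  mu <- outer(gt, st) / tot
  oracle <- (cnt - mu) / sqrt(mu + mu^2 / theta)
  clip <- sqrt(3)
  oracle <- pmin(pmax(oracle, -clip), clip)
  r <- pearson_residuals(cnt, theta = theta)
  expect_equal(unclass(r), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)

  # counts exactly at expectation -> all residuals zero
  flat <- outer(c(2, 4), c(3, 3, 3))
  dimnames(flat) <- list(c("a", "b"), c("x", "y", "z"))
  expect_true(all(abs(pearson_residuals(flat)) < 1e-12))

  # theta -> Inf equals the Poisson residual
  r_inf <- pearson_residuals(cnt, theta = Inf, clip = 100)
  expect_equal(unclass(r_inf), (cnt - mu) / sqrt(mu), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(pearson_residuals(matrix(0, 2, 2)), "zero grand total")
})

test_that("residuals center near zero for well-covered genes", {
  set.seed(71)
  spots <- make_hex_grid(10, 10)
  sim <- simulate_counts(spots, n_genes = 150, k = 2, effect = 0, theta = 50)
  cnt <- as.matrix(sim$counts)
  r <- pearson_residuals(cnt, theta = 50)
  covered <- rowSums(cnt) >= 50
  expect_true(all(abs(rowMeans(r)[covered]) < 0.2))
})

test_that("the non-negative transform clips or shifts as requested", {
  R <- matrix(c(1.5, -2.5, 0, 3), 2, 2)
  expect_equal(nonneg_transform(R), pmax(R, 0), ignore_attr = TRUE)
  expect_equal(nonneg_transform(R, "shift"), R + 2.5,
               ignore_attr = TRUE)
  allpos <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(nonneg_transform(allpos), allpos, ignore_attr = TRUE)
  set.seed(72)
  X <- matrix(rnorm(100), 10)
  expect_equal(nonneg_transform(X), matrix(pmax(X, 0), 10),
               ignore_attr = TRUE)
})

test_that("ICA initialization is deterministic and block-aware", {
  set.seed(73)
  # two disjoint block patterns
  X <- matrix(rexp(40 * 30, 5), 40, 30)
  X[1:20, 1:15] <- X[1:20, 1:15] + 4
  X[21:40, 16:30] <- X[21:40, 16:30] + 4
  init <- nmf_ica_init(X, k = 2, seed = 5)
  expect_equal(init$method, "ica")
  expect_true(all(init$W0 >= 0) && all(init$H0 >= 0))
  for (j in 1:2) {
    mass1 <- sum(init$W0[1:20, j])
    mass2 <- sum(init$W0[21:40, j])
    expect_gt(max(mass1, mass2) / (mass1 + mass2), 0.7)
  }

  init2 <- nmf_ica_init(X, k = 2, seed = 5)
  expect_identical(init, init2)

  i1 <- nmf_ica_init(X, k = 1, seed = 5)
  expect_equal(dim(i1$W0), c(40, 1))
})

test_that("NMF reaches an exact factorization when one exists", {
  set.seed(74)
  Wt <- matrix(rexp(30 * 3), 30, 3)
  Ht <- matrix(rexp(3 * 40), 3, 40)
  X <- Wt %*% Ht
  # multiplicative updates have a slow convergence tail on exact-rank
  # problems; give them room
  m <- fit_nmf(X, k = 3, max_iter = 50000, tol = 0, seed = 1)
  rel_err <- sqrt(sum((X - m$W %*% m$H)^2) / sum(X^2))
  expect_lt(rel_err, 1e-3)
  expect_true(all(m$W >= 0) && all(m$H >= 0))

  # rank-1 case
  X1 <- outer(rexp(20), rexp(15))
  m1 <- fit_nmf(X1, k = 1, max_iter = 500, tol = 1e-14, seed = 1)
  expect_lt(sqrt(sum((X1 - m1$W %*% m1$H)^2) / sum(X1^2)), 1e-6)

  # unit-norm W columns
  expect_equal(unname(colSums(m$W^2)), rep(1, 3), tolerance = 1e-9)
})

test_that("the NMF objective trace never increases", {
  set.seed(75)
  for (i in 1:3) {
    X <- matrix(rexp(25 * 35), 25, 35)
    m <- fit_nmf(X, k = 4, seed = i)
    expect_true(all(diff(m$objective_trace) <=
                      1e-10 * m$objective_trace[1]))
  }
})

test_that("driver genes are the top-loading features of a factor", {
  W <- matrix(c(0.9, 0.1, 0, 0.2, 0.3, 0.5), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  model <- structure(list(W = W, H = matrix(0, 2, 4), k = 2,
                          objective_trace = 1, iterations = 1,
                          converged = TRUE, init_method = "user"),
                     class = "factor_model")
  expect_equal(top_drivers(model, 1, 2), c("g1", "g2"))
  expect_equal(top_drivers(model, 2, 10), c("g3", "g2", "g1"))
  expect_error(top_drivers(model, 3), "factor_index")
})

test_that("planted spatial factors are recovered with their driver genes", {
  spots <- make_hex_grid(20, 20)
  sim <- simulate_counts(spots, n_genes = 150, k = 3, effect = 5,
                         theta = 10, seed = 81)
  X <- nonneg_transform(pearson_residuals(as.matrix(sim$counts)))
  m <- fit_nmf(X, k = 3, seed = 81)
  mt <- match_factors(m$H, sim$truth$factor_patterns)
  expect_gte(mt$mean_cosine, 0.8)
  hits <- vapply(seq_len(3), function(f) {
    mean(top_drivers(m, f, 10) %in%
           sim$truth$factor_gene_sets[[mt$assignment[f]]])
  }, numeric(1))
  expect_true(all(hits >= 0.8))
})

test_that("tidy and glance summarize a factor model", {
  set.seed(76)
  X <- matrix(rexp(20 * 10), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  m <- fit_nmf(X, k = 2, seed = 1)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 40)
  expect_named(td, c("gene", "factor", "loading"))
  gl <- generics::glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$k, 2)
})
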