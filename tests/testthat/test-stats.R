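test_that("alpha richness counts rows and rejects non-binary input", {
  m <- rbind(s1 = c(0, 0, 0), s2 = c(1, 1, 0), s3 = c(1, 1, 1))
  colnames(m) <- paste0("t", 1:3)
  expect_identical(alpha_richness(m), c(s1 = 0L, s2 = 2L, s3 = 3L))
  expect_error(alpha_richness(m * 2), "binary")
  set.seed(2)
  m8 <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12,
               dimnames = list(paste0("s", 1:8), paste0("t", 1:12)))
  expect_identical(unname(alpha_richness(m8)), as.integer(rowSums(m8)))
})

test_that("Jaccard dissimilarity matches set arithmetic", {
  m <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1), c = c(1, 1, 1, 0),
             d = c(0, 0, 0, 1))
  colnames(m) <- paste0("t", 1:4)
  J <- jaccard_matrix(m)
  expect_equal(J["a", "b"], 0.5)          # 1 - 2/4
  expect_equal(J["a", "c"], 0)            # identical
  expect_equal(J["a", "d"], 1)            # disjoint
  expect_true(isSymmetric(J))
  expect_true(all(diag(J) == 0))
  expect_true(all(J >= 0 & J <= 1))
})

test_that("Jaccard on empty-empty pairs is NA with a warning", {
  m <- rbind(a = c(1, 0), b = c(0, 0), c = c(0, 0))
  colnames(m) <- c("t1", "t2")
  expect_warning(J <- jaccard_matrix(m), "empty")
  expect_true(is.na(J["b", "c"]))
  expect_equal(J["a", "b"], 1) # empty vs non-empty is defined: total turnover
})

test_that("taxon-area regression recovers exact power laws and errors on zeros", {
  areas <- c(2, 4, 7, 11, 18, 26, 31, 40)
  rich <- 10 * areas^0.25
  fit <- taxon_area_regression(rich, areas)
  expect_equal(fit$slope, 0.25, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(c(fit$df_num, fit$df_den), c(1, 6))

  flat <- taxon_area_regression(rep(5, 8), areas)
  expect_equal(flat$slope, 0)

  expect_error(taxon_area_regression(c(0, 2, 3), c(1, 2, 3)), "site")
  expect_error(taxon_area_regression(c(1, 2, 3), c(0, 2, 3)), "site")
  expect_error(taxon_area_regression(c(1, 2), c(1, 2)), ">= 3")
})

test_that("OLS coefficients equal the normal-equation solution", {
  set.seed(8)
  areas <- exp(runif(8, 0, 4))
  rich <- pmax(1, round(exp(runif(8, 1, 3))))
  fit <- taxon_area_regression(rich, areas)
  X <- cbind(1, log10(areas)); y <- log10(rich)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  # F from first principles
  res <- y - X %*% beta
  mss <- sum((X %*% beta - mean(y))^2)
  expect_equal(fit$F_statistic, (mss / 1) / (sum(res^2) / 6), tolerance = 1e-8)
})

test_that("ANCOVA df structure and nested-RSS oracle", {
  set.seed(3)
  xa <- runif(8); ya <- 1 + 2 * xa + rnorm(8, 0, .1)
  xb <- runif(8); yb <- 0.5 + 1 * xb + rnorm(8, 0, .1)
  res <- ancova_compare(data.frame(x = xa, y = ya), data.frame(x = xb, y = yb))
  expect_equal(c(res$slope_test$df_num, res$slope_test$df_den), c(1, 12))
  expect_equal(c(res$intercept_test$df_num, res$intercept_test$df_den), c(1, 13))

  # oracle: F = ((RSS0 - RSS1)/d1) / (RSS1/d2) from explicit design matrices
  rss <- function(X, y) { b <- solve(t(X) %*% X, t(X) %*% y); sum((y - X %*% b)^2) }
  x <- c(xa, xb); y <- c(ya, yb); g <- rep(c(0, 1), each = 8)
  X_full <- cbind(1, x, g, x * g)
  X_comm <- cbind(1, x, g)
  X_noc <- cbind(1, x)
  F_slope <- (rss(X_comm, y) - rss(X_full, y)) / (rss(X_full, y) / 12)
  F_int <- (rss(X_noc, y) - rss(X_comm, y)) / (rss(X_comm, y) / 13)
  expect_equal(res$slope_test$F, F_slope, tolerance = 1e-8)
  expect_equal(res$intercept_test$F, F_int, tolerance = 1e-8)
  expect_equal(res$groups["A", "slope"], unname(coef(lm(ya ~ xa))[2]),
               tolerance = 1e-10)

  # identical groups: both tests vanish
  same <- ancova_compare(data.frame(x = xa, y = ya), data.frame(x = xa, y = ya))
  expect_lt(same$slope_test$F, 1e-20)
  expect_gt(same$slope_test$p_value, 0.999)

  expect_error(ancova_compare(data.frame(x = rep(1, 4), y = 1:4),
                              data.frame(x = 1:4, y = 1:4)), "degenerate")
})

test_that("Mantel r is 1 for identical matrices and p matches enumeration at n = 4", {
  set.seed(5)
  d <- as.matrix(dist(runif(5)))
  res <- mantel_test(d, d, n_permutations = 999, seed = 1)
  expect_equal(res$r, 1)

  # exhaustive oracle over all 24 relabelings of a 4-site matrix
  d1 <- as.matrix(dist(c(0, 1, 3, 7)))
  set.seed(9)
  d2 <- as.matrix(dist(runif(4, 0, 5)))
  tri <- upper.tri(d1)
  r_obs <- cor(d1[tri], d2[tri])
  perms <- do.call(rbind, combinat_perms(4))
  r_all <- apply(perms, 1, function(p) cor(d1[tri], d2[p, p][tri]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  res <- mantel_test(d1, d2, n_permutations = 9999, seed = 3)
  expect_equal(res$r, r_obs, tolerance = 1e-10)
  expect_lt(abs(res$p_value - p_exact), 0.02)
})

test_that("Mantel p is exchangeable under joint relabeling (n = 5 fixture)", {
  set.seed(12)
  d1 <- as.matrix(dist(runif(5, 0, 10)))
  d2 <- as.matrix(dist(runif(5, 0, 10)))
  base <- mantel_test(d1, d2, n_permutations = 9999, seed = 2)
  pr <- c(3, 1, 5, 2, 4)
  rel <- mantel_test(d1[pr, pr], d2[pr, pr], n_permutations = 9999, seed = 2)
  # n = 5 triggers complete enumeration, so both p-values are exact
  expect_equal(rel$r, base$r, tolerance = 1e-12)
  expect_equal(rel$p_value, base$p_value, tolerance = 1e-12)
})

test_that("mantel_test defaults and validation follow the analysis protocol", {
  expect_identical(eval(formals(mantel_test)$n_permutations), 9999)
  d <- as.matrix(dist(1:4))
  expect_error(mantel_test(d, d[1:3, 1:3]), "dimensions")
  expect_error(mantel_test(d, matrix(runif(16), 4)), "symmetric")
  expect_error(mantel_test(d[1:2, 1:2], d[1:2, 1:2]), ">= 3")
})

test_that("flow-connected subset extracts the mainstem chain", {
  g <- glatt_network()
  fc <- flow_connected_subset(g, glatt_sites())
  expect_identical(fc$mainstem, c("a", "b", "c", "d", "e", "f"))
  expect_setequal(fc$excluded, c("ab", "cd"))

  ch <- chain_network(5)
  all5 <- flow_connected_subset(ch, paste0("r", 1:5))
  expect_identical(all5$mainstem, paste0("r", 5:1)) # outlet first
  expect_length(all5$excluded, 0)

  single <- flow_connected_subset(g, "c")
  expect_identical(single$mainstem, "c")
})

test_that("transport-scale estimators run and the exponential fit is descriptive", {
  net <- glatt_network()
  pool <- species_pool(120, 0)
  truth <- simulate_true_communities(net, pool, community_params(), seed = 44)
  edna <- sample_edna_matrix(net, truth, sampling_params(transport_scale = 3),
                             glatt_sites(), seed = 45)
  est <- estimate_transport_scale(edna, net)
  expect_identical(est$method, "exponential")
  expect_true(est$lambda > 0)
  expect_true(est$j_max > 0 && est$j_max <= 1)
})
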