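# A small binary-trait null model plus genotype fixture used throughout.
agg_fixture <- function(n = 500, m = 4, seed = 11, maf = 0.02) {
  set.seed(seed)
  X <- cbind(age = rnorm(n, 70, 6), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.3)
  G <- matrix(rbinom(n * m, 2, maf), n, m,
              dimnames = list(NULL, paste0("v", 1:m)))
  G <- G[, colSums(G) > 0, drop = FALSE]
  list(null = fit_null(y, X, "binary"), G = G)
}

test_that("davies_pvalue matches exact chi-square and quantile oracles", {
  expect_equal(davies_pvalue(1, qchisq(0.95, 1))$p, 0.05, tolerance = 1e-8)
  expect_equal(davies_pvalue(1, 0)$p, 1)
  expect_equal(davies_pvalue(c(2, 2), qchisq(0.999, 2) * 2)$p, 0.001,
               tolerance = 1e-7)
  # scale invariance
  expect_equal(davies_pvalue(c(3, 1), 5)$p, davies_pvalue(c(30, 10), 50)$p,
               tolerance = 1e-9)
  expect_error(davies_pvalue(c(1, Inf), 1), "finite")
})

test_that("davies_pvalue agrees with Monte Carlo on mixtures", {
  set.seed(77)
  for (lam in list(c(2, 1, 0.5), c(1, 0.2), c(4, 3, 2, 1, 0.5))) {
    k <- length(lam)
    draws <- colSums(lam * matrix(rchisq(k * 5e5, df = 1), k))
    for (q in quantile(draws, c(0.5, 0.9, 0.99))) {
      mc <- mean(draws > q)
      se <- sqrt(mc * (1 - mc) / 5e5)
      expect_lt(abs(davies_pvalue(lam, q)$p - mc), 3 * se)
    }
  }
})

test_that("davies and Liu approximations agree in the moderate range", {
  # Liu moment matching is documented to a few 1e-3 absolute in this regime
  lam <- c(2, 1.5, 1, 0.5)
  for (q in c(3, 6, 10, 15)) {
    d <- davies_pvalue(lam, q)$p
    l <- radvar:::liu_pvalue(lam, q)
    expect_lt(abs(d - l), 0.02)
  }
})

test_that("cauchy_combine matches its closed form and guards its domain", {
  expect_equal(cauchy_combine(0.5), 0.5)
  expect_equal(cauchy_combine(c(0.1, 0.1)), 0.1, tolerance = 1e-12)
  direct <- 0.5 - atan((tan(0.49 * pi) + tan(-0.49 * pi)) / 2) / pi
  expect_equal(cauchy_combine(c(0.01, 0.99)), direct, tolerance = 1e-12)
  # random closed-form checks
  set.seed(5)
  for (i in 1:20) {
    p <- runif(3, 0.01, 0.95); w <- runif(3)
    ref <- 0.5 - atan(sum((w / sum(w)) * tan((0.5 - p) * pi))) / pi
    expect_equal(cauchy_combine(p, w), ref, tolerance = 1e-12)
  }
  expect_error(cauchy_combine(c(0, 0.5)), "> 0")
  expect_error(cauchy_combine(0.5, 0), "weights")
  expect_gte(cauchy_combine(c(1e-310 + 1e-320, 1)), 1e-300)
})

test_that("bonferroni_threshold is plain division", {
  expect_equal(bonferroni_threshold(0.05, 30276), 0.05 / 30276)
  expect_equal(signif(bonferroni_threshold(0.05, 30276), 3), 1.65e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
})

test_that("single-variant sets collapse burden, SKAT and ACAT-V to one test", {
  fx <- agg_fixture(m = 1, seed = 19, maf = 0.04)
  set <- make_set(fx$G[, 1, drop = FALSE], weights = 1)
  pb <- burden_test(set, fx$null)
  pk <- skat_test(set, fx$null)
  pv <- acat_v_test(set, fx$null, mac_collapse_threshold = 0)
  expect_equal(pb$p, pk$p, tolerance = 1e-6)
  expect_equal(pb$p, pv$p, tolerance = 1e-10)
  # SKAT-O endpoint identities
  expect_equal(skat_o_test(set, fx$null, rho_grid = 1)$p, pb$p,
               tolerance = 1e-8)
  expect_equal(skat_o_test(set, fx$null, rho_grid = 0)$p, pk$p,
               tolerance = 1e-8)
})

test_that("burden test matches a hand-rolled score test and carries direction", {
  fx <- agg_fixture(m = 3, seed = 23, maf = 0.03)
  w <- c(1, 2, 0.5)[seq_len(ncol(fx$G))]
  set <- make_set(fx$G, weights = w)
  res <- burden_test(set, fx$null)
  B <- drop(fx$G %*% w)
  st <- radvar:::score_stats(fx$null, matrix(B))
  zref <- st$S / sqrt(drop(st$V))
  expect_equal(res$statistic, zref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$p, 2 * pnorm(-abs(zref)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$direction, sign(zref), ignore_attr = TRUE)
  # degenerate set errors out
  expect_error(burden_test(make_set(matrix(0, 500, 1), maf = 0.001),
                           fx$null), "degenerate")
})

test_that("SKAT p-value agrees with Monte Carlo over its own eigenvalues", {
  fx <- agg_fixture(n = 50, m = 3, seed = 31, maf = 0.15)
  set <- make_set(fx$G, weights = rep(1, ncol(fx$G)))
  res <- skat_test(set, fx$null)
  st <- radvar:::score_stats(fx$null, set$G)
  K <- st$V * outer(set$weights, set$weights)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev)]
  set.seed(99)
  draws <- colSums(ev * matrix(rchisq(length(ev) * 2e5, 1), length(ev)))
  mc <- mean(draws > res$statistic)
  expect_lt(abs(res$p - mc), 3 * sqrt(mc * (1 - mc) / 2e5))
})

test_that("SKAT-O respects endpoint and Bonferroni bounds on simulated sets", {
  cfg <- balanced_config(n_case = 400, n_control = 400, n_genes = 40,
                         vpg = 15, seed = 37)
  f <- fit_cohort(simulate_cohort(cfg))
  sets <- f$sets[vapply(f$sets, function(s) ncol(s$G) >= 2, logical(1))]
  sets <- sets[seq_len(min(100, length(sets)))]
  grid <- c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)
  for (s in sets) {
    po <- skat_o_test(s, f$null, grid)
    pb <- burden_test(s, f$null)$p
    pk <- skat_test(s, f$null)$p
    expect_lte(po$p, min(pb, pk) * length(grid) + 1e-9)
    expect_gte(po$p, 0)
  }
  expect_error(skat_o_test(sets[[1]], f$null, numeric(0)), "non-empty")
})

test_that("ACAT-V collapses ultra-rare variants and combines by Cauchy", {
  fx <- agg_fixture(n = 800, m = 5, seed = 41, maf = 0.02)
  set <- make_set(fx$G)
  # with a huge collapse threshold everything lands in one burden component
  all_collapsed <- acat_v_test(set, fx$null,
                               mac_collapse_threshold = .Machine$integer.max)
  wb <- set$weights
  U <- sum(wb * radvar:::score_stats(fx$null, set$G)$S)
  V <- drop(crossprod(wb, radvar:::score_stats(fx$null, set$G)$V %*% wb))
  expect_equal(all_collapsed$p, 2 * pnorm(-abs(U / sqrt(V))),
               tolerance = 1e-10)
  # with no collapse, reproduces the weighted Cauchy combination of
  # per-variant score p-values
  none <- acat_v_test(set, fx$null, mac_collapse_threshold = 0)
  st <- radvar:::score_stats(fx$null, set$G)
  pj <- 2 * pnorm(-abs(st$S / sqrt(diag(st$V))))
  wj <- set$weights^2 * set$maf * (1 - set$maf)
  expect_equal(none$p, cauchy_combine(pj, wj), tolerance = 1e-10)
})

test_that("ACAT-O behaves as an equal-weight Cauchy combination", {
  set <- make_set(matrix(c(1, rep(0, 99))))
  expect_equal(acat_o_test(set, c(0.5, 0.5, 0.5))$p, 0.5, tolerance = 1e-12)
  expect_equal(acat_o_test(set, 0.123)$p, 0.123, tolerance = 1e-12)
  expect_lt(acat_o_test(set, c(1e-6, 0.5, 0.5))$p, 1e-5)
  expect_error(acat_o_test(set, numeric(0)), "no valid")
})

test_that("all tests are deterministic across repeated evaluation", {
  fx <- agg_fixture(m = 4, seed = 53, maf = 0.05)
  set <- make_set(fx$G)
  for (fun in list(burden_test, skat_test, skat_o_test, acat_v_test)) {
    expect_identical(fun(set, fx$null)$p, fun(set, fx$null)$p)
  }
})

test_that("burden p-values are uniform under phenotype permutation", {
  set.seed(61)
  n <- 500
  G <- matrix(rbinom(n * 40, 1, 0.008), n, 40,
              dimnames = list(NULL, paste0("v", 1:40)))
  G <- G[, colSums(G) > 0, drop = FALSE]
  y <- rbinom(n, 1, 0.3)
  ps <- replicate(400, {
    null <- fit_null(sample(y), kind = "binary")
    burden_test(make_set(G), null)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("power ordering: burden beats SKAT for shared-direction effects", {
  # same-direction planted effects across all variants in the set
  set.seed(71)
  n <- 1200; m <- 12
  reps <- 40
  wins_b <- wins_k <- 0
  pb <- pk <- pb2 <- pk2 <- numeric(reps)
  for (r in seq_len(reps)) {
    G <- matrix(rbinom(n * m, 1, 0.01), n, m)
    G <- G[, colSums(G) > 0, drop = FALSE]
    eta <- -1 + rowSums(G) * 0.8            # all risk
    y <- rbinom(n, 1, plogis(eta))
    null <- fit_null(y, kind = "binary")
    pb[r] <- burden_test(make_set(G), null)$p
    pk[r] <- skat_test(make_set(G), null)$p
    # mixed directions: half protective
    beta <- rep(c(0.9, -0.9), length.out = ncol(G))
    eta2 <- -1 + drop(G %*% beta)
    y2 <- rbinom(n, 1, plogis(eta2))
    null2 <- fit_null(y2, kind = "binary")
    pb2[r] <- burden_test(make_set(G), null2)$p
    pk2[r] <- skat_test(make_set(G), null2)$p
  }
  expect_gte(mean(pb < 0.05), mean(pk < 0.05) - 0.1)
  expect_gte(mean(pk2 < 0.05), mean(pb2 < 0.05) - 0.1)
})

test_that("run_gene_tests returns a sorted long table", {
  cfg <- balanced_config(n_case = 300, n_control = 300, n_genes = 10,
                         vpg = 8, seed = 81)
  f <- fit_cohort(simulate_cohort(cfg))
  res <- run_gene_tests(f$sets, f$null,
                        tests = c("burden", "skat", "acatv", "acato"))
  expect_true(all(diff(res$p) >= 0))
  expect_setequal(unique(res$test), c("Burden", "SKAT", "ACATV", "ACATO"))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$n_variants >= 1))
  # direction only reported for the burden rows
  expect_true(all(is.na(res$direction[res$test != "Burden"])))
  expect_true(all(res$direction[res$test == "Burden"] %in% c(-1, 0, 1)))
})
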