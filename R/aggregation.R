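#' Tail probability of a positive linear combination of chi-squares
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_1 > q)} by numerical inversion of
#' the characteristic function (Imhof's formula), the distribution underlying
#' SKAT-type quadratic-form tests. Falls back to the Liu et al. moment-matched
#' non-central chi-square approximation when the inversion fails or returns a
#' value outside the reliable range; the fallback is flagged.
#'
#' @param eigenvalues Non-negative weights, at least one positive.
#' @param q Observed statistic, q >= 0.
#' @param acc Target absolute accuracy of the inversion (default 1e-10).
#' @return List with \code{p} and \code{method} ("imhof" or "liu").
#' @export
#' @examples
#' davies_pvalue(1, stats::qchisq(0.95, 1))$p  # ~0.05
davies_pvalue <- function(eigenvalues, q, acc = 1e-10) {
  if (any(!is.finite(eigenvalues)) || !is.finite(q) || q < 0) {
    stop("davies_pvalue needs finite eigenvalues and finite q >= 0")
  }
  lambda <- eigenvalues[eigenvalues > 1e-9 * sum(abs(eigenvalues))]
  if (!length(lambda)) stop("davies_pvalue needs a positive eigenvalue")
  # the distribution is scale-invariant: normalize to max eigenvalue 1
  scl <- max(lambda)
  lambda <- sort(lambda / scl, decreasing = TRUE)
  q <- q / scl
  if (q == 0) return(list(p = 1, method = "exact"))
  m <- length(lambda)
  if (m == 1L) {
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                method = "exact"))
  }
  if (q < 1e-3 * sum(lambda)) {
    return(list(p = liu_pvalue(lambda, q), method = "liu"))
  }
  p <- tryCatch(imhof_tail(lambda, q, acc = acc),
                error = function(e) NA_real_)
  if (is.na(p) || p > 1 + 1e-8) {
    return(list(p = liu_pvalue(lambda, q), method = "liu"))
  }
  if (p < 1e-9) {
    # oscillatory cancellation limits absolute accuracy; the saddlepoint
    # approximation has excellent relative accuracy this far out
    sp <- saddlepoint_tail(lambda, q)
    if (is.finite(sp)) return(list(p = max(sp, 1e-300), method = "saddlepoint"))
    return(list(p = liu_pvalue(lambda, q), method = "liu"))
  }
  list(p = min(max(p, 1e-300), 1), method = "imhof")
}

# cached Gauss-Legendre rule on [0, 1] (Golub-Welsch)
.radvar_env <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n = 40L) {
  key <- paste0("gl", n)
  if (!is.null(.radvar_env[[key]])) return(.radvar_env[[key]])
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b; J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  rule <- list(x = (rev(e$values) + 1) / 2,
               w = rev(2 * e$vectors[1, ]^2) / 2)
  .radvar_env[[key]] <- rule
  rule
}

# Imhof (1961) inversion integral, evaluated by vectorized Gauss-Legendre
# quadrature over oscillation-sized chunks on (0, U), with an
# integration-by-parts correction for the truncated oscillatory tail.
imhof_tail <- function(lambda, q, acc = 1e-10) {
  m <- length(lambda)
  suml <- sum(lambda)
  prodl <- exp(0.5 * sum(log(lambda)))
  theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  gfun <- function(u) 1 / (u * exp(0.25 * colSums(log1p(outer(lambda^2, u^2)))))
  omega <- q / 2
  # truncation error bounds: non-oscillatory envelope, and the residual of a
  # two-term integration-by-parts expansion of the oscillatory tail
  env_bound <- function(U) (2 / m) * U^(-m / 2) / prodl / pi
  ibp_bound <- function(U) gfun(U) * (1 + m / 2)^2 / (U^2 * omega^3) / pi
  U <- NA_real_; use_ibp <- FALSE
  for (cand in 25 * 2^(0:14)) {
    if (env_bound(cand) < acc) { U <- cand; break }
    if (ibp_bound(cand) < acc) { U <- cand; use_ibp <- TRUE; break }
  }
  if (is.na(U)) stop("imhof truncation bound not attainable")
  freq <- 0.5 * (q + suml)
  chunk <- 6 * pi / freq                   # three oscillation periods
  n_chunk <- max(1L, ceiling(U / chunk))
  if (n_chunk > 20000L) stop("imhof integration grid too large")
  rule <- gauss_legendre_01(40L)
  a <- (seq_len(n_chunk) - 1L) * (U / n_chunk)
  len <- U / n_chunk
  u <- as.vector(outer(rule$x * len, a, `+`))
  w <- rep(rule$w * len, times = n_chunk)
  total <- sum(w * sin(theta(u)) * gfun(u))
  if (use_ibp) {
    dtheta <- function(u) 0.5 * sum(lambda / (1 + lambda^2 * u^2)) - 0.5 * q
    h <- function(u) gfun(u) / dtheta(u)
    d <- 1e-3 * U
    hp <- (h(U + d) - h(U - d)) / (2 * d)
    total <- total + cos(theta(U)) * h(U) - sin(theta(U)) * hp / dtheta(U)
  }
  0.5 + total / pi
}

# Kuonen (1999) saddlepoint approximation to P(sum lambda_k chi^2_1 > q).
saddlepoint_tail <- function(lambda, q) {
  kprime <- function(t) sum(lambda / (1 - 2 * t * lambda))
  upper <- 1 / (2 * max(lambda))
  if (kprime(0) >= q) return(NA_real_)  # saddle would be negative; not a far tail
  t_hat <- stats::uniroot(function(t) kprime(t) - q,
                          lower = 0, upper = upper * (1 - 1e-12),
                          tol = 1e-14)$root
  K <- -0.5 * sum(log(1 - 2 * t_hat * lambda))
  K2 <- 2 * sum(lambda^2 / (1 - 2 * t_hat * lambda)^2)
  w <- sign(t_hat) * sqrt(2 * (t_hat * q - K))
  v <- t_hat * sqrt(K2)
  if (abs(w) < 1e-8) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Liu-Tang-Zhang moment-matched approximation for the same tail probability.
liu_pvalue <- function(lambda, q) {
  par <- liu_params(lambda)
  tstar <- (q - par$muQ) / par$sigmaQ
  p <- stats::pchisq(tstar * par$sigmaX + par$muX, df = par$df,
                     ncp = par$ncp, lower.tail = FALSE)
  min(max(p, 1e-300), 1)
}

liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    ncp <- 0
    df <- 1 / s2
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), df = df, ncp = ncp,
       muX = df + ncp, sigmaX = sqrt(2 * (df + 2 * ncp)))
}

# Quantile of the mixture at upper-tail probability p, via the Liu approximation.
liu_quantile <- function(lambda, p) {
  par <- liu_params(lambda)
  x <- stats::qchisq(p, df = par$df, ncp = par$ncp, lower.tail = FALSE)
  (x - par$muX) / par$sigmaX * par$sigmaQ + par$muQ
}

#' Cauchy combination of p-values (ACAT)
#'
#' \eqn{T = \sum_j \tilde w_j \tan((0.5 - p_j)\pi)} with weights normalized to
#' sum to one; combined p-value \eqn{0.5 - \arctan(T)/\pi}. Components below
#' 1e-16 and at or above 0.999 use the stabilized tail approximations
#' \eqn{1/(p\pi)} and \eqn{-1/((1-p)\pi)}. The result is floored at 1e-300.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @param weights Non-negative weights, not all zero; default equal.
#' @return Combined p-value.
#' @export
#' @examples
#' cauchy_combine(c(0.1, 0.1))  # 0.1
cauchy_combine <- function(pvalues, weights = rep(1, length(pvalues))) {
  stopifnot(length(pvalues) >= 1L, length(weights) == length(pvalues))
  if (any(pvalues <= 0)) stop("p-values must be > 0 (floor them upstream)")
  if (any(pvalues > 1)) stop("p-values must be <= 1")
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  p <- pvalues
  term <- numeric(length(p))
  hi <- p >= 0.999
  lo <- p < 1e-16
  mid <- !hi & !lo
  term[mid] <- tan((0.5 - p[mid]) * pi)
  term[lo] <- 1 / (p[lo] * pi)
  term[hi] <- -1 / (pmax(1 - p[hi], 1e-16) * pi)
  t_stat <- sum(w * term)
  p_out <- if (t_stat > 1e15) 1 / (t_stat * pi) else 0.5 - atan(t_stat) / pi
  min(max(p_out, 1e-300), 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0,1).
#' @param n_genes Number of genes tested (>= 1).
#' @return alpha / n_genes.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 30276)  # 1.6515e-06
bonferroni_threshold <- function(alpha, n_genes) {
  stopifnot(alpha > 0, alpha < 1, n_genes >= 1)
  alpha / n_genes
}

new_gene_test_result <- function(set, test, statistic, p, extra = list()) {
  carriers <- sum(apply(!is.na(set$G) & set$G >= 1, 1, any))
  structure(
    c(list(gene = set$gene, mask = set$mask, test = test,
           statistic = statistic, p = p,
           n_variants = ncol(set$G), n_carriers = carriers), extra),
    class = "gene_test_result"
  )
}

#' @export
print.gene_test_result <- function(x, ...) {
  cat(sprintf("<%s> gene %s mask %s: stat = %.4g, p = %.3g (%d variants, %d carriers)\n",
              x$test, x$gene, x$mask, x$statistic, x$p,
              x$n_variants, x$n_carriers))
  invisible(x)
}

#' Weighted burden score test
#'
#' Collapses qualifying dosages into \eqn{B_i = \sum_j w_j G_{ij}} and tests
#' the covariate-adjusted score \eqn{U = \sum_i (y_i - \mu_i) B_i} against its
#' null variance; two-sided p from the normal tail. The sign of Z is the
#' direction (positive = carriers enriched in cases / higher trait).
#'
#' @param set A \code{qv_set}.
#' @param null A \code{radvar_null}.
#' @return \code{gene_test_result} with test "Burden" and a \code{direction}.
#' @export
burden_test <- function(set, null) {
  st <- score_stats(null, set$G)
  w <- set$weights
  U <- sum(w * st$S)
  V <- drop(crossprod(w, st$V %*% w))
  if (V <= 1e-12) stop("degenerate qualifying set: burden score has zero variance")
  Z <- U / sqrt(V)
  p <- 2 * stats::pnorm(-abs(Z))
  new_gene_test_result(set, "Burden", Z, max(p, 1e-300),
                       list(direction = sign(Z)))
}

#' SKAT variance-component test
#'
#' Quadratic form \eqn{Q = \sum_j w_j^2 S_j^2} over per-variant scores, with
#' p-value from the weighted chi-square mixture whose weights are the
#' eigenvalues of the covariate-projected weighted genotype cross-product
#' (Imhof inversion, Liu fallback).
#'
#' @inheritParams burden_test
#' @return \code{gene_test_result} with test "SKAT".
#' @export
skat_test <- function(set, null) {
  st <- score_stats(null, set$G)
  w <- set$weights
  Q <- sum((w * st$S)^2)
  K <- st$V * outer(w, w)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev)]
  if (!length(ev)) stop("degenerate qualifying set: no positive eigenvalues")
  dv <- davies_pvalue(ev, Q)
  new_gene_test_result(set, "SKAT", Q, dv$p, list(p_method = dv$method))
}

#' SKAT-O optimal combination of burden and SKAT
#'
#' Evaluates \eqn{Q_\rho = (1-\rho) Q_{SKAT} + \rho Q_{burden}} over a grid of
#' mixing parameters and combines the per-rho p-values by the minimum-p
#' procedure of the optimal unified test (one-dimensional integration over the
#' shared burden direction).
#'
#' @inheritParams burden_test
#' @param rho_grid Mixing grid in [0,1]; must contain 0 and 1 (pure SKAT and
#'   pure burden endpoints) unless it has a single element.
#' @return \code{gene_test_result} with test "SKATO"; \code{statistic} is the
#'   minimizing rho.
#' @export
skat_o_test <- function(set, null,
                        rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)) {
  if (!length(rho_grid)) stop("rho grid must be non-empty")
  stopifnot(all(rho_grid >= 0), all(rho_grid <= 1))
  rho_grid <- sort(unique(rho_grid))
  st <- score_stats(null, set$G)
  w <- set$weights
  Sw <- w * st$S
  K <- st$V * outer(w, w)
  p <- length(Sw)
  Q_skat <- sum(Sw^2)
  Q_burden <- sum(Sw)^2
  ones <- rep(1, p)
  k1 <- drop(K %*% ones)
  sK <- sum(k1)                            # 1'K1, burden variance (w-weighted)
  if (sK <= 1e-12) stop("degenerate qualifying set: burden score has zero variance")

  per_rho <- function(rho) {
    Q <- (1 - rho) * Q_skat + rho * Q_burden
    if (rho >= 1) {
      lam <- sK
      pv <- stats::pchisq(Q / sK, df = 1, lower.tail = FALSE)
      return(list(p = max(pv, 1e-300), lambda = lam, Q = Q))
    }
    R <- (1 - rho) * diag(p) + rho
    L <- chol(R)
    M <- L %*% K %*% t(L)
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam)]
    list(p = davies_pvalue(lam, Q)$p, lambda = lam, Q = Q)
  }
  res <- lapply(rho_grid, per_rho)
  p_rho <- vapply(res, `[[`, numeric(1), "p")
  if (length(rho_grid) == 1L) {
    return(new_gene_test_result(set, "SKATO", rho_grid, p_rho[[1]],
                                list(rho = rho_grid, p_per_rho = p_rho)))
  }
  T_min <- min(p_rho)
  rho_min <- rho_grid[which.min(p_rho)]

  # quantiles q_min(rho) with per-rho tail probability T_min
  q_min <- vapply(seq_along(rho_grid), function(i) {
    if (rho_grid[i] >= 1) sK * stats::qchisq(T_min, df = 1, lower.tail = FALSE)
    else liu_quantile(res[[i]]$lambda, T_min)
  }, numeric(1))

  # moments of the burden-orthogonal remainder, all from the Gram matrix K
  u <- k1 / p                               # z-bar' z_j
  s <- sK / p^2                             # ||z-bar||^2
  cof <- u / s
  EtE <- K - tcrossprod(cof, u) - tcrossprod(u, cof) + s * tcrossprod(cof)
  lam_r <- eigen((EtE + t(EtE)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam_r <- lam_r[lam_r > 1e-10 * max(abs(lam_r), 1e-300)]
  if (!length(lam_r)) {
    # single direction (e.g. one variant): SKAT-O collapses to the burden test
    pv <- stats::pchisq(Q_burden / sK, df = 1, lower.tail = FALSE)
    return(new_gene_test_result(set, "SKATO", rho_min, max(pv, 1e-300),
                                list(rho = rho_min, p_per_rho = p_rho)))
  }
  mu_q <- sum(lam_r)
  var_remain <- 4 * sum((s * tcrossprod(cof)) * EtE)
  var_q <- 2 * sum(lam_r^2) + var_remain
  rho_c <- pmin(rho_grid, 0.999)
  tau <- (p^2 * rho_c + sum(cof^2) * (1 - rho_c)) * s

  if (T_min < 1e-9) {
    # integration cannot resolve the complement this far out; report the
    # Bonferroni-capped minimum p, as the min-p procedure's safeguard does
    p_out <- min(1, T_min * length(rho_grid))
    return(new_gene_test_result(set, "SKATO", rho_min, max(p_out, 1e-300),
                                list(rho = rho_min, p_per_rho = p_rho)))
  }
  # p = E_z[ S(thr(z^2)) ] with z ~ N(0,1) folded (x = z^2 ~ chi^2_1);
  # integrating the survivor side keeps small p at relative accuracy.
  # S is evaluated by davies on a threshold grid and interpolated (monotone
  # spline on the log scale) so the outer quadrature stays cheap.
  sd_adj <- sqrt((var_q - var_remain) / var_q)
  surv_at <- function(thr) {
    if (thr > mu_q * 1e4) return(0)
    thr_adj <- (thr - mu_q) * sd_adj + mu_q
    if (thr_adj <= 0) return(1)
    davies_pvalue(lam_r, thr_adj, acc = 1e-7)$p
  }
  zmax <- sqrt(40)
  thr_of <- function(z) {
    vapply(z, function(zi) min((q_min - tau * zi^2) / (1 - rho_c)), numeric(1))
  }
  thr_max <- thr_of(0)
  if (thr_max <= 0) {
    return(new_gene_test_result(set, "SKATO", rho_min, 1,
                                list(rho = rho_min, p_per_rho = p_rho)))
  }
  # interpolate the survivor function on the threshold scale, where it is
  # smooth and monotone (thr(z) itself can plunge steeply near its zero)
  thr_nodes <- seq(0, thr_max, length.out = 45L)
  s_nodes <- rev(pmax(cummax(rev(
    vapply(thr_nodes, surv_at, numeric(1)))), 1e-320))
  sfun <- stats::splinefun(thr_nodes, log(s_nodes), method = "monoH.FC")
  integrand <- function(z) {
    thr <- thr_of(z)
    s <- ifelse(thr <= 0, 1, pmin(exp(sfun(pmin(thr, thr_max))), 1))
    s * 2 * stats::dnorm(z)
  }
  int <- tryCatch(
    stats::integrate(integrand, 0, zmax, subdivisions = 500L,
                     rel.tol = 1e-6, abs.tol = 1e-14)$value +
      2 * stats::pnorm(zmax, lower.tail = FALSE),
    error = function(e) NA_real_)
  p_out <- if (is.na(int)) T_min * length(rho_grid) else int
  p_out <- min(p_out, T_min * length(rho_grid))   # Bonferroni safeguard
  p_out <- min(max(p_out, max(T_min, 1e-300)), 1)
  new_gene_test_result(set, "SKATO", rho_min, p_out,
                       list(rho = rho_min, p_per_rho = p_rho))
}

#' ACAT-V Cauchy combination over per-variant score tests
#'
#' Variants with minor allele count above \code{mac_collapse_threshold} get
#' individual two-sided score-test p-values; the ultra-rare remainder is
#' collapsed into a single burden p-value. Components are combined by
#' [cauchy_combine()] with weights \eqn{w_j^2 MAF_j (1 - MAF_j)} (the
#' collapsed component uses the mean weight of its members).
#'
#' @inheritParams burden_test
#' @param mac_collapse_threshold Collapse variants with MAC at or below this
#'   count (default 10).
#' @return \code{gene_test_result} with test "ACATV".
#' @export
acat_v_test <- function(set, null, mac_collapse_threshold = 10) {
  st <- score_stats(null, set$G)
  w <- set$weights
  G0 <- as.matrix(set$G); G0[is.na(G0)] <- 0
  mac <- pmin(colSums(G0), 2 * nrow(G0) - colSums(G0))
  single <- which(mac > mac_collapse_threshold)
  collapsed <- which(mac <= mac_collapse_threshold)
  comp_w <- w^2 * set$maf * (1 - set$maf)

  pvals <- numeric(0); wts <- numeric(0)
  if (length(single)) {
    vj <- diag(st$V)[single]
    ok <- vj > 1e-12
    z <- st$S[single][ok] / sqrt(vj[ok])
    pvals <- c(pvals, pmax(2 * stats::pnorm(-abs(z)), 1e-300))
    wts <- c(wts, comp_w[single][ok])
  }
  if (length(collapsed)) {
    wc <- w[collapsed]
    U <- sum(wc * st$S[collapsed])
    V <- drop(crossprod(wc, st$V[collapsed, collapsed, drop = FALSE] %*% wc))
    if (V > 1e-12) {
      pvals <- c(pvals, max(2 * stats::pnorm(-abs(U / sqrt(V))), 1e-300))
      wts <- c(wts, mean(comp_w[collapsed]))
    }
  }
  if (!length(pvals)) stop("degenerate qualifying set: no testable component")
  p <- cauchy_combine(pvals, wts)
  new_gene_test_result(set, "ACATV", stats::qcauchy(p, lower.tail = FALSE), p,
                       list(n_single = length(single),
                            n_collapsed = length(collapsed)))
}

#' ACAT-O omnibus combination across tests
#'
#' Equal-weight Cauchy combination of the available component p-values
#' (burden, SKAT, ACAT-V) for one gene-mask set.
#'
#' @param set A \code{qv_set} (used for bookkeeping fields).
#' @param pvalues Named or unnamed vector of component p-values in (0, 1].
#' @return \code{gene_test_result} with test "ACATO".
#' @export
acat_o_test <- function(set, pvalues) {
  pvalues <- pvalues[is.finite(pvalues)]
  if (!length(pvalues)) stop("no valid component p-values for ACAT-O")
  p <- cauchy_combine(pvalues)
  new_gene_test_result(set, "ACATO", stats::qcauchy(p, lower.tail = FALSE), p)
}

#' Run all gene-based tests over a qualifying-set map
#'
#' @param sets Named list of \code{qv_set} (from [build_qualifying_sets()]).
#' @param null A \code{radvar_null} fit on the same samples.
#' @param tests Character subset of burden, skat, skato, acatv, acato.
#' @param ... Passed through to the individual tests.
#' @return data.frame sorted by p with columns gene, mask, n_variants,
#'   n_carriers, test, statistic, p, direction (NA except burden).
#' @export
run_gene_tests <- function(sets, null,
                           tests = c("burden", "skat", "skato", "acatv", "acato"),
                           ...) {
  tests <- match.arg(tests, several.ok = TRUE)
  rows <- list()
  for (key in names(sets)) {
    set <- sets[[key]]
    res <- list()
    run1 <- function(fun, ...) tryCatch(fun(set, null, ...),
                                        error = function(e) NULL)
    if (any(c("burden", "acato") %in% tests)) res$burden <- run1(burden_test)
    if (any(c("skat", "acato") %in% tests))   res$skat <- run1(skat_test)
    if ("skato" %in% tests)                   res$skato <- run1(skat_o_test)
    if (any(c("acatv", "acato") %in% tests))  res$acatv <- run1(acat_v_test)
    if ("acato" %in% tests) {
      comp <- c(burden = res$burden$p, skat = res$skat$p, acatv = res$acatv$p)
      res$acato <- tryCatch(acat_o_test(set, comp), error = function(e) NULL)
    }
    res <- res[intersect(c("burden", "skat", "skato", "acatv", "acato"), tests)]
    for (r in res) {
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = r$gene, mask = r$mask, n_variants = r$n_variants,
        n_carriers = r$n_carriers, test = r$test, statistic = r$statistic,
        p = r$p,
        direction = if (!is.null(r$direction)) r$direction else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), mask = character(0),
               n_variants = integer(0), n_carriers = integer(0),
               test = character(0), statistic = numeric(0), p = numeric(0),
               direction = numeric(0))
  out[order(out$p), , drop = FALSE]
}
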