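#' Fit the covariate-only null model for score tests
#'
#' Binary traits are fit by logistic regression (iteratively reweighted least
#' squares), quantitative traits by ordinary least squares. The returned
#' object carries fitted means, working variances and the projection pieces
#' needed to compute covariate-adjusted variances of genotype score vectors;
#' every gene-based test reuses one null fit.
#'
#' @param y Outcome vector; for \code{kind = "binary"} coded 0/1.
#' @param X Covariate matrix (a column of 1s is prepended if absent). Typical
#'   columns: age, sex, platform, PCR status, PC1..PC20.
#' @param kind \code{"binary"} or \code{"quantitative"}.
#' @return Object of class \code{radvar_null} with elements \code{kind},
#'   \code{y}, \code{X}, \code{mu}, \code{v} (working variances),
#'   \code{resid}, \code{coef}.
#' @export
fit_null <- function(y, X = NULL, kind = c("binary", "quantitative")) {
  kind <- match.arg(kind)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing outcome values; subset samples first")
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (anyNA(X)) stop("missing covariate values; subset samples first")
    if (!any(apply(X, 2, function(c) all(c == c[1])))) {
      X <- cbind("(Intercept)" = 1, X)
    }
  }
  if (nrow(X) != n) stop("covariate/outcome length mismatch")

  # drop aliased columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    warning("dropping aliased covariate column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }

  if (kind == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary outcome must be coded 0/1")
    fit <- stats::glm.fit(X, y, family = stats::binomial(),
                          control = list(epsilon = 1e-12, maxit = 100))
    mu <- fit$fitted.values
    if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      stop("logistic null model did not converge cleanly (possible perfect ",
           "separation); consider Firth/penalized regression or fewer covariates")
    }
    grad <- max(abs(crossprod(X, y - mu)))
    if (grad > 1e-6 * max(1, max(abs(crossprod(X, y))))) {
      stop("logistic null model gradient did not vanish (", format(grad), ")")
    }
    v <- mu * (1 - mu)
  } else {
    fit <- stats::lm.fit(X, y)
    mu <- fit$fitted.values
    sigma2 <- sum(fit$residuals^2) / max(1, n - ncol(X))
    v <- rep(sigma2, n)
  }
  structure(
    list(kind = kind, y = y, X = X, mu = mu, v = v, resid = y - mu,
         coef = fit$coefficients),
    class = "radvar_null"
  )
}

#' @export
print.radvar_null <- function(x, ...) {
  cat(sprintf("<radvar_null> %s outcome, n = %d, %d covariate column(s)\n",
              x$kind, length(x$y), ncol(x$X)))
  invisible(x)
}

# Covariate-adjusted score statistics for a genotype matrix.
# Returns the score vector S = G'(y - mu) and its covariance
# V = G'WG - G'WX (X'WX)^-1 X'WG, with W = diag(working variances).
# Missing dosages are treated as 0 (non-carrier), matching carrier semantics.
score_stats <- function(null, G) {
  stopifnot(inherits(null, "radvar_null"))
  G <- as.matrix(G)
  if (nrow(G) != length(null$y)) {
    stop("genotype matrix rows must match null-model samples")
  }
  G[is.na(G)] <- 0
  S <- drop(crossprod(G, null$resid))
  WG <- G * null$v
  WX <- null$X * null$v
  B <- crossprod(G, WX)                       # G'WX
  XtWX <- crossprod(null$X, WX)
  V <- crossprod(G, WG) - B %*% solve(XtWX, t(B))
  V <- (V + t(V)) / 2
  list(S = S, V = V)
}
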