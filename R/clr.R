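#' Conditional logistic (step-selection) fit
#'
#' Maximizes the stratified conditional log-likelihood
#' `sum_s [beta' x_used - ln sum_c exp(beta' x_c)]` by Newton ascent with
#' step-halving, starting at `beta = 0`, stopping when the gradient
#' infinity-norm falls below `tol`.  Standard errors come from the inverse
#' observed information.  Strata containing any undefined covariate value
#' are dropped and counted; covariates with no within-stratum variation in
#' any stratum are flagged no-information and excluded (coefficient `NA`).
#'
#' @param X numeric model matrix (rows = candidate steps).
#' @param stratum stratum id per row.
#' @param case 1 for the used step, 0 for available steps.
#' @param tol gradient convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return a `clr_fit`: `beta`, `se`, `vcov`, `loglik`, `k`, `n_strata`,
#'   `aicc`, `converged`, `flags` (dropped strata count, no-information and
#'   separation flags).
#' @export
clr_fit <- function(X, stratum, case, tol = 1e-6, max_iter = 50) {
  X <- as.matrix(X)
  keep_rows <- rowSums(!is.finite(X)) == 0
  bad_strata <- unique(stratum[!keep_rows])
  keep_rows <- !(stratum %in% bad_strata)
  X <- X[keep_rows, , drop = FALSE]
  stratum <- stratum[keep_rows]
  case <- case[keep_rows]
  sid <- match(stratum, unique(stratum))
  S <- max(sid)
  if (S < 10) stop("need >= 10 usable strata")
  if (!all(tabulate(sid[case == 1], S) == 1))
    stop("each stratum needs exactly one used step")

  # no-information screen: within-stratum variance identically zero
  noinfo <- vapply(seq_len(ncol(X)), function(j) {
    rng <- rowsum(X[, j], sid, reorder = FALSE)
    cnt <- tabulate(sid)
    mx <- rowsum(X[, j]^2, sid, reorder = FALSE)
    all(mx / cnt - (rng / cnt)^2 < 1e-12)
  }, TRUE)
  full_names <- colnames(X)
  Xf <- X[, !noinfo, drop = FALSE]
  p <- ncol(Xf)
  if (p == 0) stop("no covariate varies within strata")

  beta <- rep(0, p)
  ll_fun <- function(b) {
    eta <- drop(Xf %*% b)
    mx <- as.vector(tapply(eta, sid, max))[sid]
    denom <- drop(rowsum(exp(eta - mx), sid, reorder = FALSE))
    sum(eta[case == 1]) - sum(log(denom) + tapply(eta, sid, max))
  }
  ll <- ll_fun(beta)
  converged <- FALSE
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xf %*% beta)
    mx <- as.vector(tapply(eta, sid, max))[sid]
    w <- exp(eta - mx)
    denom <- rowsum(w, sid, reorder = FALSE)[sid]
    pr <- w / denom
    grad <- drop(crossprod(Xf, case - pr))
    M <- rowsum(pr * Xf, sid, reorder = FALSE)  # stratum means
    H <- -(crossprod(Xf, pr * Xf) - crossprod(M))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      break
    }
    # step-halving on the log-likelihood
    for (h in 0:20) {
      cand <- beta + step / 2^h
      llc <- ll_fun(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
    }
    beta <- cand
    ll <- llc
    if (max(abs(beta)) > 50) {
      separation <- TRUE
      break
    }
  }
  eta <- drop(Xf %*% beta)
  mx <- as.vector(tapply(eta, sid, max))[sid]
  w <- exp(eta - mx)
  pr <- w / rowsum(w, sid, reorder = FALSE)[sid]
  M <- rowsum(pr * Xf, sid, reorder = FALSE)
  H <- -(crossprod(Xf, pr * Xf) - crossprod(M))
  V <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, p, p))
  beta_full <- setNames(rep(NA_real_, length(full_names)), full_names)
  se_full <- beta_full
  beta_full[!noinfo] <- beta
  se_full[!noinfo] <- sqrt(pmax(diag(V), 0))
  fit <- structure(list(
    beta = beta_full, se = se_full, vcov = V,
    vcov_names = full_names[!noinfo],
    loglik = ll, k = p, n_strata = S,
    converged = converged,
    flags = list(dropped_strata = length(bad_strata),
                 no_information = full_names[noinfo],
                 separation = separation)),
    class = "clr_fit")
  fit$aicc <- aicc(fit, S)
  fit
}

#' @export
print.clr_fit <- function(x, ...) {
  cat(sprintf("clr_fit: %d strata, k = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$n_strata, x$k, x$loglik, x$aicc,
              if (!x$converged) " (NOT converged)" else ""))
  est <- data.frame(estimate = x$beta, se = x$se,
                    lower = x$beta - 1.96 * x$se,
                    upper = x$beta + 1.96 * x$se)
  print(round(est, 4))
  invisible(x)
}

#' 95% confidence intervals of a conditional-logistic fit
#' @param fit a `clr_fit`.
#' @return matrix with columns `lower`, `upper`.
#' @export
clr_confint <- function(fit) {
  cbind(lower = fit$beta - 1.96 * fit$se,
        upper = fit$beta + 1.96 * fit$se)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 LL + 2k + 2k(k+1)/(n-k-1)` with `n` the number of strata (one
#' conditional likelihood contribution each).
#'
#' @param fit a `clr_fit` (or any list with `loglik` and `k`).
#' @param n_strata effective sample size.
#' @return AICc value.
#' @export
aicc <- function(fit, n_strata = fit$n_strata) {
  k <- fit$k
  if (n_strata <= k + 1) stop("n must exceed k + 1")
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n_strata - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from an ordinary least-squares regression of
#' each column on the others, over all design rows.  Values of 3 or more
#' are flagged as collinear.
#'
#' @param X numeric matrix of main-effect covariate columns.
#' @return named numeric vector with attribute `"flagged"` (names of
#'   columns with VIF >= 3, `Inf` for perfect collinearity).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 main effects")
  out <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- lm.fit(others, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(X)
  attr(out, "flagged") <- names(out)[!is.na(out) & out >= 3]
  out
}
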