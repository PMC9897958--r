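#' Reference distribution of landscape metrics
#'
#' Sample mean vector and covariance (denominator n - 1) of the seven
#' landscape metrics over a set of reference relocations - either one
#' movement's pre-EHRM home-range relocations (scope `"IND"`) or all
#' animals' pre-EHRM relocations pooled (scope `"ALL"`).  Rows with any
#' undefined metric (e.g. IJI) are excluded listwise and counted.  If the
#' covariance is ill-conditioned (condition number above `cond_max`) a ridge
#' `lambda I` is added, starting at `1e-6 trace(C)/p` and escalating tenfold
#' until conditioned; `lambda` is recorded.
#'
#' @param metrics numeric matrix, one row per reference relocation, one
#'   column per landscape metric.
#' @param scope `"IND"` or `"ALL"`.
#' @param grain grain radius, m (metadata).
#' @param n_min minimum usable rows.
#' @param cond_max condition-number ceiling before regularization.
#' @return a `reference_distribution`: `mu`, `C` (raw), `C_reg`, `C_inv`,
#'   `lambda`, `n`, `excluded_count`, `scope`, `grain`, `degenerate` flag.
#' @export
build_reference <- function(metrics, scope = c("IND", "ALL"), grain = NA,
                            n_min = 30, cond_max = 1e8) {
  scope <- match.arg(scope)
  metrics <- as.matrix(metrics)
  ok <- complete.cases(metrics)
  excluded <- sum(!ok)
  m <- metrics[ok, , drop = FALSE]
  if (nrow(m) < n_min)
    stop(sprintf("only %d usable reference relocations (need >= %d)",
                 nrow(m), n_min))
  mu <- colMeans(m)
  C <- cov(m)
  lambda <- 0
  degenerate <- FALSE
  Creg <- C
  # 2-norm condition number; zero singular values make it infinite
  # (kappa(exact = TRUE) silently drops them, so it cannot be used here)
  cond_of <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (!all(is.finite(d)) || min(d) <= 0) Inf else max(d) / min(d)
  }
  while (cond_of(Creg) > cond_max) {
    degenerate <- TRUE
    lambda <- if (lambda == 0) 1e-6 * sum(diag(C)) / ncol(C) else 10 * lambda
    if (lambda == 0) lambda <- 1e-8  # all-constant reference
    Creg <- C + diag(lambda, ncol(C))
  }
  structure(list(mu = mu, C = C, C_reg = Creg, C_inv = solve(Creg),
                 lambda = lambda, n = nrow(m), excluded_count = excluded,
                 scope = scope, grain = grain, degenerate = degenerate),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf(
    "reference_distribution: scope %s, grain %s m, n = %d (%d excluded)%s\n",
    x$scope, as.character(x$grain), x$n, x$excluded_count,
    if (x$lambda > 0) sprintf(", ridge lambda = %.3g", x$lambda) else ""))
  invisible(x)
}

#' Squared Mahalanobis dissimilarity
#'
#' `D^2 = (x - mu)^T C^{-1} (x - mu)` of observation vector(s) from a
#' reference distribution, using the (regularized) inverse covariance.
#' Larger values mean greater dissimilarity from the reference habitat.
#'
#' @param x numeric vector (one location) or matrix (one row per location).
#' @param ref a `reference_distribution`.
#' @return numeric vector of nonnegative `D^2` values.
#' @export
mahalanobis_d2 <- function(x, ref) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(ref$mu)) stop("dimension mismatch")
  xc <- sweep(as.matrix(x), 2, ref$mu)
  rowSums((xc %*% ref$C_inv) * xc)
}

#' Serialize a reference distribution to JSON
#' @param ref a `reference_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_json <- function(ref, path) {
  jsonlite::write_json(
    list(scope = ref$scope, grain = ref$grain, n = ref$n,
         excluded_count = ref$excluded_count, lambda = ref$lambda,
         mu = ref$mu, C = ref$C), path, auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(path)
}

#' Dissimilarity along an EHRM path
#'
#' For each event relocation: straight-line distance from the first event
#' fix and the squared Mahalanobis dissimilarity at each grain, plus a
#' cubic-regression-spline trend of dissimilarity against distance (the
#' diagnostic for whether dissimilar habitat becomes more available farther
#' from the home range).
#'
#' @param x,y event relocation coordinates (first element = first EHRM fix).
#' @param metrics_by_grain named list (by grain) of metric matrices, one row
#'   per relocation.
#' @param refs_by_grain named list (by grain) of `reference_distribution`s.
#' @param k spline basis dimension.
#' @return data.frame with `dist_m`, one `D2_<grain>` column per grain, and
#'   matching `trend_<grain>` spline predictions.
#' @export
dissimilarity_profile <- function(x, y, metrics_by_grain, refs_by_grain,
                                  k = 5) {
  if (length(x) < 4) stop("event needs >= 4 fixes")
  out <- data.frame(dist_m = sqrt((x - x[1])^2 + (y - y[1])^2))
  for (g in names(refs_by_grain)) {
    d2 <- mahalanobis_d2(metrics_by_grain[[g]], refs_by_grain[[g]])
    out[[paste0("D2_", g)]] <- d2
    ok <- is.finite(d2)
    if (sum(ok) > k && var(d2[ok]) > 0) {
      fit <- mgcv::gam(d2 ~ s(dist_m, bs = "cr", k = k),
                       data = out[ok, , drop = FALSE])
      tr <- rep(NA_real_, nrow(out))
      tr[ok] <- as.numeric(predict(fit))
      out[[paste0("trend_", g)]] <- tr
    } else {
      out[[paste0("trend_", g)]] <- mean(d2[ok])
    }
  }
  out
}
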