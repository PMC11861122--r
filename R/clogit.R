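# Matched-set (set-stratified) conditional logistic regression, fitted by
# Newton-Raphson on the conditional likelihood. With one case per set the
# conditional likelihood of set s is exp(x_case'b) / sum_j exp(x_j'b), i.e. a
# per-set softmax; sets whose members share identical covariate rows carry no
# information and are dropped.

#' Fit a conditional logistic regression on matched sets
#'
#' @param y logical/0-1 case indicator (exactly one case per set).
#' @param x numeric model matrix (no intercept; the set strata absorb it).
#' @param set set identifier, one level per matched set.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the gradient max-norm.
#' @return list: `coef`, `se`, `or`, `ci_lower`, `ci_upper`, `p`, `loglik`,
#'   `n_sets`, `n_dropped`, `iter`.
#' @export
clogit_fit <- function(y, x, set, max_iter = 25L, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y), length(set) == length(y))
  set <- as.character(set)
  ok_sets <- tapply(y, set, sum)
  if (any(ok_sets != 1L)) {
    stop("every matched set must contain exactly one case", call. = FALSE)
  }
  # drop uninformative sets (all members identical on every covariate)
  key <- apply(x, 1L, paste, collapse = "\r")
  info <- tapply(key, set, function(k) length(unique(k)) > 1L)
  n_dropped <- sum(!info)
  keep <- set %in% names(info)[info]
  if (!any(keep)) {
    stop("no informative matched sets: exposure identical within every set",
         call. = FALSE)
  }
  x <- x[keep, , drop = FALSE]; y <- y[keep]; set <- set[keep]
  sf <- factor(set)
  p <- ncol(x)
  beta <- rep(0, p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    eta <- eta - ave(eta, sf, FUN = max)        # stabilise the softmax
    w <- exp(eta)
    denom <- ave(w, sf, FUN = sum)
    w <- w / denom
    ll <- sum(log(w[y]))
    xbar <- vapply(seq_len(p), function(j) ave(w * x[, j], sf, FUN = sum),
                   numeric(length(w)))
    xbar <- matrix(xbar, ncol = p)
    grad <- colSums(x[y, , drop = FALSE]) -
      colSums(xbar[y, , drop = FALSE])
    # Hessian: sum over sets of weighted covariance of x
    h <- crossprod(x, x * w)
    first <- !duplicated(sf)
    h <- h - crossprod(xbar[first, , drop = FALSE])
    step <- tryCatch(solve(h, grad), error = function(e) {
      stop("singular information matrix (possible complete separation)",
           call. = FALSE)
    })
    beta_new <- beta + step
    if (any(abs(beta_new) > 15)) {
      j <- which.max(abs(beta_new))
      stop("complete separation detected for covariate '",
           colnames(x)[j], "'", call. = FALSE)
    }
    beta <- beta_new
    if (max(abs(grad)) < tol || abs(ll - ll_old) < tol) break
    ll_old <- ll
    if (it == max_iter) {
      stop(sprintf(
        "conditional logistic regression did not converge (gradient norm %.3g)",
        max(abs(grad))), call. = FALSE)
    }
  }
  eta <- drop(x %*% beta); eta <- eta - ave(eta, sf, FUN = max)
  w <- exp(eta) / ave(exp(eta), sf, FUN = sum)
  xbar <- vapply(seq_len(p), function(j) ave(w * x[, j], sf, FUN = sum),
                 numeric(length(w)))
  xbar <- matrix(xbar, ncol = p)
  h <- crossprod(x, x * w)
  first <- !duplicated(sf)
  h <- h - crossprod(xbar[first, , drop = FALSE])
  vcov <- solve(h)
  se <- sqrt(diag(vcov))
  z <- beta / se
  zq <- stats::qnorm(0.975)
  list(coef = stats::setNames(beta, colnames(x)),
       se = stats::setNames(se, colnames(x)),
       or = exp(beta), ci_lower = exp(beta - zq * se),
       ci_upper = exp(beta + zq * se),
       p = 2 * stats::pnorm(-abs(z)),
       loglik = sum(log(w[y])), n_sets = nlevels(droplevels(sf)),
       n_dropped = n_dropped, iter = it)
}

#' Crude (pooled 2x2) odds ratio with Woolf confidence interval
#'
#' `a`/`b` are exposed/unexposed cases, `c`/`d` exposed/unexposed controls.
#' With a zero margin a 0.5 continuity correction is applied when
#' `correct = TRUE`, otherwise an error is raised.
#'
#' @param a,b,c,d non-negative 2x2 counts.
#' @param correct apply the 0.5 continuity correction on zero cells.
#' @return list: `or`, `ci_lower`, `ci_upper`.
#' @export
crude_or <- function(a, b, c, d, correct = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (any(c(a, b, c, d) == 0)) {
    if (!correct) stop("zero cell; enable `correct` for the 0.5 correction",
                       call. = FALSE)
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(0.975)
  list(or = or, ci_lower = exp(log(or) - zq * se),
       ci_upper = exp(log(or) + zq * se))
}
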