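# Seemingly unrelated regression of total cost and QALY on treatment and
# covariates, estimated by feasible generalized least squares with a
# cross-equation residual covariance. The treatment coefficients are the
# baseline-adjusted incremental cost and incremental QALY
# (intervention minus control).

sur_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(X = X, y = y)
}

#' Fit a two-equation seemingly unrelated regression
#'
#' Jointly regresses total cost and QALY on the treatment indicator and
#' covariates, allowing the residuals of the two equations to be correlated.
#' Estimation is one-step feasible GLS: per-equation least squares gives
#' residuals whose 2x2 covariance (divisor n) weights the stacked GLS solve.
#' With `method = "iterated"` the covariance and coefficients are iterated to
#' convergence; with `method = "ols"` the per-equation least-squares fit is
#' returned. When both equations share an identical regressor matrix, FGLS
#' coincides with per-equation least squares.
#'
#' @param data Complete data frame (post-imputation) with the responses and
#'   covariates referenced by the formulas.
#' @param cost_formula,qaly_formula Model formulas. Defaults regress
#'   `total_cost` and `qaly` on `treatment`, the corresponding baseline value
#'   (`baseline_cost` / `baseline_utility`), `age`, `gender_male`, and
#'   `antidepressant_use`.
#' @param method `"fgls"` (default), `"iterated"`, or `"ols"`.
#' @param tol,max_iter Convergence controls for the iterated estimator.
#' @return Object of class `sur_fit` with per-equation coefficient tables,
#'   the incremental cost (`delta_cost`) and QALY (`delta_qaly`), their 2x2
#'   covariance (`vcov`), and the residual cross-equation correlation
#'   (`rho`).
#' @export
fit_sur <- function(data,
                    cost_formula = total_cost ~ treatment + baseline_cost +
                      age + gender_male + antidepressant_use,
                    qaly_formula = qaly ~ treatment + baseline_utility +
                      age + gender_male + antidepressant_use,
                    method = c("fgls", "iterated", "ols"),
                    tol = 1e-10, max_iter = 50L) {
  method <- match.arg(method)
  dc <- sur_design(cost_formula, data)
  dq <- sur_design(qaly_formula, data)
  n <- length(dc$y)
  p1 <- ncol(dc$X); p2 <- ncol(dq$X)
  if (n <= p1 + p2) stop("more parameters than observations", call. = FALSE)
  if (!"treatment" %in% colnames(dc$X) || !"treatment" %in% colnames(dq$X)) {
    stop("both equations must include the `treatment` indicator",
         call. = FALSE)
  }

  ols <- function(X, y) qr.coef(qr(X), y)
  b1 <- ols(dc$X, dc$y)
  b2 <- ols(dq$X, dq$y)

  resid_cov <- function(b1, b2) {
    e <- cbind(dc$y - as.numeric(dc$X %*% b1),
               dq$y - as.numeric(dq$X %*% b2))
    crossprod(e) / n
  }

  gls_step <- function(S) {
    Si <- solve(S)
    A <- rbind(
      cbind(Si[1, 1] * crossprod(dc$X), Si[1, 2] * crossprod(dc$X, dq$X)),
      cbind(Si[2, 1] * crossprod(dq$X, dc$X), Si[2, 2] * crossprod(dq$X)))
    v <- c(Si[1, 1] * crossprod(dc$X, dc$y) + Si[1, 2] * crossprod(dc$X, dq$y),
           Si[2, 1] * crossprod(dq$X, dc$y) + Si[2, 2] * crossprod(dq$X, dq$y))
    # equilibrate: the two blocks live on very different scales (currency^2
    # vs QALY^2), which would otherwise make the solve ill-conditioned
    d <- sqrt(diag(A))
    As <- A / tcrossprod(d)
    Vs <- solve(As)
    beta <- (Vs %*% (v / d)) / d
    list(beta = as.numeric(beta), vcov = Vs / tcrossprod(d))
  }

  iters <- 0L
  if (method == "ols") {
    S <- resid_cov(b1, b2)
    # per-equation covariance with the same divisor-n residual variance
    V <- matrix(0, p1 + p2, p1 + p2)
    V[seq_len(p1), seq_len(p1)] <- S[1, 1] * solve(crossprod(dc$X))
    V[p1 + seq_len(p2), p1 + seq_len(p2)] <- S[2, 2] * solve(crossprod(dq$X))
    beta <- c(b1, b2)
  } else {
    S <- resid_cov(b1, b2)
    fit <- gls_step(S)
    beta <- fit$beta
    V <- fit$vcov
    if (method == "iterated") {
      repeat {
        iters <- iters + 1L
        b1n <- beta[seq_len(p1)]; b2n <- beta[p1 + seq_len(p2)]
        S <- resid_cov(b1n, b2n)
        fit <- gls_step(S)
        if (max(abs(fit$beta - beta)) < tol || iters >= max_iter) {
          beta <- fit$beta; V <- fit$vcov
          break
        }
        beta <- fit$beta; V <- fit$vcov
      }
    }
    b1 <- beta[seq_len(p1)]; b2 <- beta[p1 + seq_len(p2)]
    S <- resid_cov(b1, b2)
  }
  names(b1) <- colnames(dc$X); names(b2) <- colnames(dq$X)
  i1 <- which(colnames(dc$X) == "treatment")
  i2 <- p1 + which(colnames(dq$X) == "treatment")
  v2 <- V[c(i1, i2), c(i1, i2)]
  dimnames(v2) <- list(c("delta_cost", "delta_qaly"),
                       c("delta_cost", "delta_qaly"))
  rho <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  structure(list(
    coefficients = list(cost = b1, qaly = b2),
    se = list(cost = sqrt(diag(V))[seq_len(p1)],
              qaly = sqrt(diag(V))[p1 + seq_len(p2)]),
    delta_cost = unname(b1["treatment"]),
    delta_qaly = unname(b2["treatment"]),
    vcov = v2, rho = rho, sigma = S, n = n, method = method,
    iterations = iters,
    formulas = list(cost = cost_formula, qaly = qaly_formula)
  ), class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat(sprintf("SUR fit (%s, n = %d): delta cost %.2f (SE %.2f), delta QALY %.4f (SE %.4f), residual rho %.3f\n",
              x$method, x$n, x$delta_cost, sqrt(x$vcov[1, 1]),
              x$delta_qaly, sqrt(x$vcov[2, 2]), x$rho))
  invisible(x)
}

#' Fit the SUR system on each imputed dataset and pool by Rubin's rules
#'
#' @param stack An [mice_pmm()] stack or a plain list of complete data
#'   frames.
#' @param prepare Optional function applied to each dataset before fitting
#'   (e.g. building the analysis variables from the wide panel).
#' @param ... Passed to [fit_sur()].
#' @return Object of class `sur_pooled`: Rubin-pooled `delta_cost` and
#'   `delta_qaly` ([rubin_pool()] objects) plus the per-dataset fits.
#' @export
fit_sur_pooled <- function(stack, prepare = NULL, ...) {
  datasets <- if (inherits(stack, "imputed_stack")) stack$datasets else stack
  m <- length(datasets)
  fits <- vector("list", m)
  for (i in seq_len(m)) {
    d <- datasets[[i]]
    if (!is.null(prepare)) d <- prepare(d)
    fits[[i]] <- tryCatch(fit_sur(d, ...), error = function(e) {
      stop(sprintf("SUR fit failed on imputed dataset %d: %s", i,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dcs <- vapply(fits, `[[`, 0, "delta_cost")
  dqs <- vapply(fits, `[[`, 0, "delta_qaly")
  if (m == 1L) {
    return(structure(list(
      delta_cost = list(point = dcs, se = sqrt(fits[[1]]$vcov[1, 1])),
      delta_qaly = list(point = dqs, se = sqrt(fits[[1]]$vcov[2, 2])),
      fits = fits, m = 1L), class = "sur_pooled"))
  }
  structure(list(
    delta_cost = rubin_pool(dcs, vapply(fits, function(f) f$vcov[1, 1], 0)),
    delta_qaly = rubin_pool(dqs, vapply(fits, function(f) f$vcov[2, 2], 0)),
    fits = fits, m = m), class = "sur_pooled")
}

#' @export
print.sur_pooled <- function(x, ...) {
  cat(sprintf("Pooled SUR over m = %d datasets:\n", x$m))
  cat(sprintf("  delta cost %.2f (SE %.4g)\n", x$delta_cost$point,
              x$delta_cost$se))
  cat(sprintf("  delta QALY %.5f (SE %.4g)\n", x$delta_qaly$point,
              x$delta_qaly$se))
  invisible(x)
}
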