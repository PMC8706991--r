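#' Full-quadratic model row
#'
#' Expands a point in k factors into the full second-order model row,
#' ordered `[1, x1..xk, x1x2, x1x3, ..., x(k-1)xk, x1^2, ..., xk^2]`
#' (p = 1 + k + k(k-1)/2 + k terms; p = 10 at k = 3).
#'
#' @param x Numeric vector of length k (a single design point).
#' @return Numeric vector of length p.
#' @examples
#' quadratic_row(c(1, 2, 3))  # c(1, 1,2,3, 2,3,6, 1,4,9)
#' @export
quadratic_row <- function(x) {
  quadratic_model_matrix(matrix(x, nrow = 1))[1, ]
}

#' Full-quadratic model matrix
#'
#' @param X Numeric matrix, n points by k factors (column names used for
#'   term labels when present).
#' @return n x p model matrix with named columns: `(Intercept)`, the linear
#'   terms, `a:b` interactions (i < j order) and `a^2` quadratics.
#' @export
quadratic_model_matrix <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  cols <- list("(Intercept)" = rep(1, nrow(X)))
  for (j in seq_len(k)) cols[[nm[j]]] <- X[, j]
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      cols[[paste0(nm[i], ":", nm[j])]] <- X[, i] * X[, j]
  }
  for (j in seq_len(k)) cols[[paste0(nm[j], "^2")]] <- X[, j]^2
  do.call(cbind, cols)
}

#' Fit a full-quadratic response-surface model
#'
#' Ordinary least squares on the full second-order polynomial in the design
#' factors, with the diagnostic suite conventional in response-surface
#' software: R-squared about the mean, adjusted R-squared, PRESS and
#' predicted R-squared from the leave-one-out hat-matrix shortcut, the
#' adequate-precision signal-to-noise ratio, the overall model F test and
#' per-term t tests.
#'
#' Diagnostics (R2, adjusted/predicted R2, F and t p-values) are invariant
#' to the coded/actual choice of scale; only the coefficients change.  The
#' conventional report quotes diagnostics from the coded fit and the
#' regression equation from the actual-units fit.
#'
#' @param design A `ccd_design` (or data.frame plus `factors`) containing
#'   the response column.
#' @param response Name of the response column.
#' @param factors List of [ccd_factor()]; defaults to the design attribute.
#' @param scale `"coded"` (default) or `"actual"` — the units the
#'   polynomial is expressed in.
#' @param terms Optional character vector of non-intercept term names to
#'   keep (reduced model); default is the full quadratic.
#' @return Object of class `rsm_model`: coefficients, `n`, `p`, residuals,
#'   `mse`, `r2`, `adj_r2`, `press`, `pred_r2`, `adequate_precision`,
#'   `model_f_p`, `term_p`, plus bookkeeping used by [predict.rsm_model()].
#' @examples
#' m <- fit_quadratic(flp_design(), "size_nm")
#' m$r2
#' @export
fit_quadratic <- function(design, response, factors = NULL,
                          scale = c("coded", "actual"), terms = NULL) {
  scale <- match.arg(scale)
  if (is.null(factors)) factors <- attr(design, "factors")
  if (is.null(factors))
    stop("factor definitions required (pass 'factors' or use a ccd_design)",
         call. = FALSE)
  if (!response %in% names(design))
    stop("response column '", response, "' not found", call. = FALSE)
  y <- design[[response]]
  if (!all(is.finite(y)))
    stop("response contains non-finite values", call. = FALSE)

  coded <- design_coded(design, factors)
  nm <- vapply(factors, `[[`, character(1), "name")
  Xs <- if (scale == "coded") coded else {
    a <- coded
    for (j in seq_along(factors)) a[, j] <- coded_to_actual(coded[, j], factors[[j]])
    a
  }
  colnames(Xs) <- nm
  MM <- quadratic_model_matrix(Xs)
  if (!is.null(terms)) {
    keep <- c("(Intercept)", terms)
    bad <- setdiff(keep, colnames(MM))
    if (length(bad))
      stop("unknown model term(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    MM <- MM[, keep, drop = FALSE]
  }
  n <- nrow(MM); p <- ncol(MM)
  if (n < p)
    stop("need at least ", p, " runs to fit ", p, " terms", call. = FALSE)

  qrX <- qr(MM)
  if (qrX$rank < p)
    stop("singular design: model matrix is rank-deficient (rank ",
         qrX$rank, " < ", p, " terms)", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0)
    stop("degenerate response: no variation about the mean (SST = 0)",
         call. = FALSE)

  beta <- qr.coef(qrX, y)
  fitted <- drop(MM %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  dof <- n - p
  mse <- if (dof > 0) sse / dof else NaN
  r2 <- 1 - sse / sst
  adj_r2 <- if (dof > 0) 1 - (1 - r2) * (n - 1) / dof else NaN

  XtXi <- chol2inv(qr.R(qrX))
  lev <- rowSums((MM %*% XtXi) * MM)
  if (any(lev >= 1 - 1e-12))
    stop("leverage-degenerate fit: some h_ii >= 1; PRESS undefined",
         call. = FALSE)
  press <- sum((res / (1 - lev))^2)
  pred_r2 <- 1 - press / sst

  # zero residual variance (exact interpolation up to rounding noise):
  # signal-to-noise and the t/F tests are undefined; report sentinels
  zero_resid <- !is.finite(mse) || mse <= 0 || sse <= 1e-12 * sst

  # adequate precision: predicted-signal range over average prediction sd
  adequate_precision <- if (!zero_resid)
    (max(fitted) - min(fitted)) / sqrt(p * mse / n) else Inf

  if (!zero_resid) {
    se <- sqrt(diag(XtXi) * mse)
    tval <- beta / se
    term_p <- 2 * stats::pt(abs(tval), df = dof, lower.tail = FALSE)
    fstat <- ((sst - sse) / (p - 1)) / mse
    model_f_p <- stats::pf(fstat, p - 1, dof, lower.tail = FALSE)
  } else {
    term_p <- stats::setNames(rep(NaN, p), colnames(MM))
    fstat <- NaN
    model_f_p <- NaN
  }

  structure(
    list(response = response, scale = scale, factors = factors,
         terms = colnames(MM), coefficients = stats::setNames(beta, colnames(MM)),
         n = n, p = p, fitted = fitted, residuals = res,
         mse = mse, sst = sst, r2 = r2, adj_r2 = adj_r2,
         press = press, pred_r2 = pred_r2,
         adequate_precision = adequate_precision,
         f_statistic = fstat, model_f_p = model_f_p,
         term_p = stats::setNames(as.numeric(term_p), colnames(MM)),
         leverages = lev),
    class = "rsm_model"
  )
}

#' Predict from a fitted response-surface model
#'
#' @param object An `rsm_model`.
#' @param newdata Matrix/data.frame of factor values — coded units by
#'   default, actual units with `units = "actual"`.  Columns in factor
#'   order (names are not required but honoured when present).
#' @param units Units `newdata` is expressed in.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_model <- function(object, newdata,
                              units = c("coded", "actual"), ...) {
  units <- match.arg(units)
  X <- as.matrix(newdata)
  nm <- vapply(object$factors, `[[`, character(1), "name")
  if (!is.null(colnames(X)) && all(nm %in% colnames(X)))
    X <- X[, nm, drop = FALSE]
  if (ncol(X) != length(nm))
    stop("'newdata' must have one column per factor", call. = FALSE)
  # move to the scale the model was fitted on
  conv <- function(from, to) {
    out <- X
    for (j in seq_along(nm)) {
      out[, j] <- if (from == "coded")
        coded_to_actual(X[, j], object$factors[[j]])
      else
        actual_to_coded(X[, j], object$factors[[j]])
    }
    out
  }
  if (units != object$scale) X <- conv(units, object$scale)
  colnames(X) <- nm
  MM <- quadratic_model_matrix(X)[, object$terms, drop = FALSE]
  drop(MM %*% object$coefficients)
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("Quadratic response-surface model for '%s' (%s units)\n",
              x$response, x$scale))
  cat(sprintf("  n = %d runs, p = %d terms\n", x$n, x$p))
  cat(sprintf("  R2 %.4f | adj R2 %.4f | pred R2 %.4f | adeq. precision %.4f\n",
              x$r2, x$adj_r2, x$pred_r2, x$adequate_precision))
  cat(sprintf("  model F p-value: %s\n", format.pval(x$model_f_p, digits = 3)))
  cat("\n", rsm_equation(x), "\n", sep = "")
  invisible(x)
}

#' Regression equation as text
#'
#' Formats the fitted polynomial the way formulation papers print it, e.g.
#' `size_nm = 290.92 - 1.28*fn_mM + ...`.
#'
#' @param model An `rsm_model`.
#' @param digits Coefficient digits (default 2, the usual print precision).
#' @return A single string.
#' @export
rsm_equation <- function(model, digits = 2) {
  b <- model$coefficients
  fmt <- function(v) formatC(abs(v), format = "f", digits = digits)
  out <- paste0(model$response, " = ", formatC(b[1], format = "f", digits = digits))
  for (i in seq_along(b)[-1]) {
    out <- paste0(out, if (b[i] < 0) " - " else " + ",
                  fmt(b[i]), "*", names(b)[i])
  }
  out
}

#' Export a fitted model as a plain list (JSON-ready)
#'
#' @param model An `rsm_model`.
#' @return Nested list of coefficients and diagnostics.
#' @export
rsm_report <- function(model) {
  list(response = model$response, scale = model$scale,
       n = model$n, p = model$p,
       coefficients = as.list(model$coefficients),
       diagnostics = list(r2 = model$r2, adj_r2 = model$adj_r2,
                          press = model$press, pred_r2 = model$pred_r2,
                          adequate_precision = model$adequate_precision,
                          mse = model$mse, model_f_p = model$model_f_p),
       term_p = as.list(model$term_p),
       equation = rsm_equation(model))
}
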