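#' Define a desirability goal for one response
#'
#' Derringer-style linear desirability without shape exponents.  For a
#' `maximize` goal, predictions at or below `y_min` score 0, at or above
#' `y_max` score 1, linear in between; `minimize` is the mirror image.
#'
#' @param response Response name the goal applies to.
#' @param direction `"maximize"` or `"minimize"`.
#' @param y_min,y_max Acceptability bounds; `y_min < y_max`.
#' @return Object of class `desirability_goal`.
#' @export
desirability_goal <- function(response, direction = c("maximize", "minimize"),
                              y_min, y_max) {
  direction <- match.arg(direction)
  if (!is.numeric(y_min) || !is.numeric(y_max) || y_min >= y_max)
    stop("invalid goal: need y_min < y_max", call. = FALSE)
  structure(list(response = response, direction = direction,
                 y_min = y_min, y_max = y_max),
            class = "desirability_goal")
}

#' Individual desirability of predicted responses
#'
#' @param y_hat Numeric vector of predicted response values.
#' @param goal A [desirability_goal()].
#' @return Values in `[0, 1]`.
#' @examples
#' g <- desirability_goal("ee", "maximize", 70, 95)
#' d_individual(c(70, 82.5, 95), g)  # 0, 0.5, 1
#' @export
d_individual <- function(y_hat, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  span <- goal$y_max - goal$y_min
  d <- if (goal$direction == "maximize")
    (y_hat - goal$y_min) / span
  else
    (goal$y_max - y_hat) / span
  pmin(pmax(d, 0), 1)
}

#' Overall desirability (geometric mean)
#'
#' @param d Numeric vector of individual desirabilities in `[0, 1]`.
#' @return `(prod(d))^(1/length(d))`; 0 whenever any component is 0.
#' @export
overall_desirability <- function(d) {
  if (length(d) == 0L) stop("empty desirability vector", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]", call. = FALSE)
  prod(d)^(1 / length(d))
}

#' Locate the maximum-desirability formulation
#'
#' Dense deterministic grid search over the coded factor box, refined by a
#' derivative-free local polish (Nelder-Mead, clamped to the box).  The
#' default region is the factorial cube `[-1, +1]^k`: the face-centered
#' optimum the study reports lies on cube faces, and predictions beyond the
#' factorial box extrapolate.
#'
#' @param models List of `rsm_model` objects, one per goal (same factors).
#' @param goals List of [desirability_goal()] matching `models` by position.
#' @param lower,upper Region bounds in coded units (scalar or length-k).
#' @param step Grid step in coded units (default 0.02).
#' @param polish Run the local refinement (default TRUE).
#' @return Object of class `desirability_optimum`: `coded` and `actual`
#'   factor settings, `predicted` responses, `d_individual`, `overall_D`,
#'   and `degenerate = TRUE` with the max-min-d grid point when D is 0
#'   everywhere.
#' @export
optimize_desirability <- function(models, goals, lower = -1, upper = 1,
                                  step = 0.02, polish = TRUE) {
  if (length(models) != length(goals))
    stop("need one goal per model", call. = FALSE)
  k <- length(models[[1]]$factors)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (any(lower >= upper)) stop("need lower < upper", call. = FALSE)

  grid_axes <- lapply(seq_len(k), function(j) seq(lower[j], upper[j], by = step))
  grid <- as.matrix(expand.grid(grid_axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- vapply(models[[1]]$factors, `[[`, character(1), "name")

  d_mat <- vapply(seq_along(models), function(i) {
    d_individual(predict(models[[i]], grid, units = "coded"), goals[[i]])
  }, numeric(nrow(grid)))
  D <- exp(rowMeans(log(pmax(d_mat, .Machine$double.xmin))))
  D[apply(d_mat == 0, 1, any)] <- 0

  best <- which.max(D)  # first-found in canonical grid order on ties
  degenerate <- D[best] <= 0
  if (degenerate) {
    # no feasible point: report the grid point maximizing the worst component
    best <- which.max(apply(d_mat, 1, min))
    warning("overall desirability is zero everywhere in the region",
            call. = FALSE)
  }
  x <- grid[best, ]

  obj <- function(z) {
    z <- pmin(pmax(z, lower), upper)
    d <- vapply(seq_along(models), function(i)
      d_individual(predict(models[[i]], matrix(z, nrow = 1),
                           units = "coded"), goals[[i]]), numeric(1))
    -overall_desirability(d)
  }
  if (polish && !degenerate) {
    opt <- stats::optim(x, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    cand <- pmin(pmax(opt$par, lower), upper)
    if (-obj(cand) >= D[best]) x <- cand
  }

  d_ind <- vapply(seq_along(models), function(i)
    d_individual(predict(models[[i]], matrix(x, nrow = 1),
                         units = "coded"), goals[[i]]), numeric(1))
  names(d_ind) <- vapply(goals, `[[`, character(1), "response")
  pred <- vapply(models, function(m)
    predict(m, matrix(x, nrow = 1), units = "coded"), numeric(1))
  names(pred) <- vapply(models, `[[`, character(1), "response")
  actual <- vapply(seq_len(k), function(j)
    coded_to_actual(x[j], models[[1]]$factors[[j]]), numeric(1))
  names(actual) <- colnames(grid)

  structure(list(coded = stats::setNames(as.numeric(x), colnames(grid)),
                 actual = actual, predicted = pred,
                 d_individual = d_ind,
                 overall_D = overall_desirability(d_ind),
                 degenerate = degenerate),
            class = "desirability_optimum")
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Desirability optimum (overall D =", format(x$overall_D, digits = 4), ")\n")
  cat("  coded: ", paste(sprintf("%s=%.3f", names(x$coded), x$coded),
                         collapse = ", "), "\n")
  cat("  actual:", paste(sprintf("%s=%.3f", names(x$actual), x$actual),
                         collapse = ", "), "\n")
  cat("  predicted:", paste(sprintf("%s=%.2f (d=%.3f)", names(x$predicted),
                                    x$predicted, x$d_individual),
                            collapse = ", "), "\n")
  if (x$degenerate) cat("  NOTE: D = 0 everywhere; reporting max-min-d point\n")
  invisible(x)
}

#' Goals from observed response ranges
#'
#' Convenience used throughout the workflow: acceptability bounds default to
#' each response's observed min/max over the design runs.
#'
#' @param design Data frame holding the response columns.
#' @param directions Named character vector, e.g.
#'   `c(size_nm = "minimize", ee_pct = "maximize")`.
#' @return List of [desirability_goal()].
#' @export
goals_from_ranges <- function(design, directions) {
  lapply(names(directions), function(r) {
    y <- design[[r]]
    desirability_goal(r, directions[[r]], min(y), max(y))
  })
}
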