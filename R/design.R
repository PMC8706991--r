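#' Define a design factor
#'
#' A factor is described by its center (coded level 0) and half-width (the
#' actual-unit change corresponding to one coded unit), so that
#' `actual = center + coded * half_width`.
#'
#' @param name Column name used for the factor in design tables.
#' @param center Actual value at coded level 0.
#' @param half_width Actual units per coded unit; must be `> 0`.
#' @param label Human-readable description (optional).
#' @param unit Unit label (optional).
#' @return An object of class `ccd_factor`.
#' @examples
#' fn <- ccd_factor("fn_mM", center = 3.25, half_width = 1.75, unit = "mM")
#' coded_to_actual(c(-1, 0, 1), fn)
#' @export
ccd_factor <- function(name, center, half_width, label = name, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(half_width) || length(half_width) != 1L || half_width <= 0)
    stop("'half_width' must be a single positive number", call. = FALSE)
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("'center' must be a single finite number", call. = FALSE)
  structure(
    list(name = name, center = as.numeric(center),
         half_width = as.numeric(half_width),
         label = label, unit = unit),
    class = "ccd_factor"
  )
}

#' @export
print.ccd_factor <- function(x, ...) {
  cat(sprintf("<ccd_factor> %s (%s): center %g, half-width %g %s\n",
              x$name, x$label, x$center, x$half_width, x$unit))
  invisible(x)
}

#' Axial distance of a rotatable central composite design
#'
#' A CCD is rotatable (prediction variance depends only on distance from the
#' design center) when the axial points sit at `alpha = (2^k)^(1/4)` coded
#' units, with `k` the number of factors.  For `k = 3` this is 1.682.
#'
#' @param k Number of factors; integer `>= 2`.
#' @return The axial distance in coded units.
#' @examples
#' rotatable_alpha(3)  # 1.6818
#' rotatable_alpha(2)  # sqrt(2)
#' @export
rotatable_alpha <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 2)
    stop("'k' must be a single integer >= 2", call. = FALSE)
  (2^k)^(1 / 4)
}

#' Convert coded factor levels to actual units
#'
#' @param code Numeric vector of coded levels.
#' @param factor A [ccd_factor()].
#' @return `factor$center + code * factor$half_width`.
#' @export
coded_to_actual <- function(code, factor) {
  stopifnot(inherits(factor, "ccd_factor"))
  factor$center + code * factor$half_width
}

#' Convert actual factor values to coded units
#'
#' Exact inverse of [coded_to_actual()].
#'
#' @param value Numeric vector in actual units.
#' @param factor A [ccd_factor()].
#' @return `(value - factor$center) / factor$half_width`.
#' @export
actual_to_coded <- function(value, factor) {
  stopifnot(inherits(factor, "ccd_factor"))
  (value - factor$center) / factor$half_width
}

#' Build a central composite design
#'
#' Generates the `2^k` factorial points (coded +/-1), `2k` axial points
#' (+/-alpha on one axis, 0 elsewhere) and `n_center` center replicates.
#' The canonical run order is deterministic: factorial points in binary
#' counting order (first factor fastest), axial points by factor (low then
#' high), then the center replicates.  `shuffle_seed` requests a seeded
#' random permutation of that order instead, mirroring the randomized run
#' sheets DoE software prints.
#'
#' @param factors List of [ccd_factor()] objects (length `k >= 2`).
#' @param n_center Number of center replicates (default 6).
#' @param alpha `"rotatable"` (default, resolves to `(2^k)^(1/4)`) or a
#'   positive number.
#' @param shuffle_seed Optional integer; permutes run order reproducibly.
#' @return A `data.frame` of class `ccd_design` with columns `run_id`,
#'   `is_center` and the actual-unit factor columns, plus attributes
#'   `factors`, `alpha` and `coded` (matrix of coded levels, one row per
#'   run).  Use [design_coded()] to retrieve the coded matrix.
#' @examples
#' f <- list(ccd_factor("a", 0, 1), ccd_factor("b", 10, 5))
#' nrow(ccd_design(f, n_center = 1))  # 4 + 4 + 1 = 9
#' @export
ccd_design <- function(factors, n_center = 6, alpha = "rotatable",
                       shuffle_seed = NULL) {
  if (!is.list(factors) || length(factors) < 2L ||
      !all(vapply(factors, inherits, logical(1), "ccd_factor")))
    stop("'factors' must be a list of >= 2 ccd_factor objects", call. = FALSE)
  k <- length(factors)
  if (identical(alpha, "rotatable")) {
    alpha <- rotatable_alpha(k)
  } else if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("'alpha' must be \"rotatable\" or a positive number", call. = FALSE)
  }
  if (length(n_center) != 1L || n_center < 0 || n_center != round(n_center))
    stop("'n_center' must be a nonnegative integer", call. = FALSE)

  # factorial core in binary counting order, first factor fastest
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -alpha
    axial[2 * j, j] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k)
  coded <- rbind(fact, axial, center)
  dimnames(coded) <- list(NULL, vapply(factors, `[[`, character(1), "name"))

  if (!is.null(shuffle_seed)) {
    ord <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(shuffle_seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      sample.int(nrow(coded))
    })
    coded <- coded[ord, , drop = FALSE]
  }

  actual <- coded
  for (j in seq_len(k)) actual[, j] <- coded_to_actual(coded[, j], factors[[j]])

  out <- data.frame(run_id = seq_len(nrow(coded)),
                    is_center = rowSums(coded != 0) == 0)
  out <- cbind(out, as.data.frame(actual))
  attr(out, "factors") <- factors
  attr(out, "alpha") <- alpha
  attr(out, "coded") <- coded
  class(out) <- c("ccd_design", "data.frame")
  out
}

#' Coded-level matrix of a design
#'
#' @param design A `ccd_design`, or any data.frame holding actual-unit factor
#'   columns (then `factors` must be supplied to code them).
#' @param factors List of [ccd_factor()]; defaults to the design's own.
#' @return Numeric matrix of coded levels, one column per factor.
#' @export
design_coded <- function(design, factors = NULL) {
  if (is.null(factors)) factors <- attr(design, "factors")
  if (!is.null(attr(design, "coded")) && is.null(factors))
    return(attr(design, "coded"))
  if (is.null(factors))
    stop("no factor definitions available to code the design", call. = FALSE)
  nm <- vapply(factors, `[[`, character(1), "name")
  missing <- setdiff(nm, names(design))
  if (length(missing))
    stop("design lacks factor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  coded <- vapply(seq_along(factors),
                  function(j) actual_to_coded(design[[nm[j]]], factors[[j]]),
                  numeric(nrow(design)))
  coded <- matrix(coded, ncol = length(factors), dimnames = list(NULL, nm))
  coded
}

#' @export
print.ccd_design <- function(x, ...) {
  k <- length(attr(x, "factors"))
  cat(sprintf("Central composite design: %d factors, %d runs (alpha = %.4f)\n",
              k, nrow(x), attr(x, "alpha")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read a design table as CSV
#'
#' Plain UTF-8 CSV with dot decimal separator.  `read_design_csv()` returns a
#' regular data.frame; attach factor definitions with `factors` to re-code it.
#'
#' @param design Data frame (typically a `ccd_design` with response columns).
#' @param path File path.
#' @param factors Optional list of [ccd_factor()] attached on read.
#' @return `read_design_csv`: a data.frame (a `ccd_design` when `factors`
#'   is given).
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, factors = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(factors)) {
    attr(out, "factors") <- factors
    attr(out, "coded") <- design_coded(out, factors)
    class(out) <- c("ccd_design", "data.frame")
  }
  out
}
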