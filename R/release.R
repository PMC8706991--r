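#' Release curve container
#'
#' Times (hours) and cumulative fraction released `CR = Mt/Me`, with the
#' dissolution-cell geometry carried along for provenance.
#'
#' @param times Strictly increasing sampling times (h), `>= 0`.
#' @param cr Cumulative fraction released at each time; small analytic
#'   overshoot above 1 (up to 1.05) is tolerated.
#' @param medium_volume,sample_volume,dose Optional geometry (mL, mL, ug).
#' @return data.frame of class `release_curve` with columns `time_h`, `cr`.
#' @export
release_curve <- function(times, cr, medium_volume = NULL,
                          sample_volume = NULL, dose = NULL) {
  if (length(times) != length(cr))
    stop("'times' and 'cr' lengths differ", call. = FALSE)
  if (any(diff(times) <= 0) || any(times < 0))
    stop("'times' must be nonnegative and strictly increasing", call. = FALSE)
  if (any(cr < 0 | cr > 1.05))
    stop("'cr' must lie in [0, 1.05]", call. = FALSE)
  out <- data.frame(time_h = as.numeric(times), cr = as.numeric(cr))
  attr(out, "medium_volume") <- medium_volume
  attr(out, "sample_volume") <- sample_volume
  attr(out, "dose") <- dose
  class(out) <- c("release_curve", "data.frame")
  out
}

# replacement-corrected cumulative mass for withdraw-and-replace sampling:
# Q_n = C_n * V + V_s * sum_{i<n} C_i
corrected_cumulative_mass <- function(conc, volume, sample_volume) {
  withdrawn_before <- c(0, cumsum(conc))[seq_along(conc)]
  conc * volume + sample_volume * withdrawn_before
}

#' Cumulative release from sampled concentrations
#'
#' Converts the concentrations measured in withdrawn aliquots into the
#' cumulative fraction released, correcting for the drug mass removed by
#' earlier withdrawals (each aliquot is replaced with fresh medium):
#' `Q_n = C_n * V_medium + V_sample * sum_{i<n} C_i`, `cr_n = Q_n / dose`.
#'
#' @param concentrations Measured concentrations (ug/mL), one per timepoint.
#' @param times Sampling times (h).
#' @param medium_volume Release medium volume (mL).
#' @param sample_volume Withdrawn aliquot volume (mL); must be smaller than
#'   `medium_volume`.
#' @param dose Total drug in the donor (ug).
#' @return A [release_curve()].
#' @examples
#' cumulative_release(2, times = 1, medium_volume = 20,
#'                    sample_volume = 1, dose = 100)$cr  # 0.40
#' @export
cumulative_release <- function(concentrations, times, medium_volume,
                               sample_volume, dose) {
  if (any(concentrations < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  if (sample_volume >= medium_volume)
    stop("'sample_volume' must be smaller than 'medium_volume'", call. = FALSE)
  if (dose <= 0) stop("'dose' must be positive", call. = FALSE)
  q <- corrected_cumulative_mass(concentrations, medium_volume, sample_volume)
  release_curve(times, q / dose, medium_volume, sample_volume, dose)
}

kinetic_models <- c("zero_order", "first_order", "korsmeyer_peppas", "higuchi")

# model curves, CR as a function of time in hours
kinetic_cr <- function(model, params, t) {
  switch(model,
    zero_order = params[["k0"]] * t,
    first_order = 1 - exp(-params[["k1"]] * t),
    korsmeyer_peppas = params[["k_kp"]] * t^params[["n"]],
    higuchi = params[["k_h"]] * sqrt(t),
    stop("unknown kinetic model: ", model, call. = FALSE))
}

#' Fit a drug-release kinetic model
#'
#' Least-squares fit of one of the four standard empirical release laws to a
#' cumulative-release curve: zero-order `CR = k0*t`, first-order
#' `CR = 1 - exp(-k1*t)`, Korsmeyer-Peppas `CR = k*t^n`, Higuchi
#' `CR = kH*sqrt(t)`.  Zero-order and Higuchi are linear through the origin
#' and solved in closed form; first-order and Korsmeyer-Peppas are
#' initialized from log-linear / log-log regression and refined by
#' Levenberg-Marquardt nonlinear least squares.
#'
#' @param curve A [release_curve()] (or data.frame with `time_h`, `cr`).
#' @param model One of `"zero_order"`, `"first_order"`,
#'   `"korsmeyer_peppas"`, `"higuchi"`.
#' @param fix_n For Korsmeyer-Peppas only: fix the release exponent (e.g.
#'   `fix_n = 0.5` reproduces the Higuchi fit exactly).
#' @return Object of class `kinetic_fit`: `model`, named `params`, `r2`,
#'   `fitted`.
#' @export
fit_kinetic <- function(curve, model = kinetic_models, fix_n = NULL) {
  model <- match.arg(model)
  t <- curve$time_h; y <- curve$cr
  pos <- t > 0
  if (sum(pos) < 3)
    stop("need at least 3 points with t > 0", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  r2_of <- function(fit) 1 - sum((y - fit)^2) / sst

  if (model == "zero_order") {
    k0 <- sum(t * y) / sum(t^2)
    params <- c(k0 = k0)
  } else if (model == "higuchi") {
    k_h <- sum(sqrt(t) * y) / sum(t)
    params <- c(k_h = k_h)
  } else if (model == "first_order") {
    # log-linear initialization on points clearly below complete release
    ok <- pos & y < 0.999
    k_init <- if (sum(ok) >= 2) {
      max(sum(t[ok] * (-log(1 - y[ok]))) / sum(t[ok]^2), 1e-6)
    } else 0.1
    fit <- tryCatch(
      minpack.lm::nlsLM(cr ~ 1 - exp(-k1 * time_h),
                        data = data.frame(time_h = t, cr = y),
                        start = list(k1 = k_init), lower = 1e-9,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      stop("first-order fit failed to converge (init k1 = ",
           signif(k_init, 4), ")", call. = FALSE)
    params <- c(k1 = unname(stats::coef(fit)[["k1"]]))
  } else { # korsmeyer_peppas
    if (!is.null(fix_n)) {
      k_kp <- sum(t^fix_n * y) / sum(t^(2 * fix_n))
      params <- c(k_kp = k_kp, n = fix_n)
    } else {
      # log-log initialization excludes t = 0 and cr = 0
      ok <- pos & y > 0
      if (sum(ok) >= 2) {
        ll <- stats::lm.fit(cbind(1, log(t[ok])), log(y[ok]))$coefficients
        start <- list(k_kp = max(exp(ll[1]), 1e-6), n = max(ll[2], 1e-3))
      } else start <- list(k_kp = 0.1, n = 0.5)
      fit <- tryCatch(
        minpack.lm::nlsLM(cr ~ k_kp * time_h^n,
                          data = data.frame(time_h = t[pos], cr = y[pos]),
                          start = start, lower = c(1e-9, 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit))
        stop("Korsmeyer-Peppas fit failed to converge", call. = FALSE)
      params <- stats::coef(fit)[c("k_kp", "n")]
    }
  }
  fitted <- kinetic_cr(model, as.list(params), t)
  structure(list(model = model, params = params, r2 = r2_of(fitted),
                 fitted = fitted, times = t),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s | %s | R2 = %.4f\n", x$model,
              paste(sprintf("%s = %.5g", names(x$params), x$params),
                    collapse = ", "), x$r2))
  invisible(x)
}

#' Fit all kinetic models and rank by goodness of fit
#'
#' @param curve A [release_curve()].
#' @return List of `kinetic_fit` objects ranked by decreasing R2, ties
#'   broken in favour of fewer parameters; class `kinetic_ranking`.
#' @export
select_kinetic_model <- function(curve) {
  fits <- list()
  errs <- character()
  for (m in kinetic_models) {
    f <- tryCatch(fit_kinetic(curve, m), error = function(e) e)
    if (inherits(f, "error")) errs <- c(errs, conditionMessage(f))
    else fits[[m]] <- f
  }
  if (length(fits) < 2)
    stop("kinetic model selection failed: ", paste(errs, collapse = "; "),
         call. = FALSE)
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  npar <- vapply(fits, function(f) length(f$params), numeric(1))
  fits <- fits[order(-r2, npar)]
  class(fits) <- "kinetic_ranking"
  fits
}

#' @export
print.kinetic_ranking <- function(x, ...) {
  cat("Kinetic model ranking (best first):\n")
  for (f in x) cat("  "); for (f in x) print(f)
  invisible(x)
}
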