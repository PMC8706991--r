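# evaluate expr with a temporary RNG state; leaves the caller's stream intact
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  eval.parent(substitute(expr))
}

#' Simulate responses over a design from a known quadratic surface
#'
#' Draws `y = quadratic_row(x) . beta + N(0, noise_sd^2)` independently per
#' run, emulating the data-generating structure a central composite design
#' assumes: a smooth second-order surface plus additive Gaussian measurement
#' noise, with center replicates differing only by their noise draws.
#'
#' @param design A `ccd_design`.
#' @param true_beta Named coefficient vector on the chosen scale; names as
#'   in [quadratic_model_matrix()] (terms not named are taken as 0; the
#'   intercept may be named `"(Intercept)"`).
#' @param noise_sd Gaussian noise SD in response units (default 0).
#' @param seed Optional integer; identical seed gives identical output, and
#'   the caller's RNG stream is left untouched.
#' @param response Name of the response column added (default `"y"`).
#' @param scale Scale `true_beta` is expressed on: `"coded"` (default) or
#'   `"actual"`.
#' @return The design with the simulated response column appended.
#' @export
simulate_design_responses <- function(design, true_beta, noise_sd = 0,
                                      seed = NULL, response = "y",
                                      scale = c("coded", "actual")) {
  scale <- match.arg(scale)
  factors <- attr(design, "factors")
  coded <- design_coded(design)
  X <- if (scale == "coded") coded else {
    a <- coded
    for (j in seq_along(factors)) a[, j] <- coded_to_actual(coded[, j], factors[[j]])
    a
  }
  colnames(X) <- vapply(factors, `[[`, character(1), "name")
  MM <- quadratic_model_matrix(X)
  beta <- stats::setNames(rep(0, ncol(MM)), colnames(MM))
  bad <- setdiff(names(true_beta), names(beta))
  if (length(bad))
    stop("unknown term(s) in 'true_beta': ", paste(bad, collapse = ", "),
         call. = FALSE)
  beta[names(true_beta)] <- true_beta
  mu <- drop(MM %*% beta)
  eps <- if (noise_sd > 0)
    with_local_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  else rep(0, length(mu))
  design[[response]] <- mu + eps
  design
}

#' Simulate withdraw-and-replace sampling of a release experiment
#'
#' Mass-balance model of a well-mixed dissolution medium sampled with
#' aliquot replacement: at each sampling time the true released fraction
#' follows the chosen kinetic law; the concentration found in the medium
#' accounts for drug already carried away by earlier aliquots (each aliquot
#' replaced by fresh medium); optional Gaussian measurement noise is then
#' applied to the observed concentrations.
#'
#' The emitted concentrations are exactly inverted by
#' [cumulative_release()]: with `noise_sd = 0` the reconstructed `cr` equals
#' the true released fraction to machine precision.
#'
#' @param model Kinetic law generating the truth (see [fit_kinetic()]).
#' @param params Named parameters of the law (e.g. `list(k1 = 0.25)`).
#' @param times Sampling times (h), strictly increasing, `> 0`.
#' @param medium_volume,sample_volume,dose Cell geometry (mL, mL, ug).
#' @param noise_sd Measurement noise SD on concentrations (ug/mL).
#' @param seed Optional integer for reproducible noise.
#' @return List: `times`, `concentrations` (observed, ug/mL), `true_cr`
#'   (ground-truth released fraction), `curve` (the observed
#'   [release_curve()] reconstructed via [cumulative_release()]).
#' @export
simulate_release_sampling <- function(model, params, times,
                                      medium_volume = 20, sample_volume = 1,
                                      dose = 930, noise_sd = 0, seed = NULL) {
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  true_cr <- kinetic_cr(model, as.list(params), times)
  if (any(true_cr < 0 | true_cr > 1.05))
    stop("kinetic law yields released fractions outside [0, 1.05]",
         call. = FALSE)
  n <- length(times)
  conc <- numeric(n)
  removed <- 0  # drug mass carried away by earlier aliquots
  for (i in seq_len(n)) {
    conc[i] <- (dose * true_cr[i] - removed) / medium_volume
    removed <- removed + conc[i] * sample_volume
  }
  observed <- if (noise_sd > 0)
    pmax(conc + with_local_seed(seed, stats::rnorm(n, 0, noise_sd)), 0)
  else conc
  curve <- cumulative_release(observed, times, medium_volume,
                              sample_volume, dose)
  list(times = times, concentrations = observed, true_cr = true_cr,
       curve = curve)
}
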