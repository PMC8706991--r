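# shared generators for property-style tests

make_factors <- function(k, centers = NULL, widths = NULL) {
  if (is.null(centers)) centers <- seq_len(k) * 10
  if (is.null(widths)) widths <- rep(2, k)
  lapply(seq_len(k), function(j)
    ccd_factor(paste0("f", j), centers[j], widths[j]))
}

study_factors <- function() flp_factors()

# random full-quadratic coefficient vector on the coded scale
random_beta <- function(k, intercept = 50) {
  fnames <- paste0("f", seq_len(k))
  nm <- colnames(quadratic_model_matrix(
    matrix(0, 1, k, dimnames = list(NULL, fnames))))
  stats::setNames(c(intercept, stats::runif(length(nm) - 1, -5, 5)), nm)
}

study_timepoints <- function() c(1, 2, 4, 6, 8, 12, 24, 48)

# additive gaussian noise on a cumulative-release curve, clipped to [0, 1.05]
noisy_cr <- function(cr, sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pmin(pmax(cr + stats::rnorm(length(cr), 0, sd), 0), 1.05)
}
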