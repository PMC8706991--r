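#' Entrapment efficiency
#'
#' `EE(%) = 100 * (total - free) / total`: the share of drug incorporated in
#' the vesicles, from the total drug in the preparation and the free
#' (unentrapped) drug measured in the supernatant.
#'
#' @param total_drug Total drug (> 0); any mass/concentration unit.
#' @param free_drug Unentrapped drug, same unit, in `[0, total_drug]`.
#' @return Percentage in `[0, 100]`.
#' @export
entrapment_efficiency <- function(total_drug, free_drug) {
  if (any(total_drug <= 0)) stop("'total_drug' must be positive", call. = FALSE)
  if (any(free_drug < 0) || any(free_drug > total_drug))
    stop("'free_drug' must lie in [0, total_drug]", call. = FALSE)
  100 * (total_drug - free_drug) / total_drug
}

#' Drug loading capacity
#'
#' `DL(%) = 100 * entrapped / (entrapped + total_lipid)` with
#' `entrapped = total_drug - free_drug`.  Drug and lipid amounts must be
#' expressed in a common unit for the ratio to be meaningful.
#'
#' @inheritParams entrapment_efficiency
#' @param total_lipid Carrier lipid amount (> 0), same unit as the drug.
#' @return Percentage in `[0, 100)`.
#' @export
drug_loading <- function(total_drug, free_drug, total_lipid) {
  if (any(total_lipid <= 0)) stop("'total_lipid' must be positive", call. = FALSE)
  entrapped <- total_drug - free_drug
  if (any(total_drug <= 0)) stop("'total_drug' must be positive", call. = FALSE)
  if (any(free_drug < 0) || any(entrapped < 0))
    stop("'free_drug' must lie in [0, total_drug]", call. = FALSE)
  100 * entrapped / (entrapped + total_lipid)
}

#' Franz-cell permeation series
#'
#' Receptor-compartment concentrations sampled over time from a Franz
#' diffusion cell, with withdraw-and-replace aliquots.
#'
#' @param times Strictly increasing sampling times (h).
#' @param receptor_concentrations Measured receptor concentrations (ug/mL).
#' @param receptor_volume Receptor volume (mL), `> 0`.
#' @param sample_volume Withdrawn aliquot (mL), default 0.5; must be smaller
#'   than `receptor_volume`.
#' @param diffusion_area Exposed skin area (cm2), default 3.5.
#' @param condition `"unblocked"` (follicles open) or `"blocked"`.
#' @return data.frame of class `permeation_series`.
#' @export
permeation_series <- function(times, receptor_concentrations, receptor_volume,
                              sample_volume = 0.5, diffusion_area = 3.5,
                              condition = c("unblocked", "blocked")) {
  condition <- match.arg(condition)
  if (length(times) != length(receptor_concentrations))
    stop("'times' and concentrations lengths differ", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(receptor_concentrations < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  if (receptor_volume <= 0 || diffusion_area <= 0)
    stop("volumes and area must be positive", call. = FALSE)
  if (sample_volume >= receptor_volume)
    stop("'sample_volume' must be smaller than 'receptor_volume'", call. = FALSE)
  out <- data.frame(time_h = as.numeric(times),
                    conc_ug_ml = as.numeric(receptor_concentrations))
  attr(out, "receptor_volume") <- receptor_volume
  attr(out, "sample_volume") <- sample_volume
  attr(out, "diffusion_area") <- diffusion_area
  attr(out, "condition") <- condition
  class(out) <- c("permeation_series", "data.frame")
  out
}

#' Cumulative amount permeated per unit area
#'
#' Same replacement correction as [cumulative_release()], normalized by the
#' diffusion area: `Q_n = C_n * V_receptor + V_sample * sum_{i<n} C_i`,
#' reported as `Q_n / A` in ug/cm2.
#'
#' @param series A [permeation_series()].
#' @return Numeric vector (ug/cm2), one value per timepoint.
#' @export
cumulative_permeation <- function(series) {
  stopifnot(inherits(series, "permeation_series"))
  q <- corrected_cumulative_mass(series$conc_ug_ml,
                                 attr(series, "receptor_volume"),
                                 attr(series, "sample_volume"))
  q / attr(series, "diffusion_area")
}

#' Transfollicular cumulation
#'
#' Difference between full-skin and follicle-blocked cumulation, pairwise by
#' timepoint: the follicular-shunt contribution to permeation.  Unit
#' agnostic — apply it to percentages or to ug/cm2 series alike.
#'
#' @param full Cumulation through unblocked (full) skin.
#' @param blocked Cumulation through follicle-blocked skin, same unit.
#' @param times,times_blocked Optional timepoint grids; when given they must
#'   match exactly (alignment check).
#' @return `full - blocked`, elementwise.
#' @export
transfollicular_cumulation <- function(full, blocked, times = NULL,
                                       times_blocked = times) {
  if (length(full) != length(blocked))
    stop("'full' and 'blocked' series differ in length", call. = FALSE)
  if (!is.null(times) && !isTRUE(all.equal(times, times_blocked)))
    stop("timepoint grids of the two series do not align", call. = FALSE)
  full - blocked
}

#' Draize primary irritation index
#'
#' Mean of all recorded erythema and edema scores:
#' `PII = sum_t(erythema_t + edema_t) / (2 * T)` over the `T` observation
#' timepoints, rounded to 2 decimals, then banded into the conventional
#' irritation classes: 0-0.4 none, 0.5-1.9 slight, 2.0-4.9 moderate,
#' 5.0-8.0 severe.
#'
#' @param observations data.frame with columns `timepoint_h`, `erythema`,
#'   `edema`; scores must lie in the Draize range `[0, 4]`.
#' @return List with `pii` (2-dp), `class` label, and `pii_raw`.
#' @examples
#' obs <- data.frame(timepoint_h = c(1, 24, 48, 72),
#'                   erythema = c(1.5, 1.5, 1.25, 1), edema = 0)
#' draize_pii(obs)$pii  # 0.66
#' @export
draize_pii <- function(observations) {
  req <- c("timepoint_h", "erythema", "edema")
  if (!all(req %in% names(observations)))
    stop("observations need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(observations) < 1)
    stop("need at least one observation", call. = FALSE)
  if (anyDuplicated(observations$timepoint_h))
    stop("timepoints must be distinct", call. = FALSE)
  sc <- c(observations$erythema, observations$edema)
  if (any(sc < 0 | sc > 4))
    stop("Draize scores must lie in [0, 4]", call. = FALSE)
  pii_raw <- sum(sc) / (2 * nrow(observations))
  pii <- round(pii_raw, 2)
  list(pii = pii, class = draize_class(pii), pii_raw = pii_raw)
}

#' @rdname draize_pii
#' @param pii A primary irritation index value in `[0, 8]`.
#' @export
draize_class <- function(pii) {
  vapply(pii, function(v) {
    if (v < 0.5) "No irritation"
    else if (v < 2.0) "Slight irritation"
    else if (v < 5.0) "Moderate irritation"
    else "Severe irritation"
  }, character(1))
}

#' PII table for every group of a Draize score grid
#'
#' @param scores Long data.frame `group, timepoint_h, erythema, edema`
#'   (e.g. [flp_draize()]).
#' @return data.frame `group, pii, class`.
#' @export
draize_pii_table <- function(scores) {
  groups <- unique(scores$group)
  res <- lapply(groups, function(g) {
    r <- draize_pii(scores[scores$group == g, ])
    data.frame(group = g, pii = r$pii, class = r$class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
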