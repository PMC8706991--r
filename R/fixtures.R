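#' Packaged fixtures from the source formulation study
#'
#' Verbatim transcriptions of the printed tables of the proniosome
#' formulation study this package re-implements: the three factor
#' definitions with their coded-level anchors, the 20-run central composite
#' design matrix with measured responses (vesicle size, entrapment
#' efficiency, drug loading; run means and SDs of triplicates), and the
#' rabbit skin-irritation (Draize) score grid.  Printed values are preserved
#' exactly as published, including the duplicated center rows and the
#' 56.81/56.82 rounding wobble of the cholesterol axial point.
#'
#' @return
#' `flp_factors()`: list of three [ccd_factor()] objects (finasteride mM,
#' total lipid mM, cholesterol %).
#'
#' `flp_design()`: `ccd_design` data.frame of 20 runs with response columns
#' `size_nm`, `ee_pct`, `dl_pct` (and their `*_sd` companions).
#'
#' `flp_draize()`: long data.frame `group, timepoint_h, erythema, edema`.
#' @examples
#' d <- flp_design()
#' range(d$size_nm)  # 220.20 .. 346.00 nm
#' @export
flp_factors <- function() {
  tab <- utils::read.csv(system.file("extdata", "flp_factors.csv",
                                     package = "pronioptim"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    ccd_factor(tab$name[i], tab$center[i], tab$half_width[i],
               label = tab$label[i], unit = tab$unit[i]))
}

#' @rdname flp_factors
#' @export
flp_design <- function() {
  path <- system.file("extdata", "flp_design.csv", package = "pronioptim")
  read_design_csv(path, factors = flp_factors())
}

#' @rdname flp_factors
#' @export
flp_draize <- function() {
  utils::read.csv(system.file("extdata", "draize_scores.csv",
                              package = "pronioptim"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}
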