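## Small closed-form helpers for the acquisition design arithmetic:
## microfluidic flow speed, solvent bookkeeping of the dilution series,
## and the size of the acquisition campaign.

#' Mean flow speed in a rectangular microchannel
#'
#' `speed = volumetric rate / cross-section`; with the default design
#' (2.75 mL/min through a 100 um x 44 um channel) the mean speed is
#' about 10 m/s.
#'
#' @param flow_rate_mL_min total volumetric flow rate (mL/min).
#' @param width_um,height_um channel cross-section (micrometres).
#' @return mean flow speed in m/s.
#' @examples
#' flow_speed(2.75, 100, 44)
#' @export
flow_speed <- function(flow_rate_mL_min, width_um, height_um) {
  stopifnot(flow_rate_mL_min > 0, width_um > 0, height_um > 0)
  q <- flow_rate_mL_min * 1e-6 / 60          # m^3/s
  a <- width_um * 1e-6 * height_um * 1e-6    # m^2
  q / a
}

#' Solvent fraction after diluting a stock to a working concentration
#'
#' Diluting a stock of concentration `stock_M` to `final_M` requires a
#' volume fraction `final_M / stock_M` of the stock solution, which is the
#' carried-over solvent (e.g. DMSO) fraction. A 1 mM stock diluted to
#' 10 uM gives 1% v/v.
#'
#' @param stock_M stock concentration (molar).
#' @param final_M final concentration (molar); must not exceed `stock_M`.
#' @return solvent volume fraction in percent.
#' @examples
#' solvent_fraction_pct(1e-3, 1e-5)  # 1
#' @export
solvent_fraction_pct <- function(stock_M, final_M) {
  stopifnot(stock_M > 0, final_M > 0, final_M <= stock_M)
  100 * final_M / stock_M
}

#' Total image count of an acquisition campaign
#'
#' @param per_condition images per condition.
#' @param n_doses treated concentrations.
#' @param n_controls negative-control groups per experiment (counted as
#'   conditions).
#' @param n_durations treatment durations.
#' @param n_repeats experimental repeats.
#' @return total number of images.
#' @examples
#' study_image_count(10000, 5)  # 240000
#' @export
study_image_count <- function(per_condition, n_doses, n_controls = 1,
                              n_durations = 2, n_repeats = 2) {
  per_condition * (n_doses + n_controls) * n_durations * n_repeats
}
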