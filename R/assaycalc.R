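# Wet-lab arithmetic mirrors: qPCR ddCT relative quantification and
# percent-viability normalization against vehicle controls.

#' Relative fold change by the 2^-ddCT method
#'
#' `FC = 2^-[(Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)]`.
#' Replicate vectors are averaged on the Ct scale before the difference
#' (standard practice).
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values
#'   (scalars or replicate vectors).
#' @return list(fold_change, ddct).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) stop_sf("Ct values must be finite")
  ddct <- (mean(ct_target_case) - mean(ct_ref_case)) -
          (mean(ct_target_ctrl) - mean(ct_ref_ctrl))
  list(fold_change = 2^(-ddct), ddct = ddct)
}

#' Percent viability against vehicle controls
#'
#' `100 * mean(treated) / mean(vehicle)` with the replicate standard
#' deviation of the treated wells reported on the same percent scale.
#'
#' @param treated_readouts numeric replicate read-outs for one dose.
#' @param vehicle_readouts numeric replicate read-outs of the vehicle-only
#'   control wells.
#' @return list(percent, sd_percent, n).
#' @export
percent_viability <- function(treated_readouts, vehicle_readouts) {
  if (!length(treated_readouts) || !length(vehicle_readouts)) stop_sf("empty read-outs")
  vm <- mean(vehicle_readouts)
  if (!is.finite(vm) || vm <= 0) stop_sf("vehicle mean must be positive")
  list(percent = 100 * mean(treated_readouts) / vm,
       sd_percent = if (length(treated_readouts) > 1)
         100 * stats::sd(treated_readouts) / vm else NA_real_,
       n = length(treated_readouts))
}
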