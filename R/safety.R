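#' ANSI skin maximum-permissible-exposure calculator
#'
#' Implements the ANSI Z136.1 skin-exposure rules for the 700-1050 nm
#' wavelength band used to justify fast-scan laser parameters: the
#' single-pulse fluence limit, the extended-exposure limit for an
#' illumination period `t`, and the per-pulse limit implied by dividing
#' the exposure limit over the pulses fired during the scan.
#'
#' @param wavelength_nm Wavelength in nm, in \[700, 1050\].
#' @param t_s Exposure (scan) duration in s (> 0).
#' @param prr_hz Pulse repetition rate in Hz.
#' @name mpe
#' @examples
#' mpe_single_pulse(816)           # ~34.12 mJ/cm2
#' mpe_exposure(816, 1.5)          # ~2.08 J/cm2 (prints as 2.07 truncated)
#' mpe_per_pulse_in_scan(816, 0.3, 2000)  # ~2.31 mJ/cm2
NULL

check_wavelength <- function(wavelength_nm) {
  if (wavelength_nm < 700 || wavelength_nm > 1050)
    stop("wavelength must be in [700, 1050] nm for these skin-MPE rules")
}

ansi_ca <- function(wavelength_nm) 10^(2 * (wavelength_nm - 700) / 1000)

#' @rdname mpe
#' @return `mpe_single_pulse`: single-pulse skin limit,
#'   `20 * 10^(2(lambda-700)/1000)` in mJ/cm2.
#' @export
mpe_single_pulse <- function(wavelength_nm) {
  check_wavelength(wavelength_nm)
  20 * ansi_ca(wavelength_nm)
}

#' @rdname mpe
#' @return `mpe_exposure`: extended-exposure limit,
#'   `1.1 * 10^(2(lambda-700)/1000) * t^0.25` in J/cm2.
#' @export
mpe_exposure <- function(wavelength_nm, t_s) {
  check_wavelength(wavelength_nm)
  stopifnot(t_s > 0)
  1.1 * ansi_ca(wavelength_nm) * t_s^0.25
}

#' @rdname mpe
#' @return `mpe_per_pulse_in_scan`: the exposure limit divided by the
#'   pulse count `t * prr`, in mJ/cm2 per pulse.
#' @export
mpe_per_pulse_in_scan <- function(wavelength_nm, t_s, prr_hz) {
  stopifnot(prr_hz > 0)
  if (t_s * prr_hz < 1) stop("fewer than one pulse in the exposure window")
  1000 * mpe_exposure(wavelength_nm, t_s) / (t_s * prr_hz)
}

#' Check a laser exposure against the ANSI skin limits
#'
#' Compliant when the per-pulse fluence does not exceed (boundary
#' inclusive) both the single-pulse limit and the per-pulse limit implied
#' by the scan-duration exposure limit.
#'
#' @inheritParams mpe
#' @param fluence_mj_cm2 Delivered per-pulse fluence in mJ/cm2.
#' @return A `pat_mpe` list: `compliant` flag, both limits, the binding
#'   limit, and the safety margin (limit / fluence).
#' @examples
#' check_compliance(816, 0.3, 2000, 0.17)$compliant  # TRUE
#' @export
check_compliance <- function(wavelength_nm, t_s, prr_hz, fluence_mj_cm2) {
  stopifnot(fluence_mj_cm2 >= 0)
  single <- mpe_single_pulse(wavelength_nm)
  per_pulse <- mpe_per_pulse_in_scan(wavelength_nm, t_s, prr_hz)
  lim <- min(single, per_pulse)
  structure(list(compliant = fluence_mj_cm2 <= lim,
                 single_pulse_limit = single,
                 per_pulse_scan_limit = per_pulse,
                 exposure_limit_j_cm2 = mpe_exposure(wavelength_nm, t_s),
                 binding_limit = lim,
                 fluence = fluence_mj_cm2,
                 margin = if (fluence_mj_cm2 > 0) lim / fluence_mj_cm2
                          else Inf),
            class = "pat_mpe")
}

#' @export
print.pat_mpe <- function(x, ...) {
  cat(sprintf("<pat_mpe> %s: fluence %.3g mJ/cm2 vs limit %.3g mJ/cm2 (margin %.2gx)\n",
              if (x$compliant) "COMPLIANT" else "NON-COMPLIANT",
              x$fluence, x$binding_limit, x$margin))
  cat(sprintf("  single-pulse limit %.2f mJ/cm2; exposure limit %.2f J/cm2; per-pulse-in-scan %.2f mJ/cm2\n",
              x$single_pulse_limit, x$exposure_limit_j_cm2,
              x$per_pulse_scan_limit))
  invisible(x)
}
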