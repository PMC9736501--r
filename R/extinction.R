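# Hemoglobin extinction coefficients for the modified Beer-Lambert law.

#' Hemoglobin extinction coefficients
#'
#' Returns base-10 molar extinction coefficients (cm^-1 mM^-1) of HbO2 and
#' HbR at the requested wavelengths, from the versioned literature table
#' shipped with the package (linear interpolation between tabulated
#' wavelengths).
#'
#' @param wavelengths numeric vector of wavelengths in nm.
#' @return matrix with one row per wavelength and columns `eps_hbo2`,
#'   `eps_hbr`.
#' @export
extinction_coefficients <- function(wavelengths) {
  tab <- utils::read.delim(
    system.file("extdata", "extinction_coefficients.tsv",
                package = "fnirspipe", mustWork = TRUE),
    comment.char = "#")
  rng <- range(tab$wavelength_nm)
  bad <- wavelengths < rng[1] | wavelengths > rng[2]
  assert(!any(bad), "fp_unsupported_data",
         "no extinction data for wavelength %g nm (table covers %g-%g nm)",
         wavelengths[which(bad)[1]], rng[1], rng[2])
  cbind(
    eps_hbo2 = stats::approx(tab$wavelength_nm, tab$eps_hbo2, wavelengths)$y,
    eps_hbr  = stats::approx(tab$wavelength_nm, tab$eps_hbr, wavelengths)$y)
}

# 2x2 MBLL system matrix mapping concentration changes (mM) to natural-log
# optical density at the two wavelengths: OD(lambda) =
# ln(10) * [eps_hbo2, eps_hbr](lambda) * d_cm * DPF(lambda) %*% c(dHbO2, dHbR)
mbll_matrix <- function(wavelengths, distance_mm, dpf) {
  eps <- extinction_coefficients(wavelengths)
  E <- log(10) * eps * (distance_mm / 10) * dpf
  assert(abs(det(E)) > 1e-10, "fp_validation",
         "extinction matrix is singular (wavelengths too close)")
  E
}
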