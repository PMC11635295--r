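#' Optical model for the modified Beer-Lambert conversion
#'
#' Bundles the quantities needed to convert optical-density changes at two
#' wavelengths into hemoglobin concentration changes: molar extinction
#' coefficients of HbO and HbR at each wavelength, the differential
#' pathlength factor (DPF) and the source-detector separation.
#'
#' The shipped default extinction table (cm^-1 per uM) for 730 / 850 nm is a
#' standard literature compilation; because functional connectivity and all
#' graph metrics are invariant to a channel-wise positive linear rescaling of
#' the concentration series, the downstream results do not depend on the
#' absolute calibration of this table.  Concentrations are reported as
#' relative changes in uM with a partial-volume factor of 1.
#'
#' @param wavelengths Numeric pair of wavelengths in nm.
#' @param extinction 2x2 matrix, rows = wavelengths, columns = c(HbO, HbR),
#'   units cm^-1 uM^-1.
#' @param dpf Differential pathlength factor, recycled to one value per
#'   wavelength (default 6.0 for both).
#' @param separation Source-detector separation in cm (default 3.0).
#' @return An object of class `optical_model`.
#' @examples
#' om <- optical_model()
#' om$extinction
#' @export
optical_model <- function(wavelengths = c(730, 850),
                          extinction = default_extinction(wavelengths),
                          dpf = c(6.0, 6.0),
                          separation = 3.0) {
  stopifnot(length(wavelengths) == 2L, all(wavelengths > 0))
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2L, 2L)))
    stop("extinction must be a 2x2 matrix (wavelength x chromophore)")
  dpf <- rep_len(as.numeric(dpf), 2L)
  if (any(dpf <= 0)) stop("dpf must be positive")
  if (length(separation) != 1L || separation <= 0)
    stop("separation must be a single positive length in cm")
  # forward matrix M: dOD = M %*% c(dHbO, dHbR)
  m <- extinction * dpf * separation
  if (abs(det(m)) < 1e-12 * prod(pmax(abs(m[1, ]), abs(m[2, ]))) ||
      !is.finite(rcond(m)) || rcond(m) < 1e-12)
    stop("extinction system is singular: the two wavelengths do not separate HbO and HbR")
  dimnames(m) <- list(paste0("wl", wavelengths), c("HbO", "HbR"))
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, separation = separation, forward = m),
            class = "optical_model")
}

#' Default extinction coefficients
#'
#' @param wavelengths Wavelength pair; the shipped table covers 730 and
#'   850 nm.
#' @return 2x2 matrix of extinction coefficients in cm^-1 uM^-1
#'   (rows = wavelengths, cols = HbO, HbR).
#' @export
default_extinction <- function(wavelengths = c(730, 850)) {
  table <- rbind(
    `730` = c(HbO = 3.90e-4, HbR = 1.102e-3),
    `850` = c(HbO = 1.058e-3, HbR = 6.91e-4)
  )
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(table)))
    stop("no shipped extinction values for wavelengths ",
         paste(setdiff(key, rownames(table)), collapse = ", "),
         " nm; supply an extinction matrix explicitly")
  out <- table[key, , drop = FALSE]
  rownames(out) <- paste0("wl", wavelengths)
  out
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model:", paste(x$wavelengths, collapse = "/"), "nm, DPF",
      paste(x$dpf, collapse = "/"), ", separation", x$separation, "cm\n")
  print(x$extinction)
  invisible(x)
}
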