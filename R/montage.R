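#' Standard 32-channel montage
#'
#' The 32-electrode layout of the extended 10-20 system used by common
#' high-density affective-EEG recordings, with 2-D azimuthal-projection scalp
#' coordinates on the unit head disk (x = right, y = front, Cz at origin).
#' The central row C3, Cz, C4 sits on y = 0.
#'
#' @return data.frame with columns \code{name}, \code{x}, \code{y}.
#' @export
standardMontage <- function() {
  m <- matrix(c(
    -0.309,  0.951,   # Fp1
    -0.340,  0.800,   # AF3
    -0.809,  0.588,   # F7
    -0.390,  0.550,   # F3
    -0.280,  0.270,   # FC1
    -0.730,  0.290,   # FC5
    -1.000,  0.000,   # T7
    -0.500,  0.000,   # C3
    -0.280, -0.270,   # CP1
    -0.730, -0.290,   # CP5
    -0.809, -0.588,   # P7
    -0.390, -0.550,   # P3
     0.000, -0.500,   # Pz
    -0.340, -0.800,   # PO3
    -0.309, -0.951,   # O1
     0.000, -1.000,   # Oz
     0.309, -0.951,   # O2
     0.340, -0.800,   # PO4
     0.390, -0.550,   # P4
     0.809, -0.588,   # P8
     0.730, -0.290,   # CP6
     0.280, -0.270,   # CP2
     0.500,  0.000,   # C4
     1.000,  0.000,   # T8
     0.730,  0.290,   # FC6
     0.280,  0.270,   # FC2
     0.390,  0.550,   # F4
     0.809,  0.588,   # F8
     0.340,  0.800,   # AF4
     0.309,  0.951,   # Fp2
     0.000,  0.500,   # Fz
     0.000,  0.000),  # Cz
    ncol = 2, byrow = TRUE)
  data.frame(
    name = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1",
             "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4",
             "P8", "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8",
             "AF4", "Fp2", "Fz", "Cz"),
    x = m[, 1], y = m[, 2], stringsAsFactors = FALSE)
}

#' Names of the centrally located channels
#'
#' The central electrode row whose beta-band amplitude the synthetic
#' generator links to the arousal latent.
#' @return character vector.
#' @export
centralChannels <- function() c("C3", "Cz", "C4")

#' EEG band edges (Hz)
#'
#' theta 4-7, alpha 7-13, beta 13-30; the gamma band is deliberately
#' excluded from all analyses.
#' @return named list of length-2 numeric vectors.
#' @export
eegBands <- function() list(theta = c(4, 7), alpha = c(7, 13), beta = c(13, 30))
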