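#' Extinction matrix for dual-wavelength hemoglobin spectroscopy
#'
#' Bundles the molar extinction coefficients of deoxyhemoglobin (HbD) and
#' oxyhemoglobin (HbO) at the two measurement wavelengths (760 and 850 nm)
#' together with the optical path length. The 2x2 matrix
#' `[[eps_hbd_760, eps_hbo_760], [eps_hbd_850, eps_hbo_850]]` maps chromophore
#' concentration changes to optical-density changes (modified Beer-Lambert
#' law) and must be invertible so that the converse mapping exists.
#'
#' Default coefficients are the values tabulated in the Prahl compilation of
#' hemoglobin absorption spectra, in cm^-1 M^-1. Concentrations throughout
#' the package are expressed in micromolar (uM), so the forward model scales
#' by 1e-6 internally.
#'
#' @param eps_hbd_760,eps_hbo_760 Extinction coefficients at 760 nm
#'   (cm^-1 M^-1).
#' @param eps_hbd_850,eps_hbo_850 Extinction coefficients at 850 nm
#'   (cm^-1 M^-1).
#' @param path_length_cm Differential path length in cm (default 1).
#'
#' @return An object of class `extinction_matrix`: a list with the 2x2
#'   matrix `E` (rows = wavelengths 760, 850; columns = chromophores HbD,
#'   HbO) and `path_length_cm`.
#' @examples
#' em <- extinction_matrix()
#' em$E
#' @export
extinction_matrix <- function(eps_hbd_760 = 1548.52, eps_hbo_760 = 586.0,
                              eps_hbd_850 = 691.32, eps_hbo_850 = 1058.0,
                              path_length_cm = 1.0) {
  eps <- c(eps_hbd_760, eps_hbo_760, eps_hbd_850, eps_hbo_850)
  if (!all(is.finite(eps)) || any(eps <= 0)) {
    stop("all extinction coefficients must be finite and positive")
  }
  if (!is.finite(path_length_cm) || path_length_cm <= 0) {
    stop("path_length_cm must be positive")
  }
  E <- matrix(eps, nrow = 2, byrow = TRUE,
              dimnames = list(c("760", "850"), c("hbd", "hbo")))
  if (abs(det(E)) < .Machine$double.eps * max(abs(E))^2) {
    stop("extinction matrix is singular; chromophore spectra must differ ",
         "between wavelengths")
  }
  structure(list(E = E, path_length_cm = path_length_cm),
            class = "extinction_matrix")
}

#' @export
print.extinction_matrix <- function(x, ...) {
  cat("<extinction_matrix> (cm^-1 M^-1), path length",
      x$path_length_cm, "cm\n")
  print(x$E)
  invisible(x)
}

check_extinction <- function(em) {
  if (!inherits(em, "extinction_matrix")) {
    stop("`em` must be an extinction_matrix object")
  }
  em
}

#' Forward modified Beer-Lambert law
#'
#' Converts chromophore concentration changes (uM, relative to baseline)
#' into optical-density changes at the two wavelengths:
#' `dA(t) = E . dc(t) . L`, with `dc` in molar units. This is the forward
#' direction used by the synthetic generator; preprocessing applies the
#' inverse ([mbll_invert()]).
#'
#' @param conc A data frame with numeric columns `d_hbd` and `d_hbo`
#'   (concentration changes in uM).
#' @param em An [extinction_matrix()].
#'
#' @return A tibble with columns `da_760` and `da_850` (optical-density
#'   change, dimensionless), one row per input row.
#' @seealso [mbll_invert()]
#' @examples
#' em <- extinction_matrix()
#' fwd <- forward_mbll(data.frame(d_hbd = c(0, 1), d_hbo = c(0, -1)), em)
#' mbll_invert(fwd, em)
#' @export
forward_mbll <- function(conc, em) {
  em <- check_extinction(em)
  if (!is.data.frame(conc) || !all(c("d_hbd", "d_hbo") %in% names(conc))) {
    stop("`conc` must be a data frame with columns `d_hbd` and `d_hbo`")
  }
  dc <- rbind(conc$d_hbd, conc$d_hbo) * 1e-6          # uM -> M
  if (!all(is.finite(dc))) stop("concentrations must be finite")
  dA <- em$E %*% dc * em$path_length_cm
  tibble::tibble(da_760 = unname(dA[1, ]), da_850 = unname(dA[2, ]))
}

#' Invert the modified Beer-Lambert law
#'
#' Recovers deoxy- and oxyhemoglobin concentration changes from
#' baseline-referenced optical-density changes at 760 and 850 nm:
#' `dc(t) = E^-1 . dA(t) / L`, reported in uM. This is the core
#' preprocessing computation turning dual-wavelength absorbance into
#' hemodynamic quantities.
#'
#' @param dA A data frame with numeric columns `da_760` and `da_850`.
#' @param em An [extinction_matrix()].
#'
#' @return A tibble with columns `d_hbd` and `d_hbo` in uM.
#' @seealso [forward_mbll()]
#' @export
mbll_invert <- function(dA, em) {
  em <- check_extinction(em)
  if (!is.data.frame(dA) || !all(c("da_760", "da_850") %in% names(dA))) {
    stop("`dA` must be a data frame with columns `da_760` and `da_850` ",
         "(check wavelength ordering)")
  }
  A <- rbind(dA$da_760, dA$da_850)
  dc <- solve(em$E, A) / em$path_length_cm * 1e6      # M -> uM
  tibble::tibble(d_hbd = unname(dc[1, ]), d_hbo = unname(dc[2, ]))
}
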