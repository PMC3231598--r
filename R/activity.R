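#' Activity-model parameters
#'
#' Settings used to convert molar concentrations into single-ion activities
#' via an ionic-strength-dependent activity coefficient. The default is the
#' Davies equation,
#' \deqn{\log_{10}\gamma = -A z^2\left(\frac{\sqrt I}{1+\sqrt I} - 0.3 I\right),}
#' which is serviceable up to ionic strengths of about 0.1 M and therefore
#' covers both dilute mixture measurements and calibrations run in a 0.05 M
#' background electrolyte. The extended Debye-Hueckel form with an effective
#' ion-size parameter is available as an alternative.
#'
#' @param formalism `"davies"` (default) or `"extended_debye_huckel"`.
#' @param A Debye-Hueckel constant in L^1/2 mol^-1/2 (0.511 at 25 C).
#' @param B Debye-Hueckel B parameter (per Angstrom and sqrt molarity); used
#'   only by the extended form.
#' @param ion_size effective ion diameter in Angstrom (extended form only).
#' @param background_ionic_strength fixed ionic-strength contribution of a
#'   background electrolyte in mol/L, e.g. 0.05 for calibrations run in
#'   0.05 M lithium acetate; 0 for measurements without background.
#' @return An object of class `activity_params`.
#' @export
activity_params <- function(formalism = c("davies", "extended_debye_huckel"),
                            A = 0.511, B = 0.328, ion_size = 4.5,
                            background_ionic_strength = 0) {
  formalism <- match.arg(formalism)
  stopifnot(is.numeric(A), A > 0,
            is.numeric(background_ionic_strength),
            background_ionic_strength >= 0)
  structure(list(formalism = formalism, A = A, B = B, ion_size = ion_size,
                 background_ionic_strength = background_ionic_strength),
            class = "activity_params")
}

#' Ionic strength of a solution
#'
#' Computes \eqn{I = I_{bg} + \frac12 \sum_i c_i z_i^2} over the declared
#' anions *and* the sodium counter-ions carried by their salts (each mole of
#' an anion of charge \eqn{z} brings \eqn{|z|} moles of Na+, as for Na2S and
#' NaClO4), so the per-ion contribution is \eqn{\frac12 c (z^2 + |z|)}.
#'
#' @param conc named numeric vector of molar anion concentrations.
#' @param charges named numeric vector of signed charges covering every name
#'   in `conc`.
#' @param params an [activity_params()] object (supplies the fixed background
#'   ionic strength).
#' @return Ionic strength in mol/L.
#' @export
ionic_strength <- function(conc, charges, params = activity_params()) {
  if (length(conc) == 0) return(params$background_ionic_strength)
  if (!all(is.finite(conc))) stop("concentrations must be finite")
  if (any(conc < 0)) stop("negative concentration")
  if (is.null(names(conc))) stop("`conc` must be named")
  z <- charges[names(conc)]
  if (anyNA(z))
    stop("undeclared ion(s): ",
         paste(setdiff(names(conc), names(charges)), collapse = ", "))
  params$background_ionic_strength + 0.5 * sum(conc * (z^2 + abs(z)))
}

#' Single-ion activity coefficient
#'
#' @param charge signed ionic charge (0 returns 1).
#' @param I ionic strength in mol/L (vectorised).
#' @param params an [activity_params()] object selecting the formalism.
#' @return Dimensionless activity coefficient(s), 1 at infinite dilution.
#' @export
activity_coefficient <- function(charge, I, params = activity_params()) {
  if (any(I < 0)) stop("ionic strength must be >= 0")
  if (charge == 0) return(rep(1, length(I)))
  s <- sqrt(I)
  log10g <- switch(params$formalism,
    davies = -params$A * charge^2 * (s / (1 + s) - 0.3 * I),
    extended_debye_huckel =
      -params$A * charge^2 * s / (1 + params$B * params$ion_size * s))
  10^log10g
}

# Activities of every declared ion in one solution (named vector of molar
# concentrations -> named vector of activities).
activities <- function(conc, charges, params = activity_params()) {
  I <- ionic_strength(conc, charges, params)
  g <- vapply(names(conc),
              function(nm) activity_coefficient(charges[[nm]], I, params),
              numeric(1))
  conc * g
}
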