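# Closed-form magneto-optic and attenuation models that parameterize the
# sensing mechanism: Faraday rotation of polarized light traversing glucose
# in blood plasma under a magnetic field, and Beer-Lambert attenuation along
# the skin/adipose path.

#' Magneto-optic parameter set
#'
#' Bundles the quantities of the Faraday-rotation model: the Verdet constant
#' (magnetic rotatory power) of the medium, the applied magnetic field
#' strength, the optical interaction length, the wavelength, the
#' field-induced circular birefringence, the angle between the field and the
#' light path, and the illumination beam radius.
#'
#' @param verdet Rotatory power per unit field and length
#'   \eqn{[rad \cdot G^{-1} \cdot mm^{-1}]}.
#' @param field Magnetic field strength B in Gauss; must be >= 0.
#' @param path_length Interaction length L in mm; must be > 0.
#' @param wavelength Optical wavelength in nm; must be > 0. Default 532
#'   (green laser).
#' @param delta_n Circular birefringence (refractive-index difference between
#'   the two circular polarization states), dimensionless.
#' @param alpha Angle between the field and the light path, radians.
#' @param beam_radius Illumination beam radius in mm; must be > 0.
#' @return An object of class `magneto_optic_params`.
#' @export
magneto_optic_params <- function(verdet = 1, field = 150, path_length = 1,
                                 wavelength = 532, delta_n = 0, alpha = 0,
                                 beam_radius = 1) {
  for (nm in c("verdet", "field", "path_length", "wavelength", "delta_n",
               "alpha", "beam_radius")) {
    check_finite_scalar(get(nm), nm)
  }
  if (field < 0) stop_invalid("`field` must be >= 0")
  if (path_length <= 0) stop_invalid("`path_length` must be > 0")
  if (wavelength <= 0) stop_invalid("`wavelength` must be > 0")
  if (beam_radius <= 0) stop_invalid("`beam_radius` must be > 0")
  structure(list(verdet = verdet, field = field, path_length = path_length,
                 wavelength = wavelength, delta_n = delta_n, alpha = alpha,
                 beam_radius = beam_radius),
            class = "magneto_optic_params")
}

#' Faraday polarization rotation angle
#'
#' Rotation of the polarization plane of light traversing a magneto-optic
#' medium: phi = V * B * L, linear in each argument. For blood, the glucose
#' dissolved in plasma dominates the rotation because its Verdet constant is
#' large relative to other plasma constituents.
#'
#' @param verdet Verdet constant \eqn{[rad \cdot G^{-1} \cdot mm^{-1}]}.
#' @param field Magnetic field strength B in Gauss.
#' @param path_length Interaction length L in mm; must be > 0.
#' @return Rotation angle in radians.
#' @examples
#' faraday_rotation(2, 150, 3)  # 900
#' @export
faraday_rotation <- function(verdet, field, path_length) {
  check_finite_scalar(verdet, "verdet")
  check_finite_scalar(field, "field")
  check_finite_scalar(path_length, "path_length")
  if (path_length <= 0) stop_invalid("`path_length` must be > 0")
  verdet * field * path_length
}

#' Faraday rotation from circular birefringence
#'
#' Equivalent birefringence form of the rotation angle,
#' phi = pi * L * B * delta_n / lambda, where delta_n is the field-induced
#' difference in refractive index between the left and right circularly
#' polarized states.
#'
#' @param path_length Interaction length L in mm; must be > 0.
#' @param field Magnetic field strength B in Gauss.
#' @param delta_n Circular birefringence (dimensionless).
#' @param wavelength Optical wavelength, same length unit as implied by
#'   delta_n scaling; must be > 0.
#' @return Rotation angle in radians.
#' @export
faraday_rotation_birefringence <- function(path_length, field, delta_n,
                                           wavelength) {
  check_finite_scalar(path_length, "path_length")
  check_finite_scalar(field, "field")
  check_finite_scalar(delta_n, "delta_n")
  check_finite_scalar(wavelength, "wavelength")
  if (wavelength <= 0) stop_invalid("`wavelength` must be > 0")
  if (path_length <= 0) stop_invalid("`path_length` must be > 0")
  pi * path_length * field * delta_n / wavelength
}

#' Verdet constant from an observed rotation
#'
#' Magnetic rotatory power V = phi / (L * B * cos(alpha)) for a rotation phi
#' observed over path length L under field B inclined at angle alpha to the
#' propagation direction. Inverse of [faraday_rotation()] when alpha = 0.
#'
#' @param angle Observed polarization rotation phi, radians.
#' @param path_length Interaction length L in mm.
#' @param field Magnetic field strength B in Gauss.
#' @param alpha Angle between B and the light path, radians.
#' @return Verdet constant \eqn{[rad \cdot G^{-1} \cdot mm^{-1}]}.
#' @export
verdet_constant <- function(angle, path_length, field, alpha = 0) {
  check_finite_scalar(angle, "angle")
  check_finite_scalar(path_length, "path_length")
  check_finite_scalar(field, "field")
  check_finite_scalar(alpha, "alpha")
  denom <- path_length * field * cos(alpha)
  if (abs(denom) < .Machine$double.eps * 64) {
    stop_invalid("degenerate geometry: path_length * field * cos(alpha) is zero")
  }
  angle / denom
}

#' Minimal field strength decorrelating the speckle pattern
#'
#' The lowest magnetic field able to decorrelate the observed speckle area
#' scales as B_min = k * pi * L / (R * phi): proportional to the interaction
#' length, inversely proportional to the beam radius and the rotation angle.
#' The underlying relation is a proportionality; `proportionality_k` is an
#' explicit calibration constant (default 1).
#'
#' @param path_length Interaction length L in mm; must be > 0.
#' @param beam_radius Illumination beam radius R in mm; must be > 0.
#' @param angle Polarization rotation phi, radians; must be non-zero.
#' @param proportionality_k Calibration constant > 0.
#' @return Minimal decorrelating field strength, in the units fixed by k.
#' @export
min_decorrelation_field <- function(path_length, beam_radius, angle,
                                    proportionality_k = 1) {
  check_finite_scalar(path_length, "path_length")
  check_finite_scalar(beam_radius, "beam_radius")
  check_finite_scalar(angle, "angle")
  check_finite_scalar(proportionality_k, "proportionality_k")
  if (path_length <= 0) stop_invalid("`path_length` must be > 0")
  if (beam_radius * angle <= 0) {
    stop_invalid("degenerate geometry: beam_radius * angle must be > 0")
  }
  if (proportionality_k <= 0) stop_invalid("`proportionality_k` must be > 0")
  proportionality_k * pi * path_length / (beam_radius * angle)
}

#' Beer-Lambert attenuation parameters
#'
#' @param molar_attenuation Molar attenuation coefficient epsilon
#'   \eqn{[L \cdot mol^{-1} \cdot mm^{-1}]}; >= 0.
#' @param concentration Absorber concentration C \eqn{[mol \cdot L^{-1}]}; >= 0.
#' @param path_length Geometric light path d through the sample, mm; >= 0.
#' @param incident_intensity Incident intensity I0 (arbitrary units); > 0.
#' @param reflection_mode If `TRUE` the light traverses the sample twice
#'   (reflection off the blood vessel back through skin and adipose), so the
#'   effective optical path is 2 d.
#' @return An object of class `attenuation_params`.
#' @export
attenuation_params <- function(molar_attenuation, concentration, path_length,
                               incident_intensity = 1,
                               reflection_mode = FALSE) {
  for (nm in c("molar_attenuation", "concentration", "path_length",
               "incident_intensity")) {
    check_finite_scalar(get(nm), nm)
    if (get(nm) < 0) stop_invalid("`", nm, "` must be >= 0")
  }
  if (incident_intensity <= 0) stop_invalid("`incident_intensity` must be > 0")
  stopifnot(is.logical(reflection_mode), length(reflection_mode) == 1L)
  structure(list(molar_attenuation = molar_attenuation,
                 concentration = concentration,
                 path_length = path_length,
                 incident_intensity = incident_intensity,
                 reflection_mode = reflection_mode),
            class = "attenuation_params")
}

#' Beer-Lambert attenuation
#'
#' Absorbance A = epsilon * C * d_eff with d_eff = 2 d in reflection mode
#' (the beam crosses the skin and adipose layers twice), and transmitted
#' intensity I = I0 * exp(-A). The standard convention A = ln(I0 / I) is
#' used so that attenuating media have positive absorbance.
#'
#' @param params An [attenuation_params()] object.
#' @return A list with `absorbance` and `transmitted_intensity`.
#' @examples
#' beer_lambert(attenuation_params(1, 1, 1))  # A = 1, I = exp(-1)
#' @export
beer_lambert <- function(params) {
  if (!inherits(params, "attenuation_params")) {
    stop_invalid("`params` must be an attenuation_params object")
  }
  d_eff <- if (params$reflection_mode) 2 * params$path_length else params$path_length
  a <- params$molar_attenuation * params$concentration * d_eff
  list(absorbance = a,
       transmitted_intensity = params$incident_intensity * exp(-a))
}
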