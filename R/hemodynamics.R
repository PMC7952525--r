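# Derived hemodynamic quantities from bedside functional echocardiography.
# Flow equations use cm for diameters and velocity-time integrals, beats/min
# for heart rate and kg for weight, so that cm^3 = mL and outputs come out in
# mL/kg/min directly.

#' Echocardiographic exam record
#'
#' Constructs a validated single-exam record of raw neonatologist-performed
#' echocardiography (NPE) measurements. Values entering the constructor are
#' already averaged over consecutive cardiac cycles (see [cycle_mean()]).
#'
#' Units follow the staging convention: the transductal diameter is in mm,
#' the antegrade left-pulmonary-artery (LPA) end-diastolic velocity in cm/s,
#' diameters and velocity-time integrals entering flow equations in cm.
#'
#' @param transductal_diameter narrowest ductal diameter, mm; 0 = closed duct.
#' @param ductal_vmax_vmin_ratio ratio of maximal to minimal transductal
#'   Doppler velocity (dimensionless); must be 0 exactly when the duct is
#'   closed (`transductal_diameter == 0`) and positive otherwise.
#' @param lpa_diastolic_velocity antegrade LPA end-diastolic velocity, cm/s.
#' @param dao_flow_direction descending-aorta diastolic flow direction, one of
#'   `"forward"`, `"absent"`, `"reverse"`.
#' @param la_ao_ratio left-atrial to aortic-root diameter ratio.
#' @param aortic_root_diameter aortic root diameter at the valve hinges, cm.
#' @param aortic_vti ascending-aorta velocity-time integral, cm.
#' @param svc_max_diameter,svc_min_diameter maximal and minimal superior vena
#'   cava (SVC) diameters, cm; the minimum may not exceed the maximum.
#' @param svc_vti SVC velocity-time integral, cm.
#' @param heart_rate heart rate, beats/min.
#' @param weight body weight at the exam, kg.
#' @param e_wave_velocity,a_wave_velocity mitral inflow E- and A-wave peak
#'   velocities, cm/s.
#' @param postnatal_age postnatal age at the exam, hours.
#' @return an object of class `echo_exam` (a named list of measurements).
#' @examples
#' echo_exam(transductal_diameter = 2.0, ductal_vmax_vmin_ratio = 1.6,
#'           lpa_diastolic_velocity = 35, dao_flow_direction = "reverse")
#' @export
echo_exam <- function(transductal_diameter = 0,
                      ductal_vmax_vmin_ratio = 0,
                      lpa_diastolic_velocity = 0,
                      dao_flow_direction = c("forward", "absent", "reverse"),
                      la_ao_ratio = NA_real_,
                      aortic_root_diameter = NA_real_,
                      aortic_vti = NA_real_,
                      svc_max_diameter = NA_real_,
                      svc_min_diameter = NA_real_,
                      svc_vti = NA_real_,
                      heart_rate = NA_real_,
                      weight = NA_real_,
                      e_wave_velocity = NA_real_,
                      a_wave_velocity = NA_real_,
                      postnatal_age = NA_real_) {
  dao_flow_direction <- match.arg(dao_flow_direction)
  num <- list(transductal_diameter = transductal_diameter,
              ductal_vmax_vmin_ratio = ductal_vmax_vmin_ratio,
              lpa_diastolic_velocity = lpa_diastolic_velocity,
              la_ao_ratio = la_ao_ratio,
              aortic_root_diameter = aortic_root_diameter,
              aortic_vti = aortic_vti,
              svc_max_diameter = svc_max_diameter,
              svc_min_diameter = svc_min_diameter,
              svc_vti = svc_vti,
              heart_rate = heart_rate,
              weight = weight,
              e_wave_velocity = e_wave_velocity,
              a_wave_velocity = a_wave_velocity,
              postnatal_age = postnatal_age)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.na(v)) check_nonneg(v, nm)
  }
  if (!is.na(svc_min_diameter) && !is.na(svc_max_diameter) &&
      svc_min_diameter > svc_max_diameter) {
    stop_invalid("svc_min_diameter", "must not exceed svc_max_diameter")
  }
  if ((transductal_diameter == 0) != (ductal_vmax_vmin_ratio == 0)) {
    stop_invalid("ductal_vmax_vmin_ratio",
                 "must be 0 exactly when transductal_diameter is 0 (closed duct)")
  }
  structure(c(num, list(dao_flow_direction = dao_flow_direction)),
            class = "echo_exam")
}

#' @export
print.echo_exam <- function(x, ...) {
  cat("Echocardiographic exam\n")
  cat(sprintf("  transductal diameter: %s mm, Vmax/Vmin: %s, LPA diastolic: %s cm/s, DAo flow: %s\n",
              format(x$transductal_diameter), format(x$ductal_vmax_vmin_ratio),
              format(x$lpa_diastolic_velocity), x$dao_flow_direction))
  invisible(x)
}

#' Left ventricular output per kilogram
#'
#' Computes LVO (mL/kg/min) from the aortic root cross-section, the
#' ascending-aorta velocity-time integral and heart rate:
#' \deqn{LVO = \frac{(d^2/4)\,\pi \cdot VTI \cdot HR}{weight}}
#' with the diameter and VTI in cm, so the stroke volume is in cm^3 = mL.
#'
#' @param aortic_root_diameter aortic root diameter, cm.
#' @param aortic_vti ascending-aorta velocity-time integral, cm.
#' @param heart_rate heart rate, beats/min; must be positive.
#' @param weight body weight, kg; must be positive.
#' @return flow in mL/kg/min.
#' @examples
#' left_ventricular_output(1.0, 10, 150, 1.0)  # 1178.1 mL/kg/min
#' @export
left_ventricular_output <- function(aortic_root_diameter, aortic_vti,
                                    heart_rate, weight) {
  check_nonneg(aortic_root_diameter, "aortic_root_diameter")
  check_nonneg(aortic_vti, "aortic_vti")
  check_positive(heart_rate, "heart_rate")
  check_positive(weight, "weight")
  (aortic_root_diameter^2 / 4) * pi * aortic_vti * heart_rate / weight
}

#' Superior vena cava flow per kilogram
#'
#' SVC flow (mL/kg/min) from the mean SVC diameter (arithmetic mean of the
#' maximal and minimal M-mode diameters), the SVC velocity-time integral and
#' heart rate: \eqn{[(\bar d^2/4)\,\pi \cdot VTI \cdot HR] / weight}.
#'
#' @param svc_max_diameter,svc_min_diameter maximal and minimal SVC
#'   diameters, cm; `svc_min_diameter` may not exceed `svc_max_diameter`.
#' @param svc_vti SVC velocity-time integral, cm.
#' @param heart_rate heart rate, beats/min; must be positive.
#' @param weight body weight, kg; must be positive.
#' @return flow in mL/kg/min.
#' @examples
#' svc_flow(0.4, 0.3, 6, 150, 1.0)  # 86.59 mL/kg/min
#' @export
svc_flow <- function(svc_max_diameter, svc_min_diameter, svc_vti,
                     heart_rate, weight) {
  check_nonneg(svc_max_diameter, "svc_max_diameter")
  check_nonneg(svc_min_diameter, "svc_min_diameter")
  if (any(svc_min_diameter > svc_max_diameter)) {
    stop_invalid("svc_min_diameter", "must not exceed svc_max_diameter")
  }
  check_nonneg(svc_vti, "svc_vti")
  check_positive(heart_rate, "heart_rate")
  check_positive(weight, "weight")
  mean_d <- (svc_max_diameter + svc_min_diameter) / 2
  (mean_d^2 / 4) * pi * svc_vti * heart_rate / weight
}

#' Ratio of left ventricular output to superior vena cava flow
#'
#' The LVO/SVC flow ratio rises with left-to-right ductal shunting: pulmonary
#' over-circulation inflates LVO while systemic (upper-body) return does not.
#'
#' @param lvo left ventricular output, mL/kg/min.
#' @param svc superior vena cava flow, mL/kg/min; must be positive.
#' @return dimensionless ratio `lvo / svc`.
#' @export
lvo_svc_ratio <- function(lvo, svc) {
  check_nonneg(lvo, "lvo")
  if (!is.numeric(svc) || anyNA(svc) || any(svc <= 0)) {
    stop("undefined ratio: `svc` flow must be > 0", call. = FALSE)
  }
  lvo / svc
}

#' Mitral inflow E/A ratio
#'
#' @param e_wave E-wave peak velocity, cm/s.
#' @param a_wave A-wave peak velocity, cm/s; must be positive.
#' @return dimensionless ratio `e_wave / a_wave`.
#' @export
e_a_ratio <- function(e_wave, a_wave) {
  check_nonneg(e_wave, "e_wave")
  if (!is.numeric(a_wave) || anyNA(a_wave) || any(a_wave <= 0)) {
    stop("undefined ratio: `a_wave` must be > 0", call. = FALSE)
  }
  e_wave / a_wave
}
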