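#' Thermal properties of the tissue
#'
#' Bundles the physical constants of the Pennes bioheat model. Defaults are
#' the standard skin-tissue values: conductivity 0.5 W/m/K, blood density
#' 1000 kg/m^3, blood specific heat 4200 J/kg/K, arterial temperature 37
#' degC, spatial (external) heating 30000 W/m^3 and metabolic heating 4200
#' W/m^3. The tissue density `rho` and specific heat `c` are not part of the
#' standard property table; they default to the blood values (1000, 4200),
#' which is the usual assumption for soft, water-rich tissue, and both are
#' configurable.
#'
#' The total volumetric heating `Q_t = Q_r + Q_m` is derived at construction
#' and exposed as a read-only element.
#'
#' @param k thermal conductivity (W/m/K)
#' @param rho tissue density (kg/m^3)
#' @param c tissue specific heat (J/kg/K)
#' @param rho_b blood density (kg/m^3)
#' @param c_b blood specific heat (J/kg/K)
#' @param T_b arterial blood temperature (degC)
#' @param Q_r spatial heat source, e.g. laser deposition (W/m^3)
#' @param Q_m metabolic heat generation (W/m^3)
#' @return an object of class `tissue_properties`
#' @export
#' @examples
#' props <- tissue_properties()
#' props$Q_t  # 34200 W/m^3
tissue_properties <- function(k = 0.5, rho = 1000, c = 4200,
                              rho_b = 1000, c_b = 4200, T_b = 37,
                              Q_r = 30000, Q_m = 4200) {
  for (nm in c("k", "rho", "c", "rho_b", "c_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("tissue property '", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  for (nm in c("T_b", "Q_r", "Q_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("tissue property '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  structure(
    list(k = k, rho = rho, c = c, rho_b = rho_b, c_b = c_b,
         T_b = T_b, Q_r = Q_r, Q_m = Q_m, Q_t = Q_r + Q_m),
    class = "tissue_properties"
  )
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat("Tissue thermal properties\n")
  cat(sprintf("  k     = %g W/m/K      rho*c     = %g J/m^3/K\n", x$k, x$rho * x$c))
  cat(sprintf("  rho_b = %g kg/m^3   c_b = %g J/kg/K\n", x$rho_b, x$c_b))
  cat(sprintf("  T_b   = %g degC       Q_t = Q_r + Q_m = %g W/m^3\n", x$T_b, x$Q_t))
  invisible(x)
}

#' Temperature-dependent blood perfusion model
#'
#' The volumetric blood perfusion rate omega_b (1/s) as a function of the
#' absolute tissue temperature T (degC). Three families are supported:
#' `"constant"` omega_b = a1, `"linear"` omega_b = a1 + a2*T, and
#' `"exponential"` omega_b = a1*exp(a2*T). a1 and a2 are nonnegative
#' coefficients (a2 is ignored for the constant family).
#'
#' @param kind one of `"constant"`, `"linear"`, `"exponential"`
#' @param a1 intercept/prefactor coefficient (1/s)
#' @param a2 slope (1/s/degC, linear) or exponent rate (1/degC, exponential)
#' @return an object of class `perfusion_model`
#' @export
#' @examples
#' pm <- perfusion_model("linear", a1 = 0.0005, a2 = 0.0001)
#' perfusion_rate(pm, 37)  # 0.0042 1/s
perfusion_model <- function(kind = c("constant", "linear", "exponential"),
                            a1, a2 = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(a1) || length(a1) != 1L || !is.finite(a1) || a1 < 0) {
    stop("perfusion coefficient 'a1' must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(a2) || length(a2) != 1L || !is.finite(a2)) {
    stop("perfusion coefficient 'a2' must be a single finite number", call. = FALSE)
  }
  if (kind == "constant") a2 <- 0
  pm <- structure(list(kind = kind, a1 = a1, a2 = a2), class = "perfusion_model")
  # omega_b must stay nonnegative over the physiological range
  Tchk <- seq(0, 100, by = 1)
  if (any(perfusion_rate(pm, Tchk) < 0)) {
    stop("perfusion model is negative somewhere in [0, 100] degC", call. = FALSE)
  }
  pm
}

#' @export
print.perfusion_model <- function(x, ...) {
  form <- switch(x$kind,
    constant = sprintf("omega_b = %g", x$a1),
    linear = sprintf("omega_b(T) = %g + %g * T", x$a1, x$a2),
    exponential = sprintf("omega_b(T) = %g * exp(%g * T)", x$a1, x$a2)
  )
  cat("Blood perfusion model (", x$kind, "): ", form, "  [1/s]\n", sep = "")
  invisible(x)
}

#' Evaluate the blood perfusion rate
#'
#' @param model a [perfusion_model()]
#' @param T absolute tissue temperature(s), degC
#' @return perfusion rate(s), 1/s
#' @export
perfusion_rate <- function(model, T) {
  stopifnot(inherits(model, "perfusion_model"))
  if (any(!is.finite(T))) stop("temperature must be finite", call. = FALSE)
  switch(model$kind,
    constant = rep_len(model$a1, length(T)),
    linear = model$a1 + model$a2 * T,
    exponential = model$a1 * exp(model$a2 * T),
    stop("unknown perfusion kind: ", model$kind, call. = FALSE)
  )
}

#' Nonlinear source term of the shifted bioheat equation
#'
#' In the shifted variable theta = T - T_b the Pennes equation reads
#' d(theta)/dt = (k/(rho c)) Lap(theta) + f(theta) with
#' f(theta) = -(rho_b c_b/(rho c)) * omega_b(theta + T_b) * theta
#'            + Q_t/(rho c).
#' The perfusion sink vanishes at theta = 0 (tissue at blood temperature),
#' where f reduces to the heating term Q_t/(rho c).
#'
#' @param props a [tissue_properties()]
#' @param model a [perfusion_model()]
#' @param theta shifted temperature(s) theta = T - T_b, degC
#' @return rate(s) of temperature change, K/s
#' @export
source_term <- function(props, model, theta) {
  stopifnot(inherits(props, "tissue_properties"))
  rc <- props$rho * props$c
  omega <- perfusion_rate(model, theta + props$T_b)
  -(props$rho_b * props$c_b / rc) * omega * theta + props$Q_t / rc
}

#' Shift between absolute and blood-referenced temperature
#'
#' theta = T - T_b. The shifted variable makes the perfusion sink
#' proportional to theta and zeroes the natural rest state.
#'
#' @param T absolute temperature(s), degC
#' @param theta shifted temperature(s), degC
#' @param props a [tissue_properties()]
#' @return shifted (resp. absolute) temperature(s)
#' @export
shift_temperature <- function(T, props) {
  if (any(!is.finite(T))) stop("temperature must be finite", call. = FALSE)
  T - props$T_b
}

#' @rdname shift_temperature
#' @export
unshift_temperature <- function(theta, props) {
  if (any(!is.finite(theta))) stop("temperature must be finite", call. = FALSE)
  theta + props$T_b
}

#' Dirichlet boundary temperatures of the skin model
#'
#' The rectangle has its left edge at the skin surface (held at `T_s`) and
#' its right edge at the body core (held at `T_c`); top and bottom edges are
#' insulated. Values are stored as absolute temperatures and shifted
#' internally where needed.
#'
#' @param T_s skin-surface temperature (degC), left edge
#' @param T_c body-core temperature (degC), right edge
#' @return an object of class `boundary_conditions`
#' @export
boundary_conditions <- function(T_s = 25, T_c = 37) {
  for (nm in c("T_s", "T_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("boundary temperature '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  structure(list(T_s = T_s, T_c = T_c), class = "boundary_conditions")
}

#' @export
print.boundary_conditions <- function(x, ...) {
  cat(sprintf("Boundary conditions: surface T_s = %g degC (left), core T_c = %g degC (right),\n",
              x$T_s, x$T_c))
  cat("  top and bottom edges insulated\n")
  invisible(x)
}
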