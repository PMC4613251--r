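# Parameter sets: the dispersive amide pi-pi* oscillator (Lorentzian
# wavenumber, dipole-strength constant, in-plane polarization angle,
# static residual tensor) plus the isotropic atom polarizabilities.
# Shipped OL/H/J files live under inst/extdata/params.

ISOTROPIC_SPECIES <- c("C_aliphatic", "O_alcohol", "H_aliphatic",
                       "H_alcohol", "H_amide")

#' Build a validated parameter set
#'
#' @param name Label ("OL", "H", "J" or custom).
#' @param nu0 Oscillator wavenumber of the amide pi-pi* transition,
#'   cm^-1 (> 0).
#' @param D Dipole-strength constant of the Lorentzian oscillator,
#'   Angstrom^3 cm^-2 (> 0).
#' @param theta In-plane polar angle of the oscillator axis, degrees,
#'   measured in the amide plane from the N->C' axis toward the carbonyl
#'   oxygen side; in [-180, 180].
#' @param static_principal Length-3 principal values (Angstrom^3, >= 0)
#'   of the residual nondispersive polarizability of the amide point,
#'   expressed along the local frame axes (e1 = N->C', e2 = in-plane
#'   toward O, e3 = plane normal). Set to zeros to drop the residual
#'   tensor from the nondispersive block.
#' @param isotropic Named numeric vector of isotropic polarizabilities
#'   (Angstrom^3, > 0) for species `C_aliphatic`, `O_alcohol`,
#'   `H_aliphatic`, `H_alcohol`, `H_amide`.
#' @param bandwidth Lorentzian half-peak bandwidth Gamma, cm^-1 (> 0).
#'   Default 6000.
#' @param placement Amide point placement: `"o"` (N-C' midpoint), `"x"`
#'   (shifted 0.1 Angstrom toward C') or `"y"` (shifted 0.1 Angstrom
#'   in-plane toward the carbonyl O).
#' @param include_static Keep the static residual tensor of the amide in
#'   the nondispersive block (default `TRUE`).
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(name, nu0, D, theta,
                          static_principal = c(0, 0, 0),
                          isotropic = c(C_aliphatic = 0.878,
                                        O_alcohol = 0.465,
                                        H_aliphatic = 0.135,
                                        H_alcohol = 0.135,
                                        H_amide = 0.135),
                          bandwidth = 6000,
                          placement = c("o", "x", "y"),
                          include_static = TRUE) {
  placement <- match.arg(placement)
  check_pos <- function(value, label) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
        value <= 0) {
      rlang::abort(paste0(label, " must be a single positive number"),
                   class = "dipolecd_param_error")
    }
  }
  check_pos(nu0, "nu0")
  check_pos(D, "D")
  check_pos(bandwidth, "bandwidth")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < -180 || theta > 180) {
    rlang::abort("theta must be in [-180, 180] degrees",
                 class = "dipolecd_param_error")
  }
  if (length(static_principal) != 3L || any(!is.finite(static_principal)) ||
      any(static_principal < 0)) {
    rlang::abort("static_principal must be 3 nonnegative values",
                 class = "dipolecd_param_error")
  }
  miss <- setdiff(ISOTROPIC_SPECIES, names(isotropic))
  if (length(miss)) {
    rlang::abort(paste0("isotropic polarizability missing for: ",
                        paste(miss, collapse = ", ")),
                 class = "dipolecd_param_error")
  }
  if (any(!is.finite(isotropic)) || any(isotropic <= 0)) {
    rlang::abort("all isotropic polarizabilities must be positive",
                 class = "dipolecd_param_error")
  }
  structure(
    list(name = name, nu0 = nu0, D = D, theta = theta,
         static_principal = as.numeric(static_principal),
         isotropic = isotropic[ISOTROPIC_SPECIES],
         bandwidth = bandwidth, placement = placement,
         include_static = isTRUE(include_static)),
    class = "parameter_set"
  )
}

#' Load a parameter set from a YAML config file
#'
#' Every physical field must be present in the file; the only value that
#' may be defaulted is the bandwidth Gamma, which falls back to
#' 6000 cm^-1 when omitted. All range invariants are enforced on load.
#'
#' @param path Path to a YAML parameter file (see the files under
#'   `system.file("extdata", "params", package = "dipolecd")`).
#' @param name Optional label overriding the file's `name` field.
#' @return A `parameter_set`.
#' @export
load_parameter_set <- function(path, name = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("parameter file not found: ", path),
                 class = "dipolecd_input_error")
  }
  cfg <- yaml::read_yaml(path)
  required <- c("nu0", "D", "theta", "static_principal", "isotropic",
                "placement")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) {
    rlang::abort(paste0("parameter file missing field(s): ",
                        paste(miss, collapse = ", ")),
                 class = "dipolecd_param_error")
  }
  parameter_set(
    name = name %||% cfg$name %||% basename(path),
    nu0 = cfg$nu0, D = cfg$D, theta = cfg$theta,
    static_principal = unlist(cfg$static_principal),
    isotropic = unlist(cfg$isotropic),
    bandwidth = cfg$bandwidth %||% 6000,
    placement = cfg$placement,
    include_static = cfg$include_static %||% TRUE
  )
}

#' Save a parameter set to a YAML file
#'
#' `load_parameter_set(save_parameter_set(ps, f))` is the identity.
#'
#' @param params A `parameter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(params, path) {
  yaml::write_yaml(
    list(name = params$name, nu0 = params$nu0, D = params$D,
         theta = params$theta,
         static_principal = params$static_principal,
         isotropic = as.list(params$isotropic),
         bandwidth = params$bandwidth, placement = params$placement,
         include_static = params$include_static),
    path
  )
  invisible(path)
}

#' Locate a shipped parameter family file
#'
#' @param name One of `"OL"`, `"H"`, `"J"`.
#' @return Path to the installed YAML file.
#' @export
builtin_parameter_file <- function(name = c("OL", "H", "J")) {
  name <- match.arg(name)
  system.file("extdata", "params", paste0(name, ".yaml"),
              package = "dipolecd", mustWork = TRUE)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "<parameter_set \"%s\"> nu0 = %.0f cm-1, D = %.3g A3 cm-2, theta = %.1f deg\n",
    x$name, x$nu0, x$D, x$theta))
  cat(sprintf("  Gamma = %.0f cm-1, placement = %s, static tensor %s\n",
              x$bandwidth, x$placement,
              if (x$include_static && any(x$static_principal > 0))
                "included" else "dropped"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
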