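# Mode moments, dipole and rotational strengths, and the Lorentzian-sum
# absorption (epsilon) and CD (delta-epsilon) spectra per residue.
#
# Unit contract: positions Angstrom, polarizability volumes Angstrom^3,
# D_is Angstrom^3 cm^-2, wavenumbers cm^-1. The CGS conversions
# (Angstrom^3 -> cm^3 for D_k, an extra Angstrom -> cm for the magnetic
# moment arm in R_k) are folded into the spectral prefactors below; 6909
# is 3 x 2303 (2303 = 1000 ln 10) and already carries the orientational
# average, so the matching full-solve extinction uses the full trace over
# three field polarizations. The prefactors are pinned by the
# isolated-oscillator and full-solve equivalence tests.

AVOGADRO <- 6.02214076e23

# epsilon = SPEC_EPS * nu^2 * Gamma / p * sum_k D_k / lorentz_k  (D_k in A^3 cm^-2)
SPEC_EPS <- 8 * pi^2 * AVOGADRO * 1e-24 / 6909
# delta-epsilon = SPEC_DEPS * nu^3 * Gamma / p * sum_k R_k / lorentz_k (R_k in A^4 cm^-2)
SPEC_DEPS <- 32 * pi^3 * AVOGADRO * 1e-32 / 6909
# full-solve: epsilon = SPEC_EPS_TRACE * nu * Im tr alpha / p  (alpha in A^3)
SPEC_EPS_TRACE <- 8 * pi^2 * AVOGADRO * 1e-24 / 6909

#' Convert wavelength to wavenumber
#'
#' @param lambda_nm Wavelength, nm (> 0).
#' @return Wavenumber, cm^-1 (`1e7 / lambda_nm`).
#' @export
wavelength_to_wavenumber <- function(lambda_nm) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    rlang::abort("wavelength must be positive", class = "dipolecd_input_error")
  }
  1e7 / lambda_nm
}

#' Convert wavenumber to wavelength
#'
#' @param nu Wavenumber, cm^-1 (> 0).
#' @return Wavelength, nm.
#' @export
wavenumber_to_wavelength <- function(nu) {
  if (any(!is.finite(nu)) || any(nu <= 0)) {
    rlang::abort("wavenumber must be positive", class = "dipolecd_input_error")
  }
  1e7 / nu
}

#' Electric and magnetic mode moments, dipole and rotational strengths
#'
#' For mode k with amplitudes `t_is`:
#' `mu_k = sum_is sqrt(D_is) t_is u_is` and
#' `m_k = sum_is sqrt(D_is) t_is (r_i - origin) x u_is`, giving
#' `D_k = mu_k . mu_k` and `R_k = mu_k . m_k`. The sqrt(D) weights match
#' the scaled eigenproblem and reduce to the unweighted sums for uniform
#' D; `amplitudes = "as-printed"` drops them for the literal unweighted
#' form. The rotational strengths are origin-independent and sum to zero;
#' the dipole strengths sum to the total oscillator strength
#' `sum_is D_is`.
#'
#' @param modes A `normal_mode_set`.
#' @param units The `polarizable_unit_set` the modes came from.
#' @param origin Origin for the magnetic moment arm; defaults to the
#'   chromophore centroid (any choice gives identical R_k).
#' @param amplitudes `"scaled"` (default, sqrt(D)-weighted) or
#'   `"as-printed"` (unweighted).
#' @return A `mode_strengths` object: tibble with one row per mode
#'   (`mode`, `nu_k`, `lambda_nm`, `D_k`, `R_k`, `flagged`) carrying the
#'   3 x q moment matrices `mu` and `m` as attributes.
#' @export
mode_moments <- function(modes, units, origin = NULL,
                         amplitudes = c("scaled", "as-printed")) {
  amplitudes <- match.arg(amplitudes)
  ch <- units$chromophores
  if (nrow(ch) != nrow(modes$t)) {
    rlang::abort("modes and unit set have different oscillator counts",
                 class = "dipolecd_input_error")
  }
  r <- as.matrix(ch[, c("x", "y", "z")])
  u <- as.matrix(ch[, c("ux", "uy", "uz")])
  origin <- origin %||% colMeans(r)
  rr <- sweep(r, 2L, origin)
  rxu <- cbind(rr[, 2L] * u[, 3L] - rr[, 3L] * u[, 2L],
               rr[, 3L] * u[, 1L] - rr[, 1L] * u[, 3L],
               rr[, 1L] * u[, 2L] - rr[, 2L] * u[, 1L])
  w <- if (amplitudes == "scaled") sqrt(ch$D) else rep(1, nrow(ch))
  tw <- modes$t * w
  mu <- t(u) %*% tw    # 3 x q, columns = modes
  m <- t(rxu) %*% tw
  D_k <- colSums(mu^2)
  R_k <- colSums(mu * m)
  out <- tibble::tibble(
    mode = seq_along(D_k),
    nu_k = modes$nu_k,
    lambda_nm = 1e7 / modes$nu_k,
    D_k = D_k,
    R_k = R_k,
    flagged = modes$flagged
  )
  attr(out, "mu") <- mu
  attr(out, "m") <- m
  attr(out, "origin") <- origin
  attr(out, "amplitudes") <- amplitudes
  class(out) <- c("mode_strengths", class(out))
  out
}

#' @method tidy mode_strengths
#' @export
tidy.mode_strengths <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' Lorentzian-sum absorption and CD spectra
#'
#' Evaluates, on a wavelength grid, the per-residue molar extinction and
#' circular dichroism as sums of Lorentzian bands over all normal modes:
#' epsilon is proportional to `nu^2 sum_k D_k / ((nu_k^2 - nu^2)^2 +
#' Gamma^2 nu^2)` and delta-epsilon to the analogous `nu^3`-weighted sum
#' over `R_k`. Modes flagged with non-positive squared wavenumbers are
#' excluded with a warning.
#'
#' @param strengths A `mode_strengths` object.
#' @param Gamma Lorentzian half-peak bandwidth, cm^-1 (> 0).
#' @param p Number of peptide residues (>= 2) for the per-residue
#'   normalization.
#' @param grid_nm Wavelength grid, nm; default 175-250 nm in 1 nm steps.
#'   Use `seq(176, 250, 2)` for the coarser rebuilt-fragment convention.
#' @param metadata Optional named list stored with the spectrum.
#' @return A `cd_spectrum`: tibble with `wavelength_nm`, `wavenumber`,
#'   `epsilon` and `delta_epsilon` (M^-1 cm^-1 per residue).
#' @export
compute_spectra <- function(strengths, Gamma, p, grid_nm = 175:250,
                            metadata = list()) {
  if (!is.numeric(Gamma) || Gamma <= 0) {
    rlang::abort("Gamma must be positive", class = "dipolecd_param_error")
  }
  if (p < 2) {
    rlang::abort("p must be at least 2 residues",
                 class = "dipolecd_input_error")
  }
  if (is.unsorted(grid_nm, strictly = TRUE)) {
    rlang::abort("wavelength grid must be strictly increasing",
                 class = "dipolecd_input_error")
  }
  keep <- !strengths$flagged
  if (!any(keep)) {
    rlang::abort("no usable normal modes: empty spectrum",
                 class = "dipolecd_empty_spectrum")
  }
  if (any(!keep)) {
    rlang::warn(sprintf("%d flagged mode(s) excluded from the spectrum",
                        sum(!keep)))
  }
  nu_k_sq <- strengths$nu_k[keep]^2
  D_k <- strengths$D_k[keep]
  R_k <- strengths$R_k[keep]

  nu <- wavelength_to_wavenumber(grid_nm)
  lorentz <- outer(nu, nu_k_sq, function(v, vk2) {
    1 / ((vk2 - v^2)^2 + Gamma^2 * v^2)
  })
  eps <- SPEC_EPS * nu^2 * Gamma / p * drop(lorentz %*% D_k)
  deps <- SPEC_DEPS * nu^3 * Gamma / p * drop(lorentz %*% R_k)

  out <- tibble::tibble(
    wavelength_nm = as.numeric(grid_nm),
    wavenumber = nu,
    epsilon = eps,
    delta_epsilon = deps
  )
  attr(out, "metadata") <- utils::modifyList(
    list(Gamma = Gamma, p = p, n_modes = sum(keep)), metadata)
  class(out) <- c("cd_spectrum", class(out))
  out
}

#' @method glance cd_spectrum
#' @export
glance.cd_spectrum <- function(x, ...) {
  md <- attr(x, "metadata") %||% list()
  i_max <- which.max(x$delta_epsilon)
  i_min <- which.min(x$delta_epsilon)
  tibble::tibble(
    parameter_set = md$parameter_set %||% NA_character_,
    Gamma = md$Gamma %||% NA_real_,
    p = md$p %||% NA_integer_,
    q = md$q %||% NA_integer_,
    lambda_max_positive = x$wavelength_nm[i_max],
    delta_epsilon_max = x$delta_epsilon[i_max],
    lambda_max_negative = x$wavelength_nm[i_min],
    delta_epsilon_min = x$delta_epsilon[i_min]
  )
}

#' @method tidy cd_spectrum
#' @export
tidy.cd_spectrum <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' Plot a CD spectrum
#'
#' @param object A `cd_spectrum`.
#' @param ... Unused.
#' @return A ggplot with delta-epsilon and epsilon panels.
#' @method autoplot cd_spectrum
#' @export
autoplot.cd_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("wavelength_nm", "epsilon",
                                  "delta_epsilon")],
    cols = c("epsilon", "delta_epsilon"),
    names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("delta_epsilon", "epsilon"),
                          labels = c("Δε (M⁻¹ cm⁻¹)",
                                     "ε (M⁻¹ cm⁻¹)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength_nm,
                                     y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2,
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a spectrum as CSV with a JSON metadata sidecar
#'
#' @param spectrum A `cd_spectrum`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cd_spectrum <- function(spectrum, path) {
  utils::write.csv(
    tibble::as_tibble(spectrum)[, c("wavelength_nm", "epsilon",
                                    "delta_epsilon")],
    path, row.names = FALSE)
  md <- attr(spectrum, "metadata")
  if (!is.null(md)) {
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an experimental CD spectrum from two-column text
#'
#' Accepts whitespace- or comma-separated columns (wavelength in nm,
#' delta-epsilon in M^-1 cm^-1), with `#` comment lines; extra columns
#' beyond the first two are ignored, so processed databank exports load
#' after trivial column selection.
#'
#' @param path Input text file.
#' @return A tibble with `wavelength_nm` and `delta_epsilon`, sorted by
#'   wavelength.
#' @export
read_cd_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    rlang::abort("no data rows in spectrum file",
                 class = "dipolecd_format_error")
  }
  sep <- if (any(grepl(",", lines))) "," else ""
  dat <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           fill = TRUE)
  if (ncol(dat) < 2L) {
    rlang::abort("spectrum file needs two columns (wavelength, delta-epsilon)",
                 class = "dipolecd_format_error")
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(dat[[1L]]),
                        delta_epsilon = as.numeric(dat[[2L]]))
  if (any(!is.finite(out$wavelength_nm))) {
    rlang::abort("non-numeric wavelength column",
                 class = "dipolecd_format_error")
  }
  dplyr::arrange(out, .data$wavelength_nm)
}
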