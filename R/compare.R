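# Comparison of calculated and experimental CD spectra: linear
# resampling to a common grid, windowed RMSD, and Spearman rank
# correlation across proteins at fixed wavelengths.

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; requests outside the spectrum's range raise an
#' error (no extrapolation).
#'
#' @param spectrum Tibble with `wavelength_nm` and at least one of
#'   `delta_epsilon`, `epsilon`.
#' @param grid_nm Target wavelengths, nm.
#' @return Tibble on the new grid with the same value columns.
#' @export
resample_spectrum <- function(spectrum, grid_nm) {
  rng <- range(spectrum$wavelength_nm)
  if (any(grid_nm < rng[1L] - 1e-9) || any(grid_nm > rng[2L] + 1e-9)) {
    rlang::abort(sprintf(
      "requested grid outside spectrum range [%.1f, %.1f] nm",
      rng[1L], rng[2L]), class = "dipolecd_window_error")
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(grid_nm))
  for (col in intersect(c("epsilon", "delta_epsilon"), names(spectrum))) {
    out[[col]] <- stats::approx(spectrum$wavelength_nm, spectrum[[col]],
                                xout = grid_nm)$y
  }
  out
}

#' Windowed RMSD between calculated and experimental CD
#'
#' `sqrt(sum_i (exp(lambda_i) - calc(lambda_i))^2 / n_lambda)` over the
#' calculated grid points falling inside the window (default
#' 180-210 nm); the experimental spectrum is interpolated onto the
#' calculated grid, never the reverse.
#'
#' @param calculated A `cd_spectrum` (or tibble with `wavelength_nm`,
#'   `delta_epsilon`).
#' @param experimental Tibble with `wavelength_nm`, `delta_epsilon`.
#' @param window Wavelength window `c(min, max)`, nm.
#' @return A `comparison_result` tibble: `rmsd` (M^-1 cm^-1),
#'   `lambda_min`, `lambda_max`, `n_lambda`.
#' @export
cd_rmsd <- function(calculated, experimental, window = c(180, 210)) {
  lo <- max(window[1L], min(experimental$wavelength_nm),
            min(calculated$wavelength_nm))
  hi <- min(window[2L], max(experimental$wavelength_nm),
            max(calculated$wavelength_nm))
  grid <- calculated$wavelength_nm[calculated$wavelength_nm >= lo &
                                     calculated$wavelength_nm <= hi]
  if (length(grid) < 2L) {
    rlang::abort("fewer than 2 common wavelengths in the window",
                 class = "dipolecd_window_error")
  }
  ce <- resample_spectrum(experimental, grid)$delta_epsilon
  cc <- calculated$delta_epsilon[match(grid, calculated$wavelength_nm)]
  out <- tibble::tibble(
    rmsd = sqrt(mean((ce - cc)^2)),
    lambda_min = min(grid), lambda_max = max(grid),
    n_lambda = length(grid)
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Spearman rank correlation across proteins at one wavelength
#'
#' Correlates the calculated against the experimental delta-epsilon at a
#' fixed wavelength across a collection of spectrum pairs (one per
#' protein); ties receive averaged ranks.
#'
#' @param pairs List of pairs; each element a list with components
#'   `calculated` and `experimental` (tibbles with `wavelength_nm`,
#'   `delta_epsilon` covering the wavelength).
#' @param lambda_nm Wavelength at which to compare, nm.
#' @return Correlation coefficient in [-1, 1].
#' @export
spearman_at_wavelength <- function(pairs, lambda_nm) {
  if (length(pairs) < 3L) {
    rlang::abort("need at least 3 spectrum pairs",
                 class = "dipolecd_input_error")
  }
  value_at <- function(sp) {
    resample_spectrum(sp, lambda_nm)$delta_epsilon
  }
  calc <- vapply(pairs, function(pr) value_at(pr$calculated), numeric(1))
  expv <- vapply(pairs, function(pr) value_at(pr$experimental), numeric(1))
  stats::cor(calc, expv, method = "spearman")
}
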