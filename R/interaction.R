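# Interaction matrix assembly and the partially dispersive normal-mode
# solve. Dispersive oscillators each contribute one (projected) row; every
# nondispersive point (isotropic atom or static amide tensor) contributes
# a 3x3 Cartesian block. The eigenproblem is posed on the dimensionally
# scaled Schur complement so eigenvalues are squared wavenumbers (cm^-2).

#' Point-dipole field tensor
#'
#' The 3x3 tensor T giving the field at `ri` of a unit dipole at `rj`:
#' `T = (I r^2 - 3 r r') / r^5` with `r = rj - ri`. Symmetric in its
#' arguments, traceless, and scaling as the inverse cube of the
#' separation. Units: Angstrom^-3.
#'
#' @param ri,rj 3-vectors, Angstrom.
#' @param min_separation Separations below this (Angstrom) raise a
#'   near-singular-contact error. Default 0.5.
#' @return 3x3 numeric matrix.
#' @export
dipole_field_tensor <- function(ri, rj, min_separation = 0.5) {
  r <- rj - ri
  d <- vnorm(r)
  if (d < min_separation) {
    rlang::abort(sprintf(
      "points %.3f Angstrom apart (< %.2f): near-singular dipole contact",
      d, min_separation), class = "dipolecd_contact_error")
  }
  (diag(3) * d^2 - 3 * outer(r, r)) / d^5
}

# Row bookkeeping for the nondispersive part: each nondispersive "unit"
# is (position, 3x3 inverse-polarizability block, owner id). Owner ids
# let the static tensor that shares a chromophore's position skip the
# (singular) self interaction.
nd_units_of <- function(units) {
  out <- list()
  iso <- units$isotropics
  if (nrow(iso)) {
    for (i in seq_len(nrow(iso))) {
      out[[length(out) + 1L]] <- list(
        pos = c(iso$x[i], iso$y[i], iso$z[i]),
        inv_alpha = diag(3) / iso$alpha[i],
        owner = paste0("iso", i))
    }
  }
  if (!is.null(units$statics)) {
    ch <- units$chromophores
    for (k in seq_along(units$statics)) {
      a <- units$statics[[k]]
      if (all(abs(a) < 1e-14)) next
      out[[length(out) + 1L]] <- list(
        pos = c(ch$x[k], ch$y[k], ch$z[k]),
        inv_alpha = solve(a),
        owner = paste0("chrom", k))
    }
  }
  out
}

#' Assemble the partitioned interaction matrix
#'
#' Builds the zero-frequency interaction matrix in its dispersive /
#' nondispersive block partition. Dispersive diagonal entries are
#' `nu0^2 / D` (the inverse Lorentzian polarizability at zero
#' wavenumber); nondispersive diagonal blocks are inverse polarizability
#' tensors; off-diagonal couplings are projections of the point-dipole
#' tensor. A static amide tensor shares its chromophore's position and
#' does not self-interact with that oscillator.
#'
#' @param units A `polarizable_unit_set`.
#' @param min_separation Hard error threshold for point contacts,
#'   Angstrom.
#' @param warn_separation Pairs closer than this trigger a close-contact
#'   warning.
#' @return An `interaction_blocks` list: `A11` (q x q), `A12` (q x n),
#'   `A22` (n x n), plus the dispersive parameter table and row
#'   bookkeeping.
#' @export
assemble <- function(units, min_separation = 0.5, warn_separation = 1.5) {
  ch <- units$chromophores
  q <- nrow(ch)
  rpos <- as.matrix(ch[, c("x", "y", "z")])
  u <- as.matrix(ch[, c("ux", "uy", "uz")])
  nd <- nd_units_of(units)
  n <- 3L * length(nd)

  # contact screening over all distinct point positions
  all_pos <- rbind(rpos,
                   if (length(nd)) t(vapply(nd, `[[`, numeric(3), "pos")))
  owner <- c(sprintf("chrom%d", seq_len(q)),
             vapply(nd, `[[`, character(1), "owner"))
  if (nrow(all_pos) > 1L) {
    dm <- as.matrix(stats::dist(all_pos))
    diag(dm) <- Inf
    same <- outer(owner, owner, `==`)
    dm[same] <- Inf
    dmin <- min(dm)
    if (dmin < min_separation) {
      idx <- which(dm == dmin, arr.ind = TRUE)[1L, ]
      rlang::abort(sprintf(
        "atomic collision: points %d and %d only %.3f Angstrom apart",
        idx[1L], idx[2L], dmin), class = "dipolecd_contact_error")
    }
    if (dmin < warn_separation) {
      rlang::warn(sprintf(
        "close contact: minimum inter-point separation %.3f Angstrom",
        dmin))
    }
  }

  A11 <- matrix(0, q, q)
  diag(A11) <- ch$nu0^2 / ch$D
  if (q > 1L) {
    for (i in seq_len(q - 1L)) {
      for (j in (i + 1L):q) {
        Tij <- dipole_field_tensor(rpos[i, ], rpos[j, ], min_separation)
        A11[i, j] <- A11[j, i] <- drop(u[i, ] %*% Tij %*% u[j, ])
      }
    }
  }

  A12 <- matrix(0, q, n)
  A22 <- matrix(0, n, n)
  if (length(nd)) {
    for (b in seq_along(nd)) {
      cols <- (3L * (b - 1L) + 1L):(3L * b)
      A22[cols, cols] <- nd[[b]]$inv_alpha
      for (i in seq_len(q)) {
        if (identical(nd[[b]]$owner, paste0("chrom", i))) next
        Tib <- dipole_field_tensor(rpos[i, ], nd[[b]]$pos, min_separation)
        A12[i, cols] <- drop(u[i, ] %*% Tib)
      }
      if (b > 1L) {
        for (b2 in seq_len(b - 1L)) {
          cols2 <- (3L * (b2 - 1L) + 1L):(3L * b2)
          Tbb <- dipole_field_tensor(nd[[b2]]$pos, nd[[b]]$pos,
                                     min_separation)
          A22[cols2, cols] <- Tbb
          A22[cols, cols2] <- t(Tbb)
        }
      }
    }
  }

  structure(
    list(A11 = A11, A12 = A12, A22 = A22,
         dispersive = ch[, c("nu0", "D")],
         u = u, positions = rpos, n_nd = n, p = units$p),
    class = "interaction_blocks"
  )
}

#' Schur-complement reduction of the nondispersive block
#'
#' Eliminates the nondispersive degrees of freedom:
#' `A11 - A12 A22^-1 A21`, computed through a factorization of `A22`
#' (never an explicit inverse). With no nondispersive units `A11` is
#' returned unchanged.
#'
#' @param blocks An `interaction_blocks` object (or any list with `A11`,
#'   `A12`, `A22`).
#' @param max_condition Condition-number estimate above which `A22` is
#'   declared numerically singular.
#' @return Symmetric q x q matrix over the dispersive oscillators.
#' @export
reduce_dispersive <- function(blocks, max_condition = 1e12) {
  if (!blocks$n_nd) return(blocks$A11)
  cond <- kappa(blocks$A22)
  if (!is.finite(cond) || cond > max_condition) {
    rlang::abort(sprintf(
      "nondispersive block numerically singular (condition estimate %.3g)",
      cond), class = "dipolecd_singular_block")
  }
  red <- blocks$A11 - blocks$A12 %*% solve(blocks$A22, t(blocks$A12))
  (red + t(red)) / 2
}

#' Solve the dispersive normal-mode eigenproblem
#'
#' Poses the eigenproblem on the dimensionally scaled matrix
#' `G = S^(1/2) A_red S^(1/2)` with `S = diag(D_is)`, whose entries are
#' `nu0_is^2` on the diagonal plus `sqrt(D_is D_jt)` times the reduced
#' coupling off it; its eigenvalues are squared normal-mode wavenumbers
#' (cm^-2) exactly, and for uniform D the scaling is a similarity of the
#' plain Schur complement. Eigenvectors are orthonormal, sorted by
#' ascending wavenumber, with the sign fixed so the largest-magnitude
#' component is positive. Non-positive eigenvalues ("long-wavelength
#' modes", a signature of unphysical geometry) are retained and flagged
#' with a warning, never silently dropped.
#'
#' @param reduced Symmetric q x q reduced interaction matrix.
#' @param dispersive Tibble/data frame with columns `nu0`, `D` in the
#'   same oscillator order.
#' @return A `normal_mode_set`: list with `nu_k_sq` (cm^-2), `nu_k`
#'   (cm^-1, `NA` for flagged modes), orthonormal eigenvector matrix `t`
#'   (modes in columns), `flagged` logical vector, and the scaled
#'   `effective_matrix`.
#' @export
solve_modes <- function(reduced, dispersive) {
  if (any(!is.finite(reduced))) {
    rlang::abort("non-finite entries in reduced interaction matrix",
                 class = "dipolecd_numerical_error")
  }
  sD <- sqrt(dispersive$D)
  G <- reduced * outer(sD, sD)
  G <- (G + t(G)) / 2
  es <- eigen(G, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (k in seq_along(vals)) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  flagged <- vals <= 0
  if (any(flagged)) {
    rlang::warn(sprintf(
      "%d long-wavelength normal mode(s) with non-positive squared wavenumber; excluded from spectra",
      sum(flagged)))
  }
  structure(
    list(nu_k_sq = vals,
         nu_k = ifelse(flagged, NA_real_, sqrt(pmax(vals, 0))),
         t = vecs, flagged = flagged, effective_matrix = G,
         dispersive = tibble::as_tibble(dispersive)),
    class = "normal_mode_set"
  )
}

#' Normal modes of a unit set
#'
#' Convenience wrapper: [assemble()], [reduce_dispersive()],
#' [solve_modes()].
#'
#' @inheritParams assemble
#' @return A `normal_mode_set`.
#' @export
normal_modes <- function(units, min_separation = 0.5,
                         warn_separation = 1.5) {
  blocks <- assemble(units, min_separation, warn_separation)
  solve_modes(reduce_dispersive(blocks), blocks$dispersive)
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("<normal_mode_set> %d modes (%d flagged non-positive)\n",
              length(x$nu_k_sq), sum(x$flagged)))
  if (any(!x$flagged)) {
    lam <- 1e7 / x$nu_k[!x$flagged]
    cat(sprintf("  wavelengths %.1f - %.1f nm\n", min(lam), max(lam)))
  }
  invisible(x)
}

#' Tidy a normal-mode set
#'
#' @param x A `normal_mode_set`.
#' @param ... Unused.
#' @return Tibble with one row per mode: `mode`, `nu_k_sq`, `nu_k`,
#'   `lambda_nm`, `flagged`.
#' @method tidy normal_mode_set
#' @export
tidy.normal_mode_set <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$nu_k_sq),
    nu_k_sq = x$nu_k_sq,
    nu_k = x$nu_k,
    lambda_nm = 1e7 / x$nu_k,
    flagged = x$flagged
  )
}

#' Direct complex linear solve over a wavenumber grid
#'
#' The brute-force oracle for the normal-mode path: at each grid
#' wavenumber the full (dispersive + nondispersive) interaction matrix is
#' formed with the complex Lorentzian dispersive polarizability
#' `a(nu) = D / (nu0^2 - nu^2 + i Gamma nu)` on the diagonal and solved
#' against unit external fields along x, y and z. The isotropically
#' averaged extinction follows from the imaginary part of the response
#' trace with the same per-residue normalization as the Lorentzian mode
#' sum, so on purely dispersive systems with uniform bandwidth the two
#' paths agree to numerical precision.
#'
#' @param units A `polarizable_unit_set`.
#' @param grid_nm Wavelength grid, nm.
#' @param Gamma Lorentzian half-peak bandwidth, cm^-1.
#' @param p Residue count for normalization (defaults to the unit set's).
#' @return A `full_solve_result`: tibble with `wavelength_nm`,
#'   `wavenumber`, `alpha_re`, `alpha_im` (trace of the complex
#'   polarizability tensor, Angstrom^3) and `epsilon` (M^-1 cm^-1 per
#'   residue); the complex moment array is attached as attribute
#'   `moments` (rows = system rows, columns = field polarization, slices
#'   = grid points).
#' @export
full_solve <- function(units, grid_nm = 175:250, Gamma = 6000, p = NULL) {
  if (any(!is.finite(grid_nm)) || any(grid_nm <= 0)) {
    rlang::abort("wavelength grid must be finite and positive",
                 class = "dipolecd_input_error")
  }
  p <- p %||% units$p
  blocks <- assemble(units)
  q <- nrow(blocks$A11)
  n <- blocks$n_nd
  A0 <- rbind(cbind(blocks$A11, blocks$A12),
              cbind(t(blocks$A12), blocks$A22))
  # projection table: row r responds to field component E proj[r, ]
  proj <- matrix(0, q + n, 3L)
  proj[seq_len(q), ] <- blocks$u
  if (n) proj[(q + 1L):(q + n), ] <- do.call(
    rbind, replicate(n / 3L, diag(3), simplify = FALSE))

  nu_grid <- 1e7 / grid_nm
  nu0 <- blocks$dispersive$nu0
  D <- blocks$dispersive$D
  moments <- array(complex(real = 0), dim = c(q + n, 3L, length(nu_grid)))
  alpha_tr <- complex(length.out = length(nu_grid))
  for (g in seq_along(nu_grid)) {
    nu <- nu_grid[g]
    A <- A0 + diag(c((-nu^2 + 1i * Gamma * nu) / D, rep(0, n)),
                   q + n, q + n)
    mu <- tryCatch(solve(A, proj), error = function(e) {
      rlang::abort(sprintf(
        "interaction matrix singular at %.1f cm^-1: %s", nu,
        conditionMessage(e)), class = "dipolecd_numerical_error")
    })
    res <- max(abs(A %*% mu - proj)) / max(abs(proj))
    if (res > 1e-8) {
      rlang::abort(sprintf(
        "linear-solve residual %.2e at %.1f cm^-1 exceeds tolerance",
        res, nu), class = "dipolecd_numerical_error")
    }
    moments[, , g] <- mu
    alpha_tr[g] <- sum(diag(t(proj) %*% mu))
  }

  # with the +i Gamma nu sign convention of the Lorentzian, absorption
  # corresponds to a negative imaginary part of the polarizability
  eps <- -SPEC_EPS_TRACE * nu_grid * Im(alpha_tr) / p
  out <- tibble::tibble(
    wavelength_nm = grid_nm,
    wavenumber = nu_grid,
    alpha_re = Re(alpha_tr),
    alpha_im = Im(alpha_tr),
    epsilon = eps
  )
  attr(out, "moments") <- moments
  class(out) <- c("full_solve_result", class(out))
  out
}
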