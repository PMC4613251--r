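# Chromophore geometry: the anisotropic amide point, its local frame and
# oscillator direction, Euler angles between successive amides, and the
# assembly of a full polarizable unit set from a classification.

#' Place the anisotropic amide point
#'
#' @param N,Cprime,O 3-vectors (Angstrom): amide nitrogen, carbonyl
#'   carbon, carbonyl oxygen.
#' @param placement `"o"`: midpoint of the N-C' bond; `"x"`: midpoint
#'   shifted 0.1 Angstrom along N->C'; `"y"`: midpoint shifted 0.1
#'   Angstrom perpendicular to N-C', in the NC'O plane, toward the
#'   carbonyl oxygen.
#' @return 3-vector position of the amide point.
#' @export
place_amide_point <- function(N, Cprime, O, placement = c("o", "x", "y")) {
  placement <- match.arg(placement)
  check_amide_geometry(N, Cprime, O)
  mid <- (N + Cprime) / 2
  if (placement == "o") return(mid)
  e1 <- vunit(Cprime - N)
  if (placement == "x") return(mid + 0.1 * e1)
  w <- O - mid
  nhat <- vunit(w - sum(w * e1) * e1)
  mid + 0.1 * nhat
}

check_amide_geometry <- function(N, Cprime, O) {
  if (vnorm(vcross(Cprime - N, O - N)) <
      1e-8 * max(vnorm(Cprime - N), vnorm(O - N))) {
    rlang::abort("N, C', O are (near) collinear: degenerate amide geometry",
                 class = "dipolecd_degenerate_geometry")
  }
  invisible(TRUE)
}

#' Local orthonormal frame of an amide group
#'
#' `e1` points along N->C', `e3` is the unit normal of the NC'O plane
#' (oriented so that `e2 = e3 x e1` points to the carbonyl-oxygen side of
#' the N-C' axis), and the three axes form a right-handed orthonormal
#' triple.
#'
#' @inheritParams place_amide_point
#' @param origin Frame origin; defaults to the `"o"` placement point.
#' @return An `amide_frame`: list with `origin`, `e1`, `e2`, `e3`.
#' @export
amide_frame <- function(N, Cprime, O, origin = NULL) {
  check_amide_geometry(N, Cprime, O)
  e1 <- vunit(Cprime - N)
  e3 <- vunit(vcross(e1, O - N))
  e2 <- vcross(e3, e1)
  structure(list(origin = origin %||% ((N + Cprime) / 2),
                 e1 = e1, e2 = e2, e3 = e3),
            class = "amide_frame")
}

#' Oscillator polarization direction within an amide frame
#'
#' @param frame An `amide_frame`.
#' @param theta In-plane angle, degrees, from `e1` toward `e2`.
#' @return Unit 3-vector `cos(theta) e1 + sin(theta) e2`.
#' @export
oscillator_direction <- function(frame, theta) {
  t <- deg2rad(theta)
  cos(t) * frame$e1 + sin(t) * frame$e2
}

frame_matrix <- function(frame) cbind(frame$e1, frame$e2, frame$e3)

#' Euler angles between two amide frames
#'
#' Returns the z-y-z convention angles (phi, theta, psi), in degrees, of
#' the rotation carrying the reference frame onto the other frame, i.e.
#' `R_other = R_ref Rz(phi) Ry(theta) Rz(psi)`. In the gimbal cases
#' (theta = 0 or 180) psi is fixed at 0 and the full twist is reported in
#' phi.
#'
#' @param reference,other `amide_frame` objects.
#' @return Named numeric vector `c(phi, theta, psi)`, degrees.
#' @export
euler_angles <- function(reference, other) {
  R <- t(frame_matrix(reference)) %*% frame_matrix(other)
  ct <- max(-1, min(1, R[3L, 3L]))
  theta <- acos(ct)
  if (sin(theta) > 1e-9) {
    phi <- atan2(R[2L, 3L], R[1L, 3L])
    psi <- atan2(R[3L, 2L], -R[3L, 1L])
  } else if (ct > 0) {
    psi <- 0
    phi <- atan2(R[2L, 1L], R[1L, 1L])
  } else {
    psi <- 0
    phi <- atan2(-R[2L, 1L], -R[1L, 1L])
  }
  c(phi = rad2deg(phi), theta = rad2deg(theta), psi = rad2deg(psi))
}

# Rz(phi) Ry(theta) Rz(psi), angles in degrees. Used by tests to confirm
# the extracted angles reconstruct the relative rotation.
euler_rotation <- function(phi, theta, psi) {
  rot_z(deg2rad(phi)) %*% rot_y(deg2rad(theta)) %*% rot_z(deg2rad(psi))
}

#' Construct a polarizable unit set
#'
#' Turns an atom classification plus a parameter set into the point-dipole
#' system of the model: one anisotropic chromophore point per amide triad
#' (position per the placement rule, dispersive oscillator along the
#' parameterized in-plane direction, static residual tensor rotated into
#' the lab frame) and one isotropic point per parameterized atom.
#'
#' @param classification A `unit_classification`.
#' @param params A `parameter_set`.
#' @return A `polarizable_unit_set`.
#' @export
build_unit_set <- function(classification, params) {
  tri <- classification$triads
  frames <- purrr::pmap(tri, function(n_x, n_y, n_z, c_x, c_y, c_z,
                                      o_x, o_y, o_z, ...) {
    N <- c(n_x, n_y, n_z); Cp <- c(c_x, c_y, c_z); O <- c(o_x, o_y, o_z)
    fr <- amide_frame(N, Cp, O,
                      origin = place_amide_point(N, Cp, O, params$placement))
    fr
  })
  pos <- t(vapply(frames, function(f) f$origin, numeric(3)))
  u <- t(vapply(frames, function(f) oscillator_direction(f, params$theta),
                numeric(3)))
  statics <- NULL
  if (params$include_static && any(params$static_principal > 0)) {
    statics <- lapply(frames, function(f) {
      Rm <- frame_matrix(f)
      Rm %*% diag(params$static_principal) %*% t(Rm)
    })
  }
  chrom <- tibble::tibble(
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    ux = u[, 1L], uy = u[, 2L], uz = u[, 3L],
    nu0 = params$nu0, D = params$D
  )
  iso <- tibble::tibble(
    x = classification$isotropic$x,
    y = classification$isotropic$y,
    z = classification$isotropic$z,
    alpha = as.numeric(params$isotropic[classification$isotropic$species]),
    species = classification$isotropic$species
  )
  polarizable_unit_set(chrom, iso, p = classification$p, statics = statics)
}

#' Assemble a polarizable unit set directly from tables
#'
#' Low-level constructor used by [build_unit_set()] and by synthetic test
#' systems: hand-placed oscillators do not need a protein structure.
#'
#' @param chromophores Tibble with columns `x`, `y`, `z` (Angstrom),
#'   `ux`, `uy`, `uz` (unit oscillator direction), `nu0` (cm^-1) and `D`
#'   (Angstrom^3 cm^-2); one row per dispersive oscillator.
#' @param isotropics Tibble with columns `x`, `y`, `z`, `alpha`
#'   (Angstrom^3); may have zero rows for a chromophores-only model.
#' @param p Residue count for the per-residue spectral normalization;
#'   defaults to one more than the oscillator count, as for a monomeric
#'   chain.
#' @param statics Optional list of 3x3 symmetric static polarizability
#'   tensors, one per chromophore (lab frame), entering the nondispersive
#'   block at the chromophore position.
#' @return A `polarizable_unit_set`: list with `chromophores`,
#'   `isotropics`, `statics`, `p`, `q`.
#' @export
polarizable_unit_set <- function(chromophores,
                                 isotropics = tibble::tibble(
                                   x = numeric(), y = numeric(),
                                   z = numeric(), alpha = numeric()),
                                 p = NULL, statics = NULL) {
  chromophores <- tibble::as_tibble(chromophores)
  isotropics <- tibble::as_tibble(isotropics)
  un <- sqrt(chromophores$ux^2 + chromophores$uy^2 + chromophores$uz^2)
  if (any(abs(un - 1) > 1e-8)) {
    rlang::abort("oscillator directions must be unit vectors",
                 class = "dipolecd_input_error")
  }
  if (any(chromophores$nu0 <= 0) || any(chromophores$D <= 0)) {
    rlang::abort("nu0 and D must be positive for every oscillator",
                 class = "dipolecd_param_error")
  }
  if (nrow(isotropics) && any(isotropics$alpha <= 0)) {
    rlang::abort("isotropic polarizabilities must be positive",
                 class = "dipolecd_param_error")
  }
  if (!is.null(statics) && length(statics) != nrow(chromophores)) {
    rlang::abort("need one static tensor per chromophore (or NULL)",
                 class = "dipolecd_input_error")
  }
  q <- nrow(chromophores)
  structure(
    list(chromophores = chromophores, isotropics = isotropics,
         statics = statics, p = p %||% (q + 1L), q = q),
    class = "polarizable_unit_set"
  )
}

#' @export
print.polarizable_unit_set <- function(x, ...) {
  n_st <- if (is.null(x$statics)) 0L else length(x$statics)
  cat(sprintf(
    "<polarizable_unit_set> q = %d dispersive oscillators, %d isotropic points, %d static amide tensors, p = %d residues\n",
    x$q, nrow(x$isotropics), n_st, x$p))
  invisible(x)
}

#' Mirror image of a unit set
#'
#' Reflects all positions and oscillator directions through a plane
#' (default the xy-plane). Static tensors transform as M A M'. Applying
#' the reflection twice restores the original system; spectra of the
#' mirror image have identical epsilon and pointwise negated
#' delta-epsilon.
#'
#' @param units A `polarizable_unit_set`.
#' @param normal Unit normal of the mirror plane.
#' @param point A point on the mirror plane.
#' @return The reflected `polarizable_unit_set`.
#' @export
mirror_image <- function(units, normal = c(0, 0, 1), point = c(0, 0, 0)) {
  nh <- vunit(normal)
  M <- diag(3) - 2 * outer(nh, nh)
  reflect <- function(xyz) {
    sweep(sweep(xyz, 2L, point) %*% t(M), 2L, point, `+`)
  }
  ch <- units$chromophores
  pos <- reflect(as.matrix(ch[, c("x", "y", "z")]))
  dir <- as.matrix(ch[, c("ux", "uy", "uz")]) %*% t(M)
  ch$x <- pos[, 1L]; ch$y <- pos[, 2L]; ch$z <- pos[, 3L]
  ch$ux <- dir[, 1L]; ch$uy <- dir[, 2L]; ch$uz <- dir[, 3L]
  iso <- units$isotropics
  if (nrow(iso)) {
    ipos <- reflect(as.matrix(iso[, c("x", "y", "z")]))
    iso$x <- ipos[, 1L]; iso$y <- ipos[, 2L]; iso$z <- ipos[, 3L]
  }
  statics <- if (!is.null(units$statics)) {
    lapply(units$statics, function(a) M %*% a %*% t(M))
  }
  polarizable_unit_set(ch, iso, p = units$p, statics = statics)
}

#' Dump a unit set as a TSV table
#'
#' One row per point (dispersive oscillators first), for debugging and
#' cross-implementation diffing.
#'
#' @param units A `polarizable_unit_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unit_set <- function(units, path) {
  ch <- dplyr::mutate(units$chromophores, kind = "dispersive",
                      .before = 1L)
  iso <- units$isotropics
  tab <- dplyr::bind_rows(
    ch,
    if (nrow(iso)) dplyr::mutate(iso, kind = "isotropic", .before = 1L)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
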