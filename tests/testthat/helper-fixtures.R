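# Fixtures built in code: synthetic parameter sets, random oscillator
# systems, ideal-chain fixtures, and independent oracles (dense Schur
# inverse, Kabsch superposition, PCA helix-axis fit).

synthetic_params <- function(nu0 = 52000, D = 1.9e9, theta = -9.1,
                             static_principal = c(1, 0.7, 0.4),
                             bandwidth = 6000, placement = "o",
                             include_static = TRUE) {
  parameter_set("synthetic", nu0 = nu0, D = D, theta = theta,
                static_principal = static_principal,
                bandwidth = bandwidth, placement = placement,
                include_static = include_static)
}

# Random dispersive-only (plus optional isotropic) point system with a
# guaranteed minimum separation so the dipole expansion stays sane.
random_unit_set <- function(n_disp, n_iso = 0, spread = 12,
                            min_sep = 2.5, p = NULL) {
  n <- n_disp + n_iso
  pos <- matrix(stats::runif(3 * n, 0, spread), ncol = 3L)
  for (iter in 1:200) {
    dm <- as.matrix(stats::dist(pos))
    diag(dm) <- Inf
    bad <- which(apply(dm, 1L, min) < min_sep)
    if (!length(bad)) break
    pos[bad, ] <- matrix(stats::runif(3 * length(bad), 0, spread),
                         ncol = 3L)
  }
  u <- matrix(stats::rnorm(3 * n_disp), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  ch <- tibble::tibble(
    x = pos[seq_len(n_disp), 1L], y = pos[seq_len(n_disp), 2L],
    z = pos[seq_len(n_disp), 3L],
    ux = u[, 1L], uy = u[, 2L], uz = u[, 3L],
    nu0 = stats::runif(n_disp, 48000, 56000),
    D = stats::runif(n_disp, 1e9, 3e9)
  )
  iso <- if (n_iso > 0) {
    tibble::tibble(
      x = pos[n_disp + seq_len(n_iso), 1L],
      y = pos[n_disp + seq_len(n_iso), 2L],
      z = pos[n_disp + seq_len(n_iso), 3L],
      alpha = stats::runif(n_iso, 0.1, 1.5)
    )
  } else {
    tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                   alpha = numeric())
  }
  polarizable_unit_set(ch, iso, p = p)
}

ideal_helix <- function(n = 15, hydrogens = FALSE) {
  build_chain(chain_recipe(rep("ALA", n), phi = -57, psi = -47),
              hydrogens = hydrogens)
}

# Independent helix-axis oracle: principal axis of the CA cloud; rise is
# the end-to-end projection divided by the residue steps.
helix_rise_fit <- function(structure) {
  ca <- as.matrix(structure[structure$name == "CA", c("x", "y", "z")])
  axis <- stats::prcomp(ca)$rotation[, 1L]
  abs(sum((ca[nrow(ca), ] - ca[1L, ]) * axis)) / (nrow(ca) - 1L)
}

# Dense-inverse Schur oracle (explicit solve(A22), the thing the
# production path avoids).
dense_schur <- function(blocks) {
  if (!blocks$n_nd) return(blocks$A11)
  blocks$A11 - blocks$A12 %*% solve(blocks$A22) %*% t(blocks$A12)
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

rigid_transform_units <- function(units, R = random_rotation(),
                                  shift = stats::rnorm(3, sd = 5)) {
  ch <- units$chromophores
  pos <- as.matrix(ch[, c("x", "y", "z")]) %*% t(R)
  pos <- sweep(pos, 2L, shift, `+`)
  dir <- as.matrix(ch[, c("ux", "uy", "uz")]) %*% t(R)
  ch$x <- pos[, 1L]; ch$y <- pos[, 2L]; ch$z <- pos[, 3L]
  ch$ux <- dir[, 1L]; ch$uy <- dir[, 2L]; ch$uz <- dir[, 3L]
  iso <- units$isotropics
  if (nrow(iso)) {
    ip <- sweep(as.matrix(iso[, c("x", "y", "z")]) %*% t(R), 2L, shift, `+`)
    iso$x <- ip[, 1L]; iso$y <- ip[, 2L]; iso$z <- ip[, 3L]
  }
  statics <- if (!is.null(units$statics)) {
    lapply(units$statics, function(a) R %*% a %*% t(R))
  }
  polarizable_unit_set(ch, iso, p = units$p, statics = statics)
}

# Kabsch superposition RMSD between two conformers of the same atoms.
superposed_rmsd <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  s <- svd(t(B) %*% A)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

count_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# Minimal hand-written PDB text for reader edge cases.
write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, altloc = " ", element = NULL,
                          record = "ATOM") {
  element <- element %||% substr(gsub("[0-9]", "", name), 1L, 1L)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resid, chain, resno, x, y, z, occ, 0, element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
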