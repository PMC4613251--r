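# Idealized peptide-chain builder: sequential natural-extension placement
# of backbone atoms from bond lengths, bond angles and the user's torsion
# angles. Serves both as the rebuilt-secondary-structure route and as the
# synthetic fixture generator for the whole package.

#' Ideal peptide internal-coordinate table
#'
#' Standard peptide-geometry defaults (bond lengths in Angstrom, angles
#' in degrees); every entry can be overridden. Correctness of the builder
#' is established by round-trip and planarity properties, not by these
#' particular numbers.
#'
#' @param ... Named overrides, e.g. `b_c_n = 1.33`.
#' @return Named list of internal coordinates.
#' @export
ideal_geometry <- function(...) {
  geo <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_ca_cb = 1.521, b_n_h = 1.010, b_ca_ha = 1.090, b_cb_hb = 1.090,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_c_ca_cb = 110.1, a_c_n_h = 119.5,
    a_ca_cb_hb = 109.5, a_n_ca_ha = 109.0,
    t_cb = 122.6   # torsion N-C'-CA-CB fixing the L configuration
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(geo))
  if (length(bad)) {
    rlang::abort(paste0("unknown ideal-geometry field(s): ",
                        paste(bad, collapse = ", ")),
                 class = "dipolecd_input_error")
  }
  utils::modifyList(geo, overrides)
}

#' Chain recipe: sequence plus backbone torsions
#'
#' @param sequence Character vector of 3-letter residue codes (`"ALA"` or
#'   `"GLY"` by default; other codes build an alanine-like backbone+CB).
#' @param phi,psi Backbone torsions per residue, degrees; recycled if
#'   scalar. The first residue's phi is geometrically unused (the seed
#'   frame fixes its carbonyl) and may be `NA`.
#' @param omega Peptide-bond torsion per residue, degrees; default 180
#'   (trans, planar amide). The first residue's omega is unused.
#' @return A `chain_recipe` tibble with columns `resid`, `phi`, `psi`,
#'   `omega`.
#' @export
chain_recipe <- function(sequence, phi, psi, omega = 180) {
  n <- length(sequence)
  if (n < 1L) {
    rlang::abort("empty sequence", class = "dipolecd_input_error")
  }
  rec <- tibble::tibble(
    resid = toupper(sequence),
    phi = rep_len(phi, n),
    psi = rep_len(psi, n),
    omega = rep_len(omega, n)
  )
  if (!(length(phi) %in% c(1L, n)) || !(length(psi) %in% c(1L, n)) ||
      !(length(omega) %in% c(1L, n))) {
    rlang::abort("torsion lists must have length 1 or length(sequence)",
                 class = "dipolecd_input_error")
  }
  class(rec) <- c("chain_recipe", class(rec))
  rec
}

#' Build a peptide chain with idealized geometry
#'
#' Places backbone atoms (N, CA, C, O, plus CB for non-glycine and
#' hydrogens on request) sequentially by natural extension: every bond
#' length and bond angle equals the ideal table; the supplied phi, psi
#' and omega torsions are honored exactly. The seed frame puts the first
#' N at the origin, the first CA on +x and the first C' in the xy-plane.
#'
#' @param recipe A `chain_recipe` (or anything [chain_recipe()] accepts
#'   via `sequence`/`phi`/`psi`).
#' @param hydrogens Add amide H, HA and CB methyl hydrogens at ideal
#'   positions.
#' @param geometry Ideal internal-coordinate table from
#'   [ideal_geometry()].
#' @param chain Chain identifier for the output atoms.
#' @param resno_start First residue number.
#' @return A `protein_structure`.
#' @export
build_chain <- function(recipe, hydrogens = FALSE,
                        geometry = ideal_geometry(), chain = "A",
                        resno_start = 1L) {
  g <- geometry
  n <- nrow(recipe)
  rows <- list()
  add <- function(nm, el, i, pos) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = nm, element = el, resno = resno_start + i - 1L,
      resid = recipe$resid[i], chain = chain,
      x = pos[1L], y = pos[2L], z = pos[3L], occupancy = 1, altloc = "")
  }

  N_prev <- CA_prev <- C_prev <- NULL
  for (i in seq_len(n)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(g$b_n_ca, 0, 0)
      ang <- deg2rad(g$a_n_ca_c)
      C <- CA + g$b_ca_c * c(-cos(ang), sin(ang), 0)
    } else {
      N <- nerf_place(N_prev, CA_prev, C_prev, g$b_c_n, g$a_ca_c_n,
                      recipe$psi[i - 1L])
      CA <- nerf_place(CA_prev, C_prev, N, g$b_n_ca, g$a_c_n_ca,
                       recipe$omega[i])
      C <- nerf_place(C_prev, N, CA, g$b_ca_c, g$a_n_ca_c,
                      recipe$phi[i])
    }
    add("N", "N", i, N)
    add("CA", "C", i, CA)
    add("C", "C", i, C)

    if (i > 1L && hydrogens) {
      H <- nerf_place(CA, C_prev, N, g$b_n_h, g$a_c_n_h, 180)
      add("H", "H", i, H)
    }

    if (recipe$resid[i] != "GLY") {
      # torsion N-C'-CA-CB fixes the L configuration
      CB <- nerf_place(N, C, CA, g$b_ca_cb, g$a_c_ca_cb, g$t_cb)
      add("CB", "C", i, CB)
      if (hydrogens) {
        for (tor in c(60, 180, 300)) {
          HB <- nerf_place(N, CA, CB, g$b_cb_hb, g$a_ca_cb_hb, tor)
          add(paste0("HB", match(tor, c(60, 180, 300))), "H", i, HB)
        }
        HA <- nerf_place(CB, C, CA, g$b_ca_ha, g$a_n_ca_ha, 121)
        add("HA", "H", i, HA)
      }
    } else if (hydrogens) {
      HA <- nerf_place(N, C, CA, g$b_ca_ha, g$a_n_ca_ha, -g$t_cb)
      add("HA2", "H", i, HA)
      HA3 <- nerf_place(N, C, CA, g$b_ca_ha, g$a_n_ca_ha, g$t_cb)
      add("HA3", "H", i, HA3)
    }

    # carbonyl O: anti to the next N about the CA-C' axis, so the amide
    # N(i+1)-C'-O-CA(i) group is exactly planar for omega = 180
    O <- nerf_place(N, CA, C, g$b_c_o, g$a_ca_c_o, recipe$psi[i] + 180)
    add("O", "O", i, O)

    N_prev <- N; CA_prev <- CA; C_prev <- C
  }

  atoms <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$resno, match(.data$name, c("N", "H", "CA", "HA",
                                                    "HA2", "HA3", "C",
                                                    "O", "CB", "HB1",
                                                    "HB2", "HB3")))
  new_protein_structure(atoms, check_backbone = FALSE)
}

#' Backbone torsions measured from coordinates
#'
#' @param structure A `protein_structure` (single chain, sequential
#'   residues assumed; measured per chain).
#' @return Tibble with `chain`, `resno`, `phi`, `psi`, `omega` (degrees);
#'   torsions that need a missing neighbour are `NA`.
#' @export
measure_torsions <- function(structure) {
  res <- structure |>
    tibble::as_tibble() |>
    dplyr::filter(.data$name %in% c("N", "CA", "C")) |>
    tidyr::pivot_wider(id_cols = c("chain", "resno"),
                       names_from = "name",
                       values_from = c("x", "y", "z"))
  out <- list()
  for (ch in unique(res$chain)) {
    rs <- dplyr::arrange(res[res$chain == ch, ], .data$resno)
    nr <- nrow(rs)
    at <- function(i, nm) c(rs[[paste0("x_", nm)]][i],
                            rs[[paste0("y_", nm)]][i],
                            rs[[paste0("z_", nm)]][i])
    phi <- psi <- omega <- rep(NA_real_, nr)
    for (i in seq_len(nr)) {
      prev_ok <- i > 1L && rs$resno[i] == rs$resno[i - 1L] + 1L
      next_ok <- i < nr && rs$resno[i + 1L] == rs$resno[i] + 1L
      if (prev_ok) {
        phi[i] <- vtorsion(at(i - 1L, "C"), at(i, "N"), at(i, "CA"),
                           at(i, "C"))
        omega[i] <- vtorsion(at(i - 1L, "CA"), at(i - 1L, "C"),
                             at(i, "N"), at(i, "CA"))
      }
      if (next_ok) {
        psi[i] <- vtorsion(at(i, "N"), at(i, "CA"), at(i, "C"),
                           at(i + 1L, "N"))
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      chain = ch, resno = rs$resno, phi = phi, psi = psi, omega = omega)
  }
  dplyr::bind_rows(out)
}

# psi implied by the carbonyl oxygen: the builder places O at torsion
# N-CA-C'-O = psi + 180, so psi is recovered from the O when no
# following N exists.
psi_from_carbonyl <- function(structure, chain_id, resno) {
  res <- structure[structure$chain == chain_id &
                     structure$resno == resno, ]
  at <- function(nm) {
    row <- res[res$name == nm, ][1L, ]
    c(row$x, row$y, row$z)
  }
  tor <- vtorsion(at("N"), at("CA"), at("C"), at("O")) - 180
  ((tor + 180) %% 360) - 180
}

#' Detect steric collisions
#'
#' All pairs of non-bonded heavy atoms closer than the cutoff. Pairs
#' within one residue and the backbone C'(i)-N(i+1) bond are exempt.
#'
#' @param structure A `protein_structure`.
#' @param cutoff Distance threshold, Angstrom (default 2).
#' @return Tibble with one row per offending pair (`atom_i`, `atom_j`,
#'   row indices into the structure, and `distance`).
#' @export
detect_collisions <- function(structure, cutoff = 2.0) {
  heavy <- which(structure$element != "H")
  empty <- tibble::tibble(atom_i = integer(), atom_j = integer(),
                          distance = numeric())
  if (cutoff <= 0 || length(heavy) < 2L) return(empty)
  xyz <- as.matrix(structure[heavy, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  hits <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  keep <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    i <- heavy[hits[k, 1L]]; j <- heavy[hits[k, 2L]]
    same_res <- structure$chain[i] == structure$chain[j] &&
      structure$resno[i] == structure$resno[j]
    pep_bond <- structure$chain[i] == structure$chain[j] &&
      ((structure$name[i] == "C" && structure$name[j] == "N" &&
          structure$resno[j] == structure$resno[i] + 1L) ||
         (structure$name[j] == "C" && structure$name[i] == "N" &&
            structure$resno[i] == structure$resno[j] + 1L))
    keep[k] <- !same_res && !pep_bond
  }
  hits <- hits[keep, , drop = FALSE]
  tibble::tibble(atom_i = heavy[hits[, 1L]], atom_j = heavy[hits[, 2L]],
                 distance = dm[hits])
}

#' Fragment plan for a secondary-structure rebuild
#'
#' @param chain,start,end Parallel vectors: chain id and inclusive
#'   residue-number range of each kept fragment.
#' @param label Optional secondary-structure labels.
#' @return A `fragment_plan` tibble.
#' @export
fragment_plan <- function(chain, start, end, label = "fragment") {
  plan <- tibble::tibble(chain = chain, start = start, end = end,
                         label = rep_len(label, length(chain)))
  if (any(plan$end < plan$start)) {
    rlang::abort("fragment end before start", class = "dipolecd_input_error")
  }
  for (ch in unique(plan$chain)) {
    pc <- dplyr::arrange(plan[plan$chain == ch, ], .data$start)
    if (nrow(pc) > 1L && any(pc$start[-1L] <= pc$end[-nrow(pc)])) {
      rlang::abort("overlapping fragments in plan",
                   class = "dipolecd_input_error")
    }
  }
  class(plan) <- c("fragment_plan", class(plan))
  plan
}

#' Rebuild planned fragments with idealized geometry
#'
#' Residues outside the plan are dropped; non-treated residue types are
#' mutated to alanine first; each kept fragment's backbone torsions are
#' measured from the input structure and the fragment is rebuilt with the
#' ideal internal-coordinate table (omega retained from the structure by
#' default). Fragments whose rebuild produces steric collisions are
#' discarded, worst offender first, until the remainder is collision
#' free. If the residues ignored (unplanned + discarded) exceed 50% of
#' the protein the rebuild is declared a failure.
#'
#' @param structure A `protein_structure`.
#' @param plan A `fragment_plan`.
#' @param geometry Ideal internal-coordinate table.
#' @param hydrogens Add ideal hydrogens to the rebuilt fragments.
#' @param idealize_omega Replace measured omega by 180 degrees.
#' @param collision_cutoff Heavy-atom collision threshold, Angstrom.
#' @param max_ignored_fraction Failure threshold on the ignored-residue
#'   fraction (default 0.5).
#' @return A `protein_structure` with one chain per surviving fragment;
#'   attributes `ignored_fraction` and `dropped_fragments` record the
#'   bookkeeping.
#' @export
rebuild_from_structure <- function(structure, plan,
                                   geometry = ideal_geometry(),
                                   hydrogens = FALSE,
                                   idealize_omega = FALSE,
                                   collision_cutoff = 2.0,
                                   max_ignored_fraction = 0.5) {
  p_total <- n_residues(structure)
  structure <- alanize(structure)
  tors <- measure_torsions(structure)

  frags <- list()
  for (f in seq_len(nrow(plan))) {
    sel <- tors$chain == plan$chain[f] &
      tors$resno >= plan$start[f] & tors$resno <= plan$end[f]
    if (!any(sel)) {
      rlang::abort(sprintf("plan fragment %s %d-%d not found in structure",
                           plan$chain[f], plan$start[f], plan$end[f]),
                   class = "dipolecd_input_error")
    }
    ft <- tors[sel, ]
    resid <- structure |>
      tibble::as_tibble() |>
      dplyr::filter(.data$chain == plan$chain[f],
                    .data$resno %in% ft$resno, .data$name == "CA") |>
      dplyr::arrange(.data$resno) |>
      dplyr::pull("resid")
    rec <- chain_recipe(resid, phi = ft$phi, psi = ft$psi,
                        omega = if (idealize_omega) 180 else ft$omega)
    # the last residue's psi has no following N; recover it from the
    # carbonyl O so the terminal O rebuilds in place
    last <- nrow(rec)
    rec$psi[last] <- psi_from_carbonyl(structure, plan$chain[f],
                                       max(ft$resno))
    rec$omega[1L] <- 180
    rec$phi[1L] <- 0
    frags[[f]] <- list(recipe = rec, resno_start = min(ft$resno),
                       n = nrow(rec))
  }

  build_all <- function(active) {
    built <- purrr::imap(frags[active], function(fr, k) {
      build_chain(fr$recipe, hydrogens = hydrogens, geometry = geometry,
                  chain = LETTERS[((k - 1L) %% 26L) + 1L],
                  resno_start = fr$resno_start)
    })
    # separate the fragments in space along x so only genuinely
    # self-colliding fragments register collisions
    offset <- 0
    for (k in seq_along(built)) {
      span <- range(built[[k]]$x)
      built[[k]]$x <- built[[k]]$x - span[1L] + offset
      offset <- offset + (span[2L] - span[1L]) + 10
    }
    dplyr::bind_rows(built)
  }

  active <- seq_along(frags)
  dropped <- integer(0)
  repeat {
    combined <- build_all(active)
    coll <- detect_collisions(new_protein_structure(combined,
                                                    check_backbone = FALSE),
                              cutoff = collision_cutoff)
    if (!nrow(coll)) break
    # discard the fragment owning the most colliding atoms
    frag_of <- function(idx) {
      chn <- combined$chain[idx]
      active[match(chn, LETTERS[seq_along(active)])]
    }
    counts <- table(c(vapply(coll$atom_i, frag_of, numeric(1)),
                      vapply(coll$atom_j, frag_of, numeric(1))))
    worst <- as.integer(names(counts)[which.max(counts)])
    dropped <- c(dropped, worst)
    active <- setdiff(active, worst)
    if (!length(active)) break
  }

  kept_res <- sum(vapply(frags[active], `[[`, numeric(1), "n"))
  ignored_fraction <- 1 - kept_res / p_total
  if (ignored_fraction > max_ignored_fraction) {
    rlang::abort(sprintf(
      "rebuild failure: %.0f%% of the protein ignored (limit %.0f%%)",
      100 * ignored_fraction, 100 * max_ignored_fraction),
      class = "dipolecd_rebuild_failure")
  }

  out <- new_protein_structure(build_all(active), check_backbone = FALSE)
  attr(out, "ignored_fraction") <- ignored_fraction
  attr(out, "dropped_fragments") <- dropped
  out
}
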