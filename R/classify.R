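# Atom classification: amide chromophore triads, isotropic points, and
# ignored atoms. The amide N-C'-O group of each peptide bond becomes one
# anisotropic chromophoric point; aliphatic carbons, alcohol oxygens and
# (optionally) hydrogens become isotropic points; everything else is
# dropped with a logged reason.

ALIPHATIC_RESIDUES <- c("ALA", "VAL", "PRO", "GLY", "LEU", "ILE")
ALCOHOL_OXYGENS <- c("OG", "OG1", "OH")

#' Replace non-aliphatic side chains with alanine
#'
#' Residues outside the treated aliphatic set (ALA, VAL, PRO, GLY, LEU,
#' ILE) lose all side-chain atoms beyond C-beta (hydrogens riding on
#' removed heavy atoms go with them) and are renamed ALA. Backbone and
#' C-beta coordinates are untouched; glycine passes through.
#'
#' @param structure A `protein_structure`.
#' @return A `protein_structure` with only aliphatic residue types.
#' @export
alanize <- function(structure) {
  keep_heavy <- c("N", "CA", "C", "O", "OXT", "CB")
  is_h <- structure$element == "H"
  mutate_res <- !(structure$resid %in% ALIPHATIC_RESIDUES)

  heavy_kept <- !is_h & (!mutate_res | structure$name %in% keep_heavy)

  # hydrogens survive only if still riding on a kept heavy atom
  hk <- which(heavy_kept)
  keep <- heavy_kept
  for (i in which(is_h)) {
    if (!mutate_res[i]) {
      keep[i] <- TRUE
      next
    }
    same_res <- hk[structure$chain[hk] == structure$chain[i] &
                     structure$resno[hk] == structure$resno[i]]
    if (length(same_res)) {
      d2 <- (structure$x[same_res] - structure$x[i])^2 +
        (structure$y[same_res] - structure$y[i])^2 +
        (structure$z[same_res] - structure$z[i])^2
      keep[i] <- any(d2 < 1.25^2)
    }
  }

  out <- structure[keep, ]
  out$resid[!(out$resid %in% ALIPHATIC_RESIDUES)] <- "ALA"
  class(out) <- class(structure)
  out
}

#' Classify atoms into chromophoric, isotropic and ignored sets
#'
#' One amide triad (N of residue i+1, C' and O of residue i) is created
#' per peptide bond; a bond requires consecutive residue numbering within
#' the same chain and a C'-N distance below 2 Angstrom (anything else is
#' treated as a chain break). Aliphatic carbons and alcohol oxygens become
#' isotropic points. Hydrogens are included only on request, are assigned
#' a species from the heavy atom they ride on, and methyl-group hydrogens
#' can be deleted (the united-atom reduction). Atoms with no isotropic
#' parameter (S, P, metals, terminal carboxyl groups, the free N-terminal
#' amine) are ignored with a reason code.
#'
#' @param structure A `protein_structure` with at least 2 residues.
#' @param include_hydrogens Treat hydrogens as isotropic points.
#' @param drop_methyl_hydrogens Delete hydrogens of CH3 groups (carbons
#'   with exactly three attached hydrogens and one heavy neighbour).
#' @return A `unit_classification`: list with tibbles `triads` (one row
#'   per peptide bond, with N/C'/O coordinates), `isotropic` (atoms plus
#'   `species`), `ignored` (atoms plus `reason`), and the residue count
#'   `p` and oscillator count `q`.
#' @export
classify_units <- function(structure, include_hydrogens = FALSE,
                           drop_methyl_hydrogens = TRUE) {
  if (n_residues(structure) < 2) {
    rlang::abort("structure needs at least 2 residues to form an amide",
                 class = "dipolecd_input_error")
  }

  atoms <- tibble::as_tibble(structure)
  atoms$.atom <- seq_len(nrow(atoms))

  res <- atoms |>
    dplyr::distinct(.data$chain, .data$resno) |>
    dplyr::mutate(.res = dplyr::row_number())
  atoms <- dplyr::left_join(atoms, res, by = c("chain", "resno"))

  get_atom <- function(res_row, nm) {
    hit <- atoms[atoms$.res == res_row & atoms$name == nm, ]
    if (!nrow(hit)) {
      rlang::abort(sprintf("residue %s%d lacks backbone atom %s",
                           res$chain[res_row], res$resno[res_row], nm),
                   class = "dipolecd_missing_atom")
    }
    hit[1L, ]
  }

  # peptide bonds: consecutive numbering in one chain + C'-N < 2 A
  triads <- list()
  donor_res <- integer(0)   # residues contributing C', O
  acceptor_res <- integer(0) # residues contributing N
  for (k in seq_len(nrow(res) - 1L)) {
    i <- k; j <- k + 1L
    if (res$chain[i] != res$chain[j]) next
    if (res$resno[j] != res$resno[i] + 1L) next
    ci <- get_atom(i, "C"); nj <- get_atom(j, "N"); oi <- get_atom(i, "O")
    d <- sqrt((ci$x - nj$x)^2 + (ci$y - nj$y)^2 + (ci$z - nj$z)^2)
    if (d >= 2.0) next
    triads[[length(triads) + 1L]] <- tibble::tibble(
      chain = res$chain[i], res_i = res$resno[i], res_j = res$resno[j],
      n_atom = nj$.atom, c_atom = ci$.atom, o_atom = oi$.atom,
      n_x = nj$x, n_y = nj$y, n_z = nj$z,
      c_x = ci$x, c_y = ci$y, c_z = ci$z,
      o_x = oi$x, o_y = oi$y, o_z = oi$z
    )
    donor_res <- c(donor_res, i)
    acceptor_res <- c(acceptor_res, j)
  }
  triads <- if (length(triads)) dplyr::bind_rows(triads) else
    tibble::tibble()
  if (!nrow(triads)) {
    rlang::abort("no peptide bond found (no amide chromophore)",
                 class = "dipolecd_input_error")
  }

  chromo_atoms <- c(triads$n_atom, triads$c_atom, triads$o_atom)

  # geometric connectivity for hydrogens and methyl detection
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  is_h <- atoms$element == "H"
  heavy_idx <- which(!is_h)
  h_parent <- rep(NA_integer_, nrow(atoms))
  for (i in which(is_h)) {
    d2 <- (xyz[heavy_idx, 1] - xyz[i, 1])^2 +
      (xyz[heavy_idx, 2] - xyz[i, 2])^2 +
      (xyz[heavy_idx, 3] - xyz[i, 3])^2
    jmin <- which.min(d2)
    if (length(jmin) && d2[jmin] < 1.25^2) h_parent[i] <- heavy_idx[jmin]
  }

  # CH3 carbon: exactly 3 hydrogens (< 1.2 A) and exactly 1 heavy
  # neighbour (< 1.8 A)
  methyl_carbon <- rep(FALSE, nrow(atoms))
  for (i in heavy_idx[atoms$element[heavy_idx] == "C"]) {
    kids <- which(!is.na(h_parent) & h_parent == i)
    if (length(kids)) {
      dk <- sqrt((xyz[kids, 1] - xyz[i, 1])^2 + (xyz[kids, 2] - xyz[i, 2])^2 +
                   (xyz[kids, 3] - xyz[i, 3])^2)
      nh <- sum(dk < 1.2)
    } else {
      nh <- 0L
    }
    others <- setdiff(heavy_idx, i)
    d2 <- (xyz[others, 1] - xyz[i, 1])^2 + (xyz[others, 2] - xyz[i, 2])^2 +
      (xyz[others, 3] - xyz[i, 3])^2
    n_heavy <- sum(d2 < 1.8^2)
    if (nh == 3L && n_heavy == 1L) methyl_carbon[i] <- TRUE
  }

  category <- rep(NA_character_, nrow(atoms))
  species <- rep(NA_character_, nrow(atoms))
  reason <- rep(NA_character_, nrow(atoms))

  category[chromo_atoms] <- "chromophore"

  for (i in seq_len(nrow(atoms))) {
    if (!is.na(category[i])) next
    el <- atoms$element[i]
    nm <- atoms$name[i]
    if (el == "C") {
      # aliphatic carbon; a C' not in any triad is a terminal carboxyl
      if (nm == "C") {
        category[i] <- "ignored"; reason[i] <- "terminal carboxyl carbon"
      } else {
        category[i] <- "isotropic"; species[i] <- "C_aliphatic"
      }
    } else if (el == "O") {
      if (nm %in% ALCOHOL_OXYGENS) {
        category[i] <- "isotropic"; species[i] <- "O_alcohol"
      } else if (nm == "OXT") {
        category[i] <- "ignored"; reason[i] <- "terminal carboxylate oxygen"
      } else if (nm == "O") {
        category[i] <- "ignored"; reason[i] <- "terminal carbonyl oxygen"
      } else {
        category[i] <- "ignored"; reason[i] <- "unparameterized oxygen"
      }
    } else if (el == "N") {
      # backbone N not in a triad = free N-terminal amine; side-chain N
      # has no isotropic parameter either
      category[i] <- "ignored"
      reason[i] <- if (nm == "N") "free N-terminal amine nitrogen"
        else "unparameterized nitrogen"
    } else if (el == "H") {
      if (!include_hydrogens) {
        category[i] <- "ignored"; reason[i] <- "hydrogens excluded"
      } else if (is.na(h_parent[i])) {
        category[i] <- "ignored"; reason[i] <- "hydrogen with no bonded heavy atom"
      } else {
        p <- h_parent[i]
        pel <- atoms$element[p]
        if (pel == "C" && methyl_carbon[p] && drop_methyl_hydrogens) {
          category[i] <- "ignored"; reason[i] <- "methyl hydrogen (united atom)"
        } else if (pel == "C") {
          category[i] <- "isotropic"; species[i] <- "H_aliphatic"
        } else if (pel == "O" && atoms$name[p] %in% ALCOHOL_OXYGENS) {
          category[i] <- "isotropic"; species[i] <- "H_alcohol"
        } else if (pel == "N") {
          category[i] <- "isotropic"; species[i] <- "H_amide"
        } else {
          category[i] <- "ignored"; reason[i] <- "hydrogen on unparameterized atom"
        }
      }
    } else {
      category[i] <- "ignored"
      reason[i] <- paste0("unparameterized element ", el)
    }
  }

  iso <- atoms[category == "isotropic",
               c("name", "element", "resno", "resid", "chain",
                 "x", "y", "z", ".atom")]
  iso$species <- species[category == "isotropic"]
  ign <- atoms[category == "ignored",
               c("name", "element", "resno", "resid", "chain", ".atom")]
  ign$reason <- reason[category == "ignored"]

  if (any(atoms$resid == "PRO")) {
    rlang::inform("proline residues present: amide chromophore parameters applied unchanged to N-alkylated amides")
  }

  structure(
    list(triads = triads, isotropic = iso, ignored = ign,
         p = n_residues(structure), q = nrow(triads)),
    class = "unit_classification"
  )
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf(
    "<unit_classification> p = %d residues, q = %d amide triads, %d isotropic atoms, %d ignored\n",
    x$p, x$q, nrow(x$isotropic), nrow(x$ignored)))
  invisible(x)
}

#' Tidy an atom classification into one long table
#'
#' @param x A `unit_classification`.
#' @param ... Unused.
#' @return Tibble with one row per classified atom and columns `atom`,
#'   `category` and `detail` (species or ignore reason; triad role for
#'   chromophore atoms).
#' @method tidy unit_classification
#' @export
tidy.unit_classification <- function(x, ...) {
  tri <- tibble::tibble(
    atom = c(x$triads$n_atom, x$triads$c_atom, x$triads$o_atom),
    category = "chromophore",
    detail = rep(c("amide N", "amide C'", "amide O"), each = nrow(x$triads))
  )
  iso <- tibble::tibble(atom = x$isotropic$.atom, category = "isotropic",
                        detail = x$isotropic$species)
  ign <- tibble::tibble(atom = x$ignored$.atom, category = "ignored",
                        detail = x$ignored$reason)
  dplyr::arrange(dplyr::bind_rows(tri, iso, ign), .data$atom)
}

#' Write a classification report as TSV
#'
#' @param classification A `unit_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(tidy.unit_classification(classification), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
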