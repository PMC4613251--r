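#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (HETATM records are dropped), resolves alternate
#' locations by keeping the highest-occupancy copy (ties broken by the
#' alphabetically first altloc label), and returns the atoms of one model
#' as a tibble. Chain and residue order of the file is preserved.
#'
#' @param path Path to a PDB file.
#' @param model Model number to extract (1-based), for multi-model
#'   (NMR-style) files. Default 1.
#' @param check_backbone If `TRUE` (default), every residue must carry the
#'   N, CA, C and O backbone atoms; a residue missing one raises an error
#'   naming it.
#'
#' @return A `protein_structure`: a tibble with one row per atom and
#'   columns `name`, `element`, `resno`, `resid`, `chain`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`.
#' @export
read_pdb <- function(path, model = 1, check_backbone = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("PDB file not found: ", path),
                 class = "dipolecd_input_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      rlang::abort(paste0("failed to parse PDB file: ", conditionMessage(e)),
                   class = "dipolecd_format_error")
    }
  )

  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!any(keep)) {
    rlang::abort("no ATOM records in file (HETATM-only or empty structure)",
                 class = "dipolecd_empty_structure")
  }

  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    rlang::abort(sprintf("model %d requested but file has %d model(s)",
                         model, n_models),
                 class = "dipolecd_input_error")
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)

  atoms <- tibble::tibble(
    name      = trimws(at$elety),
    element   = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
    resno     = at$resno,
    resid     = trimws(at$resid),
    chain     = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x         = xyz[, 1L],
    y         = xyz[, 2L],
    z         = xyz[, 3L],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc    = trimws(ifelse(is.na(at$alt), "", at$alt))
  )[keep, ]

  atoms <- resolve_altloc(atoms)
  atoms$element <- infer_element(atoms$name, atoms$element)
  new_protein_structure(atoms, check_backbone = check_backbone)
}

# Keep the highest-occupancy alternate location per (chain, resno, name);
# ties go to the alphabetically first altloc label.
resolve_altloc <- function(atoms) {
  atoms |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

# Element from the element field when present, else the first alphabetic
# character of the atom name (handles 1HB vs HB1 hydrogen dialects).
infer_element <- function(name, element = "") {
  element <- toupper(trimws(element))
  fallback <- toupper(substr(gsub("^[^A-Za-z]*", "", name), 1L, 1L))
  two <- toupper(name) %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA2")
  out <- ifelse(element == "", fallback, element)
  out[two & element == ""] <- toupper(name[two & element == ""])
  out
}

#' Construct a protein structure from an atom table
#'
#' @param atoms Tibble (or data frame) with columns `name`, `element`,
#'   `resno`, `resid`, `chain`, `x`, `y`, `z`; `occupancy` and `altloc`
#'   are filled in when absent.
#' @param check_backbone Require N, CA, C, O in every residue.
#' @return A `protein_structure` tibble.
#' @export
new_protein_structure <- function(atoms, check_backbone = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("name", "element", "resno", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    rlang::abort(paste0("atom table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "dipolecd_input_error")
  }
  if (!nrow(atoms)) {
    rlang::abort("empty atom table", class = "dipolecd_empty_structure")
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    rlang::abort("non-finite coordinates in atom table",
                 class = "dipolecd_input_error")
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""

  if (check_backbone) {
    bad <- atoms |>
      dplyr::group_by(.data$chain, .data$resno, .data$resid) |>
      dplyr::summarise(
        ok = all(c("N", "CA", "C", "O") %in% .data$name),
        .groups = "drop"
      ) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad)) {
      rlang::abort(
        paste0("residue(s) missing backbone atoms (N/CA/C/O): ",
               paste(sprintf("%s %s%d", bad$resid, bad$chain, bad$resno),
                     collapse = ", ")),
        class = "dipolecd_missing_atom"
      )
    }
  }
  class(atoms) <- c("protein_structure", class(tibble::tibble()))
  atoms
}

#' Number of residues in a structure
#'
#' @param structure A `protein_structure`.
#' @return Integer count of distinct (chain, residue) pairs, the residue
#'   count `p` entering the per-residue spectral normalization.
#' @export
n_residues <- function(structure) {
  nrow(dplyr::distinct(structure, .data$chain, .data$resno))
}

#' Write a structure to a PDB file
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  xyz <- as.numeric(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = structure$resno, resid = structure$resid,
    eleno = seq_len(nrow(structure)), elety = structure$name,
    chain = structure$chain, o = structure$occupancy,
    b = rep(0, nrow(structure)), elesy = structure$element
  )
  invisible(path)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %d atoms, %d residues, %d chain(s)\n",
              nrow(x), n_residues(x), length(unique(x$chain))))
  NextMethod()
}
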