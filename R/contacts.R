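#' Atomic structure as a tidy atom table
#'
#' A structure is a tibble with one row per atom and columns `chain`,
#' `resno` (residue number), `resid` (3-letter residue name), `elety`
#' (atom name) and Cartesian coordinates `x`, `y`, `z` in Angstrom.
#'
#' @param atoms Data frame with the columns above.
#' @return Validated tibble of class `jm_structure`.
#' @export
as_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    abort_param("atoms", paste("needs columns", paste(need, collapse = ", ")))
  }
  if (nrow(atoms) < 1) {
    rlang::abort("structure must contain at least one atom",
                 class = "junctionmech_structure_error")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rlang::abort("non-finite atom coordinates",
                 class = "junctionmech_structure_error")
  }
  out <- tibble::as_tibble(atoms[need])
  class(out) <- c("jm_structure", class(out))
  out
}

#' Read a structure from a PDB file
#'
#' @param path PDB file path.
#' @param model Model number for multi-model files (default 1).
#' @return A [as_structure()] tibble.
#' @export
read_pdb_structure <- function(path, model = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  as_structure(tibble::tibble(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

#' Write a structure to a PDB file
#'
#' @param structure A [as_structure()] tibble.
#' @param path Output path.
#' @export
write_pdb_structure <- function(structure, path) {
  s <- as_structure(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(s[c("x", "y", "z")]))),
                   resno = s$resno, resid = s$resid, chain = s$chain,
                   elety = s$elety)
  invisible(path)
}

#' Residue centres of geometry
#'
#' Unweighted mean of the atom coordinates of each residue.
#'
#' @param structure A [as_structure()] tibble.
#' @return Tibble with one row per residue: `chain`, `resno`, `resid`,
#'   `x`, `y`, `z`, `n_atoms`, in the order residues first appear.
#' @export
residue_cog <- function(structure) {
  s <- as_structure(structure)
  s |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno)
}

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

aa_one <- function(resid) {
  one <- AA_321[toupper(resid)]
  ifelse(is.na(one), "X", one)
}

# Grid (cell-list) accelerated radius search between two COG sets.
# Returns integer matrix of index pairs (i into a, j into b) with dist <= cutoff.
grid_pairs <- function(a, b, cutoff) {
  cell <- function(m) floor(m / cutoff)
  ca <- cell(a); cb <- cell(b)
  key <- function(cm) paste(cm[, 1], cm[, 2], cm[, 3])
  bkey <- key(cb)
  bmap <- split(seq_len(nrow(b)), bkey)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    neigh <- sweep(shifts, 2, ca[i, ], "+")
    js <- unlist(bmap[paste(neigh[, 1], neigh[, 2], neigh[, 3])],
                 use.names = FALSE)
    if (length(js) == 0) next
    d2 <- (b[js, 1] - a[i, 1])^2 + (b[js, 2] - a[i, 2])^2 + (b[js, 3] - a[i, 3])^2
    hit <- js[d2 <= cutoff^2 + 1e-12]
    if (length(hit)) out[[i]] <- cbind(i, hit, sqrt(d2[d2 <= cutoff^2 + 1e-12]))
  }
  do.call(rbind, out %||% list()) %||% matrix(numeric(0), ncol = 3)
}

#' Residue contact map between a peptide and a domain
#'
#' A peptide residue and a domain residue are in contact when the Euclidean
#' distance between their centres of geometry is at most `cutoff` (inclusive
#' boundary). Peptide positions are labelled backwards from the C-terminus:
#' `C-1` is the last residue, `C-2` the one before it, and so on, the
#' convention used for PDZ-binding motifs. Domain residues are labelled by
#' one-letter code and residue number (e.g. `L321`). The search is
#' cell-list accelerated; it is exactly equivalent to the all-pairs search.
#'
#' @param peptide,domain Structures ([as_structure()] tibbles).
#' @param cutoff Contact cutoff in Angstrom (default 6.5).
#' @return Tibble of class `contact_map`: `peptide_position`, `peptide_resno`,
#'   `peptide_resid`, `domain_residue`, `domain_resno`, `distance`.
#' @export
contact_map <- function(peptide, domain, cutoff = 6.5) {
  check_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  pc <- residue_cog(peptide)
  dc <- residue_cog(domain)
  pm <- as.matrix(pc[c("x", "y", "z")])
  dm <- as.matrix(dc[c("x", "y", "z")])
  hits <- grid_pairs(pm, dm, cutoff)
  n_pep <- nrow(pc)
  out <- tibble::tibble(
    peptide_position = character(0), peptide_resno = integer(0),
    peptide_resid = character(0), domain_residue = character(0),
    domain_resno = integer(0), distance = numeric(0))
  if (nrow(hits) > 0) {
    i <- hits[, 1]; j <- hits[, 2]
    out <- tibble::tibble(
      peptide_position = paste0("C-", n_pep - i + 1L),
      peptide_resno = pc$resno[i],
      peptide_resid = pc$resid[i],
      domain_residue = paste0(aa_one(dc$resid[j]), dc$resno[j]),
      domain_resno = dc$resno[j],
      distance = hits[, 3]) |>
      dplyr::arrange(.data$peptide_resno, .data$domain_resno)
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "n_peptide") <- n_pep
  class(out) <- c("contact_map", class(out))
  out
}

#' Summarise a contact map per peptide residue
#'
#' Produces the per-position contact listing (position, residue, contact list,
#' `-` when none) and the count of peptide residues with at least one contact.
#'
#' @param map A [contact_map()] tibble, or any tibble with
#'   `peptide_position` and `domain_residue` columns.
#' @param n_peptide Peptide length; defaults to the `n_peptide` attribute of
#'   the map.
#' @param residues Optional character vector of one-letter peptide residue
#'   codes in N-to-C order, used to fill the `residue` column.
#' @return List with `contacting_residues` (count) and `table` (tibble with
#'   columns `position`, `residue`, `contacts`, `n_contacts`).
#' @export
summarize_contact_table <- function(map, n_peptide = NULL, residues = NULL) {
  n_peptide <- n_peptide %||% attr(map, "n_peptide")
  if (is.null(n_peptide)) abort_param("n_peptide", "must be supplied")
  pos_num <- as.integer(sub("^C-", "", map$peptide_position))
  if (length(pos_num) && max(pos_num) > n_peptide) {
    abort_param("n_peptide", "smaller than a referenced peptide position")
  }
  tab <- tibble::tibble(position = paste0("C-", seq_len(n_peptide)))
  if (!is.null(residues)) {
    # residues given N-to-C; C-1 is the last
    tab$residue <- rev(residues)[seq_len(n_peptide)]
  } else if (nrow(map) > 0 && "peptide_resid" %in% names(map)) {
    lookup <- stats::setNames(aa_one(map$peptide_resid), map$peptide_position)
    tab$residue <- unname(lookup[tab$position])
  } else {
    tab$residue <- NA_character_
  }
  agg <- if (nrow(map) > 0) {
    map |>
      dplyr::group_by(position = .data$peptide_position) |>
      dplyr::summarise(contacts = paste(.data$domain_residue, collapse = " "),
                       n_contacts = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(position = character(0), contacts = character(0),
                   n_contacts = integer(0))
  }
  tab <- dplyr::left_join(tab, agg, by = "position") |>
    dplyr::mutate(
      n_contacts = dplyr::coalesce(.data$n_contacts, 0L),
      contacts = dplyr::coalesce(.data$contacts, "-"))
  list(contacting_residues = sum(tab$n_contacts > 0), table = tab)
}

#' Classify residues as hydrophobic or hydrophilic from parch values
#'
#' The parch hydropathy scale runs from 0 to 10; values strictly below the
#' threshold (default 1) mark hydrophobic character.
#'
#' @param parch Data frame with columns `residue` (or `position`) and `parch`.
#' @param threshold Classification threshold (default 1; strict `<`).
#' @return Input tibble with an added `class` column
#'   (`"hydrophobic"`/`"hydrophilic"`).
#' @export
classify_hydropathy <- function(parch, threshold = 1.0) {
  if (!is.data.frame(parch) || !"parch" %in% names(parch)) {
    abort_param("parch", "must be a data frame with a `parch` column")
  }
  if (any(!is.finite(parch$parch)) || any(parch$parch < 0 | parch$parch > 10)) {
    rlang::abort("parch values must lie in [0, 10]",
                 class = "junctionmech_validation_error")
  }
  dplyr::mutate(tibble::as_tibble(parch),
                class = ifelse(.data$parch < threshold,
                               "hydrophobic", "hydrophilic"))
}

#' Count water molecules contacting each residue
#'
#' A water counts as contacting a residue when its oxygen lies within
#' `cutoff_nm` (default 0.315 nm = 3.15 Angstrom) of any atom of the residue
#' (`mode = "atom"`), or of the residue's centre of geometry
#' (`mode = "cog"`). Structural coordinates are in Angstrom; the nm cutoff is
#' converted internally at this single site.
#'
#' @param structure A [as_structure()] tibble.
#' @param waters Data frame of water oxygen coordinates with columns
#'   `x`, `y`, `z` in Angstrom.
#' @param cutoff_nm Contact cutoff in nm.
#' @param mode `"atom"` (minimum atom-oxygen distance) or `"cog"`.
#' @return Tibble `chain`, `resno`, `resid`, `n_waters`.
#' @export
count_water_contacts <- function(structure, waters, cutoff_nm = 0.315,
                                 mode = c("atom", "cog")) {
  mode <- match.arg(mode)
  s <- as_structure(structure)
  check_number(cutoff_nm, "cutoff_nm", lower = 0, strict_lower = TRUE)
  if (!all(c("x", "y", "z") %in% names(waters))) {
    abort_param("waters", "needs columns x, y, z")
  }
  if (nrow(waters) > 0 && !all(is.finite(as.matrix(waters[c("x", "y", "z")])))) {
    abort_param("waters", "coordinates must be finite")
  }
  cutoff_A <- cutoff_nm * 10
  res <- residue_cog(s)
  if (nrow(waters) == 0) {
    return(dplyr::mutate(res[c("chain", "resno", "resid")], n_waters = 0L))
  }
  wm <- as.matrix(waters[c("x", "y", "z")])
  counts <- vapply(seq_len(nrow(res)), function(i) {
    if (mode == "cog") {
      am <- as.matrix(res[i, c("x", "y", "z")])
    } else {
      sel <- s$chain == res$chain[i] & s$resno == res$resno[i]
      am <- as.matrix(s[sel, c("x", "y", "z")])
    }
    d2min <- vapply(seq_len(nrow(wm)), function(w) {
      min((am[, 1] - wm[w, 1])^2 + (am[, 2] - wm[w, 2])^2 +
            (am[, 3] - wm[w, 3])^2)
    }, numeric(1))
    sum(d2min <= cutoff_A^2 + 1e-12)
  }, numeric(1))
  dplyr::mutate(res[c("chain", "resno", "resid")], n_waters = as.integer(counts))
}
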