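#' JAM-A C-terminal tail / ZO-2 PDZ-2 reference tables
#'
#' Reference inputs for the JAM-A (junctional adhesion molecule A) 10-mer
#' tail bound to the second PDZ domain of ZO-2: the published per-residue
#' parch hydropathy values and residue-contact lists at the 6.5-Angstrom
#' centre-of-geometry cutoff. Positions are labelled backwards from the
#' C-terminus (`C-1` = C-terminal valine of the ...SFLV motif).
#'
#' @return `jam_pdz2_contact_table()`: tibble with columns `position`,
#'   `residue`, `parch`, `contacts` (space-separated domain residues, `-`
#'   when none). `jam_tail_sequence()` and `zo2_pdz2_sequence()` return the
#'   one-letter sequences (tail N-to-C; PDZ-2 numbering starts at 306).
#' @export
jam_pdz2_contact_table <- function() {
  tibble::tibble(
    position = paste0("C-", 1:10),
    residue  = c("V", "L", "F", "S", "S", "T", "Q", "K", "F", "E"),
    parch    = c(0.9, 0.4, 0.1, 0.2, 0.0, 0.2, 0.1, 1.3, 0.3, 2.2),
    contacts = c("L321 L323 I370 R367",
                 "R322",
                 "G324 L363 R367",
                 "R322 K330 E331",
                 "-",
                 "-",
                 "G347 S325 K330",
                 "-",
                 "Q326 F328",
                 "G347"))
}

#' @rdname jam_pdz2_contact_table
#' @export
jam_tail_sequence <- function() "EFKQTSSFLV"

#' @rdname jam_pdz2_contact_table
#' @export
zo2_pdz2_sequence <- function() {
  paste0("IGVLLMKSRANEEYGLRLGSQIFVKEMTRTGLATKDGNLHEGDIILKINGTVTENMSLTD",
         "ARKLIEKSRGKLQLVVLRDSQ")
}

#' @rdname jam_pdz2_contact_table
#' @param table A tibble in the shape of [jam_pdz2_contact_table()].
#' @return `contact_table_to_map()`: a long contact tibble (one row per
#'   peptide-domain contact pair) usable with [summarize_contact_table()].
#' @export
contact_table_to_map <- function(table = jam_pdz2_contact_table()) {
  out <- table |>
    dplyr::filter(.data$contacts != "-") |>
    dplyr::mutate(domain_residue = strsplit(.data$contacts, "\\s+")) |>
    tidyr::unnest("domain_residue") |>
    dplyr::transmute(peptide_position = .data$position,
                     peptide_residue = .data$residue,
                     domain_residue = .data$domain_residue)
  attr(out, "n_peptide") <- nrow(table)
  out
}
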