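# Readers/writers for the plain-text and TIFF interchange formats.

#' Read and write force-indentation curves as CSV
#'
#' Curves are stored with columns `indentation_nm,force_nN`, plus `curve_id`
#' in long multi-curve files.
#'
#' @param path CSV file, or a directory of one-curve CSV files (read).
#' @return Tibble with `curve_id`, `indentation_nm`, `force_nN`.
#' @export
read_force_curves <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  purrr::map(files, function(f) {
    df <- readr::read_csv(f, show_col_types = FALSE)
    if (!"curve_id" %in% names(df)) {
      df$curve_id <- tools::file_path_sans_ext(basename(f))
    }
    df
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("curve_id", "indentation_nm", "force_nN")
}

#' @rdname read_force_curves
#' @param data Long tibble of curves (with `curve_id`) or one curve.
#' @export
write_force_curves <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and write umbrella-sampling windows as CSV
#'
#' Long format with columns `center_nm,k_kJ_mol_nm2,sample_nm`; a directory
#' of per-window files is concatenated.
#'
#' @param path CSV file or directory (read); output file (write).
#' @return Long window tibble accepted by [wham()].
#' @export
read_umbrella_windows <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  purrr::map(files, readr::read_csv, show_col_types = FALSE) |>
    dplyr::bind_rows() |>
    dplyr::select("center_nm", "k_kJ_mol_nm2", "sample_nm")
}

#' @rdname read_umbrella_windows
#' @param data Long window tibble.
#' @export
write_umbrella_windows <- function(data, path) {
  readr::write_csv(data[c("center_nm", "k_kJ_mol_nm2", "sample_nm")], path)
  invisible(path)
}

#' Read and write three-channel FRET image sets as multi-page TIFF
#'
#' Page order is donor, acceptor, FRET. Images are stored as 16-bit
#' greyscale; intensities are de/re-scaled by `2^16 - 1`, so integer counts
#' up to 65535 round-trip exactly.
#'
#' @param path TIFF path.
#' @return A [fret_imageset()].
#' @export
read_fret_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) abort_param("path", "multi-page TIFF needs 3 pages")
  scale <- 2^16 - 1
  fret_imageset(round(pages[[1]] * scale), round(pages[[2]] * scale),
                round(pages[[3]] * scale))
}

#' @rdname read_fret_tiff
#' @param images A [fret_imageset()] with counts in `[0, 65535]`.
#' @export
write_fret_tiff <- function(images, path) {
  stopifnot(inherits(images, "fret_imageset"))
  scale <- 2^16 - 1
  tiff::writeTIFF(lapply(images[c("donor", "acceptor", "fret")],
                         function(m) m / scale),
                  path, bits.per.sample = 16)
  invisible(path)
}

#' Read/write an ROI label mask as single-page TIFF
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * (2^16 - 1))), nrow(m), ncol(m))
}

#' @rdname read_label_tiff
#' @param labels Integer label matrix (0 = background).
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / (2^16 - 1), path, bits.per.sample = 16)
  invisible(path)
}

#' Write a contact summary table as CSV
#'
#' Columns `position,residue,parch,contacts`, mirroring the published
#' per-residue listing; `parch` is filled with NA unless supplied.
#'
#' @param summary Result of [summarize_contact_table()].
#' @param path Output CSV path.
#' @param parch Optional parch values in C-1..C-n order.
#' @export
write_contact_table <- function(summary, path, parch = NULL) {
  tab <- summary$table
  tab$parch <- parch %||% NA_real_
  readr::write_csv(tab[c("position", "residue", "parch", "contacts")], path)
  invisible(path)
}

#' Write a PMF profile and its summary
#'
#' The profile goes to CSV (`xi_nm,free_energy_kJ_mol,error_kJ_mol`); the
#' binding-energy extraction and convergence diagnostics go to a JSON
#' sidecar.
#'
#' @param fit A `pmf_fit` from [wham()].
#' @param path Output CSV path; the JSON summary is written next to it.
#' @export
write_pmf_profile <- function(fit, path) {
  stopifnot(inherits(fit, "pmf_fit"))
  readr::write_csv(fit$profile[c("xi_nm", "free_energy_kJ_mol", "error_kJ_mol")],
                   path)
  be <- binding_energy(fit)
  jsonlite::write_json(list(
    delta_g_kJ_mol = be$delta_g_kJ_mol, error_kJ_mol = be$error_kJ_mol,
    xi_min_nm = be$xi_min_nm, converged = fit$converged,
    iterations = fit$iterations, n_windows = fit$n_windows,
    temperature_K = fit$temperature),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
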