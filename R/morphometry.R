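# Cell-shape metrics and monolayer hole quantification on labelled masks.

# Connected-component labelling of a logical matrix by BFS flood fill.
# connectivity 4 or 8.
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  }
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier) > 0) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb[k, 1]; cc <- c + nb[k, 2]
        okp <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        idx <- (cc[okp] - 1L) * nr + rr[okp]
        idx <- idx[mask[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

region_pixels <- function(region) {
  if (is.matrix(region) && is.logical(region)) return(which(region))
  abort_param("region", "must be a logical mask matrix")
}

#' Cell area from a region mask
#'
#' @param region Logical mask of one cell.
#' @param pixel_size Pixel edge length in micrometres.
#' @return Area in square micrometres.
#' @export
cell_area <- function(region, pixel_size = 1) {
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  px <- region_pixels(region)
  if (length(px) == 0) {
    rlang::abort("empty region", class = "junctionmech_region_error")
  }
  length(px) * pixel_size^2
}

#' Aspect ratio of a region from its equivalent ellipse
#'
#' Major-to-minor axis ratio of the ellipse with the same second central
#' moments as the region. The per-pixel moment includes the 1/12 square-pixel
#' term, so rasterised rectangles return their exact side ratio. The result
#' is rotation-invariant and always >= 1.
#'
#' @param region Logical mask of one cell.
#' @return Dimensionless aspect ratio.
#' @export
aspect_ratio <- function(region) {
  px <- region_pixels(region)
  if (length(px) < 3) {
    rlang::abort("region needs at least 3 pixels",
                 class = "junctionmech_geometry_error")
  }
  nr <- nrow(region)
  r <- ((px - 1L) %% nr) + 1L
  c <- ((px - 1L) %/% nr) + 1L
  xy <- cbind(r, c)
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  cov0 <- crossprod(d) / length(px)
  if (abs(det(cov0)) < 1e-9) {
    rlang::abort("degenerate (collinear) region; aspect ratio undefined",
                 class = "junctionmech_geometry_error")
  }
  covp <- cov0 + diag(1 / 12, 2)      # square-pixel second moment
  ev <- eigen(covp, symmetric = TRUE)$values
  sqrt(ev[1] / ev[2])
}

#' Shape metrics for every labelled region
#'
#' @param labels Integer label matrix (0 = background) or logical mask.
#' @param pixel_size Pixel edge length in micrometres.
#' @return Tibble `label`, `area_um2`, `aspect_ratio`.
#' @export
cell_shape_metrics <- function(labels, pixel_size = 1) {
  if (is.logical(labels)) labels <- label_components(labels)
  ids <- sort(unique(labels[labels > 0]))
  purrr::map(ids, function(l) {
    m <- labels == l
    tibble::tibble(label = l, area_um2 = cell_area(m, pixel_size),
                   aspect_ratio = tryCatch(aspect_ratio(m),
                                           error = function(e) NA_real_))
  }) |> dplyr::bind_rows()
}

#' Quantify holes in a monolayer mask
#'
#' Holes are connected components (4-connectivity) of the background that are
#' fully enclosed by foreground — components touching the image border are
#' gaps, not holes, and are excluded. Components smaller than `min_area`
#' (in square micrometres) are treated as noise.
#'
#' @param mask Logical monolayer mask (`TRUE` = covered by cells).
#' @param min_area Minimum hole area retained, in square micrometres.
#' @param pixel_size Pixel edge length in micrometres.
#' @return One-row tibble `holes_per_field`, `hole_area_per_field_um2`; the
#'   per-hole table is in attribute `holes`.
#' @export
quantify_holes <- function(mask, min_area = 10, pixel_size = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  lab <- label_components(!mask, connectivity = 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(unique(lab[lab > 0]), border)
  holes <- tibble::tibble(label = integer(0), area_um2 = numeric(0))
  if (length(keep) > 0) {
    holes <- tibble::tibble(
      label = keep,
      area_um2 = vapply(keep, function(l) sum(lab == l) * pixel_size^2,
                        numeric(1))) |>
      dplyr::filter(.data$area_um2 >= min_area)
  }
  out <- tibble::tibble(
    holes_per_field = nrow(holes),
    hole_area_per_field_um2 = sum(holes$area_um2))
  attr(out, "holes") <- holes
  out
}
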