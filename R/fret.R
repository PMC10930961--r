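#' Three-channel FRET image set
#'
#' Container for one acquisition of a ratiometric tension-sensor experiment:
#' donor channel (donor emission under donor excitation), acceptor channel
#' (acceptor emission under acceptor excitation) and FRET channel (acceptor
#' emission under donor excitation), as numeric matrices of equal size in
#' detector counts.
#'
#' @param donor,acceptor,fret Numeric matrices of identical dimensions.
#' @return An object of class `fret_imageset`.
#' @export
fret_imageset <- function(donor, acceptor, fret) {
  chans <- list(donor = donor, acceptor = acceptor, fret = fret)
  for (nm in names(chans)) {
    if (!is.matrix(chans[[nm]]) || !is.numeric(chans[[nm]])) {
      abort_param(nm, "must be a numeric matrix")
    }
  }
  if (!all(vapply(chans, function(m) identical(dim(m), dim(donor)), logical(1)))) {
    abort_param("images", "all three channels must have identical dimensions")
  }
  structure(chans, class = "fret_imageset")
}

#' @export
print.fret_imageset <- function(x, ...) {
  cat(sprintf("<fret_imageset %d x %d> mean counts donor %.1f, acceptor %.1f, FRET %.1f\n",
              nrow(x$donor), ncol(x$donor),
              mean(x$donor), mean(x$acceptor), mean(x$fret)))
  invisible(x)
}

#' Background-subtract all three channels equally
#'
#' Subtracts the same constant from donor, acceptor and FRET channels
#' (`method = "constant"`), or a per-channel low-percentile estimate of the
#' background (`method = "percentile"`). Negative results are clamped to 0.
#'
#' @param images A [fret_imageset()].
#' @param method `"constant"` or `"percentile"`.
#' @param value Background in counts (constant method) or percentile in
#'   (0, 100) (percentile method).
#' @return Background-subtracted `fret_imageset`; the values subtracted are in
#'   attribute `background`. Warns when clamping zeroed an entire channel.
#' @export
subtract_background <- function(images, method = c("constant", "percentile"),
                                value = 0) {
  stopifnot(inherits(images, "fret_imageset"))
  method <- match.arg(method)
  if (method == "constant") {
    check_number(value, "value", lower = 0)
    bg <- c(donor = value, acceptor = value, fret = value)
  } else {
    if (!is.numeric(value) || length(value) != 1 || value <= 0 || value >= 100) {
      abort_param("value", "percentile must lie strictly in (0, 100)")
    }
    bg <- vapply(images[c("donor", "acceptor", "fret")],
                 function(m) unname(stats::quantile(m, value / 100)), numeric(1))
  }
  out <- images
  for (nm in c("donor", "acceptor", "fret")) {
    sub <- images[[nm]] - bg[[nm]]
    if (all(sub <= 0) && any(images[[nm]] > 0)) {
      rlang::warn(sprintf("background exceeds every pixel in the %s channel; clamped to zero", nm))
    }
    out[[nm]] <- pmax(sub, 0)
  }
  attr(out, "background") <- bg
  out
}

roi_list <- function(rois, dim_ref) {
  # Accept a label matrix (integer labels, 0 = outside), a single logical
  # mask, or a named list of logical masks.
  if (is.matrix(rois) && is.logical(rois)) rois <- list(roi_1 = rois)
  if (is.matrix(rois)) {
    labs <- sort(unique(rois[rois > 0]))
    rois <- stats::setNames(
      lapply(labs, function(l) rois == l),
      paste0("roi_", labs))
  }
  if (!is.list(rois) || length(rois) == 0) {
    abort_param("rois", "must be a label matrix, a logical mask, or a list of masks")
  }
  if (is.null(names(rois)) || any(names(rois) == "")) {
    names(rois) <- paste0("roi_", seq_along(rois))
  }
  for (nm in names(rois)) {
    m <- rois[[nm]]
    if (!is.matrix(m) || !is.logical(m) || !identical(dim(m), dim_ref)) {
      abort_param("rois", sprintf("mask `%s` must be logical with image dimensions", nm))
    }
    if (!any(m)) {
      rlang::abort(sprintf("ROI `%s` is empty", nm),
                   class = "junctionmech_degenerate_roi_error")
    }
  }
  rois
}

roi_means <- function(images, roi) {
  c(donor = mean(images$donor[roi]),
    acceptor = mean(images$acceptor[roi]),
    fret = mean(images$fret[roi]))
}

#' Estimate spectral bleed-through coefficients from single-fluorophore controls
#'
#' Donor bleed-through is the FRET-channel to donor-channel mean-intensity
#' ratio in donor-only control ROIs; acceptor bleed-through is the
#' FRET-to-acceptor ratio in acceptor-only control ROIs. Per-ROI ratios are
#' pooled by unweighted mean.
#'
#' @param donor_only,acceptor_only Background-subtracted [fret_imageset()]s of
#'   the single-fluorophore control constructs.
#' @param donor_rois,acceptor_rois ROIs for each control: label matrix,
#'   logical mask, or list of logical masks.
#' @return An object of class `sbt_coefficients`: list with `sbt_donor`,
#'   `sbt_acceptor`, `n_rois_used`, and the per-ROI ratios.
#' @export
estimate_sbt <- function(donor_only, donor_rois, acceptor_only, acceptor_rois) {
  stopifnot(inherits(donor_only, "fret_imageset"),
            inherits(acceptor_only, "fret_imageset"))
  one_side <- function(images, rois, denom_channel) {
    rois <- roi_list(rois, dim(images$donor))
    vapply(names(rois), function(nm) {
      m <- roi_means(images, rois[[nm]])
      if (m[[denom_channel]] <= 0) {
        rlang::abort(sprintf("ROI `%s` has zero mean %s intensity; cannot form bleed-through ratio",
                             nm, denom_channel),
                     class = "junctionmech_degenerate_roi_error")
      }
      m[["fret"]] / m[[denom_channel]]
    }, numeric(1))
  }
  rd <- one_side(donor_only, donor_rois, "donor")
  ra <- one_side(acceptor_only, acceptor_rois, "acceptor")
  structure(list(sbt_donor = mean(rd), sbt_acceptor = mean(ra),
                 n_rois_used = length(rd) + length(ra),
                 donor_ratios = rd, acceptor_ratios = ra),
            class = "sbt_coefficients")
}

#' @export
print.sbt_coefficients <- function(x, ...) {
  cat(sprintf("SBT coefficients: donor %.4f, acceptor %.4f (%d control ROIs)\n",
              x$sbt_donor, x$sbt_acceptor, x$n_rois_used))
  invisible(x)
}

#' Bleed-through-corrected FRET signal of one ROI
#'
#' \eqn{cFRET = \bar I_{FRET} - SBT_{donor}\,\bar I_{donor} -
#' SBT_{acceptor}\,\bar I_{acceptor}} over the ROI pixels.
#'
#' @param images Background-subtracted [fret_imageset()].
#' @param sbt An [estimate_sbt()] result (or list with `sbt_donor`,
#'   `sbt_acceptor`).
#' @param roi Logical mask with the image dimensions.
#' @return cFRET in counts (may be negative; callers flag rather than clamp).
#' @export
corrected_fret <- function(images, sbt, roi) {
  stopifnot(inherits(images, "fret_imageset"))
  roi <- roi_list(roi, dim(images$donor))[[1]]
  m <- roi_means(images, roi)
  unname(m["fret"] - sbt$sbt_donor * m["donor"] - sbt$sbt_acceptor * m["acceptor"])
}

#' FRET index of one ROI
#'
#' Corrected FRET normalised by the ROI's mean acceptor intensity, which
#' cancels expression-level differences: index = cFRET / mean(acceptor).
#'
#' @inheritParams corrected_fret
#' @param cfret cFRET of the same ROI in counts (from [corrected_fret()]).
#' @return Dimensionless FRET index.
#' @export
fret_index <- function(cfret, images, roi) {
  stopifnot(inherits(images, "fret_imageset"))
  roi <- roi_list(roi, dim(images$donor))[[1]]
  acc <- mean(images$acceptor[roi])
  if (acc <= 0) {
    rlang::abort("ROI has zero mean acceptor intensity; FRET index undefined",
                 class = "junctionmech_degenerate_roi_error")
  }
  cfret / acc
}

#' Quantify junctional FRET indices for a full experiment
#'
#' Runs the whole pipeline: equal background subtraction of every image set,
#' bleed-through estimation from the donor-only and acceptor-only controls,
#' then per-ROI corrected FRET and FRET index for each sensor group.
#'
#' @param sensors Named list of groups; each element is
#'   `list(images = fret_imageset, rois = <label matrix | mask | list>)`.
#' @param donor_only,acceptor_only Control sets in the same
#'   `list(images=, rois=)` form.
#' @param background Constant background in counts, or percentile when
#'   `background_method = "percentile"`.
#' @param background_method Passed to [subtract_background()].
#' @return Tibble with columns `group`, `roi_id`, `cfret`, `fret_index`,
#'   `flagged` (`TRUE` where cFRET < 0); the fitted [estimate_sbt()]
#'   coefficients are attached as attribute `sbt`.
#' @export
quantify_junctions <- function(sensors, donor_only, acceptor_only,
                               background = 0, background_method = "constant") {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("[%s] %s", what, conditionMessage(e)), parent = e)
    })
  }
  sub <- function(x) subtract_background(x, background_method, background)
  d0 <- stage("background", sub(donor_only$images))
  a0 <- stage("background", sub(acceptor_only$images))
  sbt <- stage("estimate_sbt",
               estimate_sbt(d0, donor_only$rois, a0, acceptor_only$rois))

  rows <- purrr::imap(sensors, function(grp, gname) {
    imgs <- stage("background", sub(grp$images))
    rois <- stage("rois", roi_list(grp$rois, dim(imgs$donor)))
    purrr::imap(rois, function(roi, rname) {
      cf <- stage("corrected_fret", corrected_fret(imgs, sbt, roi))
      idx <- stage("fret_index", fret_index(cf, imgs, roi))
      tibble::tibble(group = gname, roi_id = rname, cfret = cf,
                     fret_index = idx, flagged = cf < 0)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(rows, "sbt") <- sbt
  rows
}

#' Intensity linescan across an image
#'
#' Samples the image along the segment from `p0` to `p1` at one-pixel pitch,
#' averaging `width` nearest-pixel samples taken perpendicular to the segment.
#' Distances are reported relative to the segment midpoint, so a junction
#' centred on the midpoint peaks at distance 0.
#'
#' @param image Numeric matrix.
#' @param p0,p1 Segment endpoints as `c(row, col)` in pixel units (1-based).
#' @param width Averaging width in pixels, >= 1.
#' @param pixel_size Physical pixel size (micrometres per pixel) used for the
#'   distance axis.
#' @return Tibble with columns `distance_um`, `intensity`.
#' @export
linescan <- function(image, p0, p1, width = 1, pixel_size = 1) {
  stopifnot(is.matrix(image), length(p0) == 2, length(p1) == 2)
  if (width < 1) abort_param("width", "must be >= 1")
  inside <- function(p) all(p >= 1) && p[1] <= nrow(image) && p[2] <= ncol(image)
  if (!inside(p0) || !inside(p1)) {
    rlang::abort("linescan segment endpoints fall outside the image",
                 class = "junctionmech_geometry_error")
  }
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) abort_param("p1", "segment has zero length")
  u <- v / len                      # along-segment unit vector (row, col)
  perp <- c(-u[2], u[1])
  t_steps <- seq(0, len, by = 1)
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  intensity <- vapply(t_steps, function(t) {
    pts <- lapply(offsets, function(o) p0 + t * u + o * perp)
    vals <- vapply(pts, function(p) {
      r <- min(max(round(p[1]), 1), nrow(image))
      c <- min(max(round(p[2]), 1), ncol(image))
      image[r, c]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  tibble::tibble(distance_um = (t_steps - len / 2) * pixel_size,
                 intensity = intensity)
}

#' Rasterise a polygon ROI to a logical mask
#'
#' Even-odd fill evaluated at pixel centres; vertex coordinates are 0-based
#' `(row, col)` pairs, matching coordinates exported by common image tools.
#'
#' @param vertices Two-column matrix or data frame of 0-based (row, col)
#'   polygon vertices.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical mask matrix.
#' @export
polygon_mask <- function(vertices, dim) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) abort_param("vertices", "need >= 3 (row, col) vertices")
  nr <- dim[1]; nc <- dim[2]
  ys <- v[, 1]; xs <- v[, 2]
  mask <- matrix(FALSE, nr, nc)
  # pixel centres at 0-based integer coordinates
  px <- rep(0:(nc - 1), each = nr)
  py <- rep(0:(nr - 1), times = nc)
  n <- nrow(v)
  crossings <- integer(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- ys[i]; yj <- ys[j]; xi <- xs[i]; xj <- xs[j]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crossings <- crossings + as.integer(hit)
    j <- i
  }
  mask[cbind(py + 1, px + 1)] <- crossings %% 2L == 1L
  mask
}
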