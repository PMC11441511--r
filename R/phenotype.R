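#' Cell spreading area from a traced outline
#'
#' Shoelace area of the outline polygon in pixel units, scaled to square
#' micrometres by `pixel_size^2`. Orientation-independent.
#'
#' @param x,y Vertex coordinates in pixels (>= 3 vertices, simple polygon
#'   assumed).
#' @param pixel_size Pixel edge length in micrometres (default 1).
#' @return Area in square micrometres.
#' @examples
#' spreading_area(c(0, 10, 10, 0), c(0, 0, 10, 10))  # 100
#' @export
spreading_area <- function(x, y, pixel_size = 1) {
  stopifnot(length(x) == length(y), pixel_size > 0)
  if (length(x) < 3L) stop("an outline needs at least 3 vertices")
  xs <- c(x, x[1]); ys <- c(y, y[1])
  n <- length(x)
  a <- 0.5 * abs(sum(xs[1:n] * ys[2:(n + 1)] - xs[2:(n + 1)] * ys[1:n]))
  a * pixel_size^2
}

#' Read cell outlines from TSV
#'
#' Columns `cell_id, vertex_index, x_px, y_px`; vertices ordered by
#' `vertex_index` within each cell.
#'
#' @param path TSV path.
#' @param pixel_size Pixel edge length in micrometres.
#' @return data.frame `cell_id, area_um2`.
#' @export
read_outline_areas <- function(path, pixel_size = 1) {
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("cell_id", "vertex_index", "x_px", "y_px") %in% names(dt)))
  data.table::setorder(dt, cell_id, vertex_index)
  x_px <- y_px <- cell_id <- NULL
  out <- dt[, list(area_um2 = spreading_area(x_px, y_px, pixel_size)),
            by = cell_id]
  as.data.frame(out)
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' `[(nuclear mean) - (background mean)] / [(cytoplasmic mean) -
#' (background mean)]`. Ratios above 1 indicate nuclear enrichment of the
#' stained protein (a mechanoactive state for YAP).
#'
#' @param nuclear_mean,cytoplasmic_mean,background_mean Mean intensities
#'   (arbitrary units, vectorized).
#' @return Dimensionless ratio; `NA` with a warning where the
#'   background-subtracted cytoplasmic intensity is not positive.
#' @examples
#' nc_ratio(1000, 500, 100)  # 2.25
#' @export
nc_ratio <- function(nuclear_mean, cytoplasmic_mean, background_mean = 0) {
  stopifnot(all(nuclear_mean >= 0), all(cytoplasmic_mean >= 0))
  denom <- cytoplasmic_mean - background_mean
  bad <- denom <= 0
  if (any(bad)) {
    warning("cytoplasmic mean not above background for ", sum(bad),
            " cell(s); ratio undefined")
    denom[bad] <- NA_real_
  }
  (nuclear_mean - background_mean) / denom
}

#' Measure the N/C ratio from an image and masks
#'
#' Means are taken over the nuclear mask and over the cytoplasmic region
#' (the cell mask minus the nuclear mask). Background defaults to the mean
#' over pixels outside the cell mask unless a dedicated background mask is
#' supplied.
#'
#' @param image Numeric intensity matrix.
#' @param nuc_mask,cell_mask Logical matrices, same shape as `image`; the
#'   nuclear mask must lie inside the cell mask.
#' @param bg_mask Optional logical background mask.
#' @return List: `nuclear_mean`, `cytoplasmic_mean`, `background_mean`,
#'   `ratio`.
#' @export
measure_nc_from_image <- function(image, nuc_mask, cell_mask,
                                  bg_mask = NULL) {
  stopifnot(all(dim(image) == dim(nuc_mask)),
            all(dim(image) == dim(cell_mask)))
  cyto <- cell_mask & !nuc_mask
  if (!any(nuc_mask) || !any(cyto))
    stop("empty nuclear or cytoplasmic region")
  bg <- if (is.null(bg_mask)) !cell_mask else bg_mask
  nm <- mean(image[nuc_mask])
  cm <- mean(image[cyto])
  bm <- if (any(bg)) mean(image[bg]) else 0
  list(nuclear_mean = nm, cytoplasmic_mean = cm, background_mean = bm,
       ratio = nc_ratio(nm, cm, bm))
}

#' Normalized RhoA activation
#'
#' Lysate luminescence divided by the positive-control protein signal.
#'
#' @param lysate_signal Lysate luminescence (vectorized).
#' @param positive_control_signal Positive-control luminescence, > 0.
#' @return Dimensionless normalized activation.
#' @export
normalize_rho <- function(lysate_signal, positive_control_signal) {
  if (any(positive_control_signal <= 0))
    stop("positive control signal must be positive")
  lysate_signal / positive_control_signal
}

#' Compare two groups of phenotype values
#'
#' `mann_whitney`: two-sided Mann-Whitney U, exact null when the smaller
#' group has at most `exact_max` values and there are no ties, otherwise
#' the tie-corrected normal approximation. `welch_anova`: Welch's
#' unequal-variance one-way test.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param test `"mann_whitney"` (default) or `"welch_anova"`.
#' @param exact_max Largest min-group size for the exact Mann-Whitney null
#'   (default 8).
#' @return The two-sided p-value.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "welch_anova"),
                           exact_max = 8) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (test == "mann_whitney") {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && min(length(a), length(b)) <= exact_max
    stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value
  } else {
    vals <- c(a, b)
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    stats::oneway.test(vals ~ grp, var.equal = FALSE)$p.value
  }
}
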