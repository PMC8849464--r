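#' Georeferenced raster surface
#'
#' Minimal raster container: a numeric matrix (row 1 = northernmost row),
#' square cell size in metres, lower-left corner origin, and `NA` for nodata.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, x/y of the lower-left corner of the grid.
#' @param kind `"continuous"` or `"categorical"`.
#' @param classes for categorical rasters, the declared class values.
#' @return an object of class `raster_surface`.
#' @export
raster_surface <- function(values, cell_size, origin = c(0, 0),
                           kind = c("continuous", "categorical"),
                           classes = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) stop("raster has non-positive dimensions")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be positive")
  if (any(!is.finite(values) & !is.na(values))) stop("raster values must be finite or NA")
  if (kind == "categorical") {
    if (is.null(classes)) classes <- sort(unique(values[!is.na(values)]))
    bad <- !is.na(values) & !(values %in% classes)
    if (any(bad)) stop("categorical raster has values outside the declared class list")
  }
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin), kind = kind, classes = classes),
            class = "raster_surface")
}

#' @export
print.raster_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_surface: %d x %d cells of %g m (%s)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$kind))
  cat(sprintf("  range [%g, %g], %d nodata cells\n",
              min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of every cell
#'
#' @param raster a `raster_surface`.
#' @return data.frame with `row`, `col`, `x`, `y` (projected metres).
#' @export
cell_centres <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  g$x <- raster$origin[1] + (g$col - 0.5) * raster$cell_size
  # row 1 is the northern edge
  g$y <- raster$origin[2] + (nr - g$row + 0.5) * raster$cell_size
  g
}

## nearest valid cell (row, col) for projected coordinates
coords_to_cell <- function(raster, x, y) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  col <- pmin(pmax(ceiling((x - raster$origin[1]) / raster$cell_size), 1L), nc)
  row <- pmin(pmax(nr - ceiling((y - raster$origin[2]) / raster$cell_size) + 1L, 1L), nr)
  cbind(row = row, col = col)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path of a `.asc` grid.
#' @param kind passed to [raster_surface()].
#' @return a `raster_surface`.
#' @export
read_ascii_grid <- function(path, kind = "continuous") {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  for (key in c("ncols", "nrows", "cellsize")) {
    if (!key %in% names(hdr)) stop("ASCII grid header missing ", key)
  }
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != hdr["ncols"] * hdr["nrows"]) {
    stop("ASCII grid body does not match declared dimensions")
  }
  vals <- matrix(body, nrow = hdr["nrows"], ncol = hdr["ncols"], byrow = TRUE)
  if ("nodata_value" %in% names(hdr)) vals[vals == hdr["nodata_value"]] <- NA
  xll <- if ("xllcorner" %in% names(hdr)) hdr[["xllcorner"]] else 0
  yll <- if ("yllcorner" %in% names(hdr)) hdr[["yllcorner"]] else 0
  raster_surface(vals, hdr[["cellsize"]], c(xll, yll), kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' @param raster a `raster_surface`.
#' @param path output path.
#' @param nodata numeric value written for `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(raster$origin[1], scientific = FALSE)),
    paste("yllcorner", format(raster$origin[2], scientific = FALSE)),
    paste("cellsize", format(raster$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rescale a raster to the common [1, 100] resistance input scale
#'
#' All candidate landscape surfaces are mapped onto the same scale (minimum 1,
#' maximum 100) before any resistance transformation, so transform parameters
#' are comparable across surfaces.
#'
#' @param raster a continuous `raster_surface`.
#' @return a `raster_surface` with valid cells affinely mapped to `[1, 100]`.
#' @export
rescale_surface <- function(raster) {
  v <- raster$values
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) stop("cannot rescale a constant raster")
  out <- 1 + (v - rng[1]) / diff(rng) * 99
  raster_surface(out, raster$cell_size, raster$origin, kind = raster$kind,
                 classes = NULL)
}

#' Pairwise Spearman correlation between co-registered surfaces
#'
#' Candidate surfaces entering a joint optimisation should be close to
#' uncorrelated; following Cohen's small-effect convention the function warns
#' when any absolute rank correlation reaches 0.29.
#'
#' @param rasters named list of co-registered `raster_surface` objects.
#' @param warn_level absolute rho at which to warn (default 0.29).
#' @return symmetric matrix of Spearman rho over jointly valid cells.
#' @export
surface_collinearity <- function(rasters, warn_level = 0.29) {
  stopifnot(length(rasters) >= 2)
  dims <- vapply(rasters, function(r) dim(r$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("rasters are misaligned: differing grid dimensions")
  }
  cs <- vapply(rasters, function(r) r$cell_size, numeric(1))
  if (any(abs(cs - cs[1]) > 1e-9)) stop("rasters are misaligned: differing cell size")
  vals <- vapply(rasters, function(r) as.vector(r$values),
                 numeric(length(rasters[[1]]$values)))
  ok <- stats::complete.cases(vals)
  rho <- stats::cor(vals[ok, , drop = FALSE], method = "spearman")
  if (is.null(names(rasters))) names(rasters) <- paste0("surface", seq_along(rasters))
  dimnames(rho) <- list(names(rasters), names(rasters))
  off <- abs(rho[lower.tri(rho)])
  if (any(off >= warn_level)) {
    warning(sprintf("surfaces are correlated: max |rho| = %.3f (threshold %.2f)",
                    max(off), warn_level))
  }
  rho
}

#' Monomolecular resistance transformation
#'
#' Maps a `[1, 100]`-scaled landscape raster to a resistance surface in
#' `[1, m]` through a saturating monomolecular curve. Eight variants span
#' increasing/decreasing responses, forward/reversed input, and the
#' convex inverse curve:
#' the base curve is `g(x') = (1 - exp(-x'/s)) / (1 - exp(-1/s))` on the unit
#' interval `x' = (x - 1)/99`; variants 1-4 are `g(x')`, `1 - g(x')`,
#' `g(1 - x')`, `1 - g(1 - x')`; variants 5-8 repeat these with the inverse
#' (convex) curve `h(x') = (exp(x'/s) - 1) / (exp(1/s) - 1)`. Resistance is
#' `R = 1 + (m - 1) * curve`.
#'
#' @param raster a `raster_surface` rescaled to `[1, 100]`.
#' @param variant integer 1-8.
#' @param shape positive shape parameter `s` (small = sharp saturation).
#' @param max_resistance maximum resistance `m`, in `(1, 100]` by convention.
#' @return a resistance `raster_surface` with values in `[1, max_resistance]`.
#' @export
monomolecular <- function(raster, variant, shape, max_resistance) {
  if (!variant %in% 1:8) stop("variant must be an integer in 1..8")
  if (!is.numeric(shape) || shape <= 0) stop("shape must be > 0")
  if (!is.numeric(max_resistance) || max_resistance <= 1) {
    stop("max_resistance must be > 1")
  }
  x <- (raster$values - 1) / 99
  x <- pmin(pmax(x, 0), 1)
  if (variant %in% c(3, 4, 7, 8)) x <- 1 - x
  g <- if (variant <= 4) {
    (1 - exp(-x / shape)) / (1 - exp(-1 / shape))
  } else {
    expm1(x / shape) / expm1(1 / shape)
  }
  if (variant %in% c(2, 4, 6, 8)) g <- 1 - g
  r <- 1 + (max_resistance - 1) * g
  r <- pmin(pmax(r, 1), max_resistance)
  raster_surface(r, raster$cell_size, raster$origin, kind = "continuous")
}

#' Reclassify a categorical raster to resistance values
#'
#' @param raster a categorical `raster_surface`.
#' @param class_values named numeric vector mapping each class to a resistance
#'   in `[1, 100]`; at least one (anchor) class must be exactly 1.
#' @return a continuous resistance `raster_surface`.
#' @export
reclassify_surface <- function(raster, class_values) {
  if (raster$kind != "categorical") stop("reclassify_surface needs a categorical raster")
  if (any(class_values < 1)) stop("resistance values must be >= 1")
  if (min(class_values) != 1) stop("one anchor class must have resistance exactly 1")
  missing_cls <- setdiff(raster$classes, as.numeric(names(class_values)))
  if (length(missing_cls)) {
    stop("no resistance value for class(es): ", paste(missing_cls, collapse = ", "))
  }
  v <- raster$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (cls in names(class_values)) {
    out[!is.na(v) & v == as.numeric(cls)] <- class_values[[cls]]
  }
  raster_surface(out, raster$cell_size, raster$origin, kind = "continuous")
}
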