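#' Percent tree-cover raster
#'
#' Container for one region-year grid of percent tree cover (0-100). Missing
#' cells (water masks, fill values) are `NA` and are always treated as
#' non-forest downstream.
#'
#' @param values numeric matrix of percent cover, values in \[0, 100\] or `NA`.
#' @param region_id region label.
#' @param year integer year.
#' @param cell_area area of one cell in km^2, or `NA` to work in cell units.
#'   The 231-m MODIS-VCF cell corresponds to 0.0534 km^2.
#' @return an object of class `cover_raster`.
#' @export
cover_raster <- function(values, region_id = "region", year = NA_integer_,
                         cell_area = NA_real_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("cover values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("grid must be at least 1x1")
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 100)) {
    stop("cover values must lie in [0, 100]")
  }
  structure(
    list(values = values, region_id = as.character(region_id),
         year = as.integer(year), cell_area = cell_area),
    class = "cover_raster"
  )
}

#' @export
print.cover_raster <- function(x, ...) {
  cat(sprintf("<cover_raster> %s year %s: %d x %d cells, cover %s-%s%%\n",
              x$region_id, x$year, nrow(x$values), ncol(x$values),
              format(min(x$values, na.rm = TRUE)),
              format(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Read a percent-cover grid from an ASCII file
#'
#' Whitespace-separated rows of integer percent cover; an optional ESRI-style
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) is recognised and skipped. NODATA cells become `NA`.
#'
#' @param path file path.
#' @param nodata sentinel value mapped to `NA`; overrides the header when
#'   given.
#' @inheritParams cover_raster
#' @return a [cover_raster()].
#' @export
read_ascii_grid <- function(path, region_id = "region", year = NA_integer_,
                            nodata = NULL, cell_area = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_pat <- "^\\s*(ncols|nrows|xllcorner|yllcorner|cellsize|NODATA_value)\\s"
  is_hdr <- grepl(hdr_pat, lines, ignore.case = TRUE)
  if (is.null(nodata)) {
    nd_line <- grep("^\\s*NODATA_value", lines, ignore.case = TRUE, value = TRUE)
    if (length(nd_line)) nodata <- as.numeric(strsplit(trimws(nd_line[1]), "\\s+")[[1]][2])
  }
  body <- lines[!is_hdr]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("ragged rows in ASCII grid: ", path)
  m <- do.call(rbind, rows)
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  cover_raster(m, region_id = region_id, year = year, cell_area = cell_area)
}

#' Write a cover raster as an ASCII grid (ESRI-style header)
#'
#' @param x a [cover_raster()].
#' @param path output path.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "cover_raster"))
  m <- x$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           "xllcorner 0", "yllcorner 0", "cellsize 1",
           sprintf("NODATA_value %g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a single-band TIFF of percent cover
#'
#' Reads the raster payload of a single-band (Geo)TIFF; georeferencing tags
#' are ignored. Requires the `tiff` package. Values already in \[0, 100\] are
#' used as-is; values in \[0, 1\] (normalised storage) are rescaled by 100.
#'
#' @inheritParams read_ascii_grid
#' @return a [cover_raster()].
#' @export
read_cover_tiff <- function(path, region_id = "region", year = NA_integer_,
                            cell_area = NA_real_) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF rasters requires the 'tiff' package")
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (max(m, na.rm = TRUE) > 100) {
    # float storage read raw: fall back to the normalised [0, 1] reading
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
  }
  if (max(m, na.rm = TRUE) <= 1) m <- m * 100
  cover_raster(m, region_id = region_id, year = year, cell_area = cell_area)
}

#' Binarise a cover raster at a percent threshold
#'
#' A cell is forest iff its cover is greater than or equal to the threshold;
#' missing cells are non-forest.
#'
#' @param cover a [cover_raster()] or a bare numeric matrix.
#' @param threshold percent cover threshold in (0, 100\].
#' @return a `binary_landscape`: logical forest mask plus metadata.
#' @export
binarize <- function(cover, threshold) {
  if (!inherits(cover, "cover_raster")) cover <- cover_raster(cover)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100) {
    stop("threshold must be a single percent in (0, 100]")
  }
  mask <- !is.na(cover$values) & cover$values >= threshold
  structure(
    list(mask = mask, threshold = threshold, region_id = cover$region_id,
         year = cover$year, cell_area = cover$cell_area),
    class = "binary_landscape"
  )
}

#' @export
print.binary_landscape <- function(x, ...) {
  cat(sprintf("<binary_landscape> %s year %s @%g%%: %d x %d, %d forest cells\n",
              x$region_id, x$year, x$threshold, nrow(x$mask), ncol(x$mask),
              sum(x$mask)))
  invisible(x)
}

as_binary_landscape <- function(x, threshold = NA_real_,
                                region_id = "region", year = NA_integer_,
                                cell_area = NA_real_) {
  if (inherits(x, "binary_landscape")) return(x)
  mask <- as.matrix(x)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  structure(
    list(mask = mask, threshold = threshold, region_id = region_id,
         year = year, cell_area = cell_area),
    class = "binary_landscape"
  )
}

#' Extract the Moore-neighbourhood patch census
#'
#' Labels maximal 8-connected (Moore neighbourhood) components of the forest
#' mask and returns the multiset of patch sizes with the largest-patch
#' summary statistics. Sizes are in cells, multiplied by `cell_area` when one
#' was supplied with the raster.
#'
#' @param land a `binary_landscape` (from [binarize()]) or a logical matrix.
#' @param periodic wrap the grid at its edges (used by the lattice
#'   simulators; empirical rasters are bounded so the default is `FALSE`).
#' @return a `patch_census` with fields `sizes`, `s_max`, `total_forest`,
#'   `rs_max` (`NA` when the landscape is empty), `n_patches`, `threshold`,
#'   `region_id`, `year`.
#' @export
label_patches <- function(land, periodic = FALSE) {
  land <- as_binary_landscape(land)
  labels <- .ccl_label(land$mask, periodic)
  nlab <- max(labels)
  sizes <- if (nlab == 0L) numeric(0) else tabulate(labels, nbins = nlab)
  unit <- if (is.na(land$cell_area)) 1 else land$cell_area
  sizes <- sizes * unit
  new_patch_census(sizes, land$threshold, land$region_id, land$year)
}

new_patch_census <- function(sizes, threshold, region_id, year) {
  total <- sum(sizes)
  structure(
    list(sizes = sizes,
         n_patches = length(sizes),
         s_max = if (length(sizes)) max(sizes) else 0,
         total_forest = total,
         rs_max = if (total > 0) max(sizes) / total else NA_real_,
         threshold = threshold, region_id = region_id, year = year),
    class = "patch_census"
  )
}

#' @export
print.patch_census <- function(x, ...) {
  cat(sprintf(
    "<patch_census> %s year %s @%s%%: %d patches, total %g, Smax %g (RSmax %s)\n",
    x$region_id, x$year, format(x$threshold), x$n_patches, x$total_forest,
    x$s_max, format(round(x$rs_max, 4))))
  invisible(x)
}

#' Patch censuses across a sweep of cover thresholds
#'
#' @param cover a [cover_raster()].
#' @param thresholds percent thresholds; the default 20-40% in 5% steps is
#'   the standard working range for MODIS-VCF forest definitions.
#' @return list of `patch_census`, one per threshold.
#' @export
census_sweep <- function(cover, thresholds = c(20, 25, 30, 35, 40)) {
  if (length(thresholds) < 1L) stop("thresholds must be non-empty")
  lapply(thresholds, function(th) label_patches(binarize(cover, th)))
}

#' Write patch sizes, one per line
#'
#' File layout mirrors the deposited patch-size archives:
#' `<region>_<year>_<threshold>.csv` with one size per line, no header.
#'
#' @param census a `patch_census`.
#' @param dir output directory (created if needed).
#' @return the path written, invisibly.
#' @export
write_patch_sizes <- function(census, dir = ".") {
  stopifnot(inherits(census, "patch_census"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_%s.csv", census$region_id,
                                 census$year, format(census$threshold)))
  writeLines(format(census$sizes, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Track the largest patch's identity across years
#'
#' Patch identity is followed by maximal spatial overlap: the largest patch
#' of year t is matched to the year t-1 patch sharing the most cells. An
#' overlap fraction near 1 means the same patch persisted; a drop signals a
#' break-up or identity switch of the largest patch.
#'
#' @param landscapes list of `binary_landscape` (same grid, ordered years).
#' @return data frame with `year`, `s_max`, `overlap_prev` (fraction of the
#'   current largest patch covered by the previous year's largest patch;
#'   `NA` for the first year), `same_patch` (overlap above 0.5).
#' @export
track_largest_patch <- function(landscapes) {
  stopifnot(length(landscapes) >= 1L)
  prev_mask <- NULL
  rows <- lapply(seq_along(landscapes), function(i) {
    land <- as_binary_landscape(landscapes[[i]])
    labels <- .ccl_label(land$mask, FALSE)
    nlab <- max(labels)
    if (nlab == 0L) {
      cur <- matrix(FALSE, nrow(land$mask), ncol(land$mask))
      smax <- 0
    } else {
      sizes <- tabulate(labels, nbins = nlab)
      cur <- labels == which.max(sizes)
      smax <- max(sizes)
    }
    ov <- if (is.null(prev_mask) || smax == 0) NA_real_
      else sum(cur & prev_mask) / sum(cur)
    prev_mask <<- cur
    data.frame(year = land$year, s_max = smax, overlap_prev = ov,
               same_patch = !is.na(ov) & ov > 0.5)
  })
  do.call(rbind, rows)
}

#' Export largest-patch masks as a PNG sequence
#'
#' Writes one greyscale PNG per year (forest grey, largest patch white,
#' background black) for quick animation of largest-patch dynamics.
#' Requires the `png` package.
#'
#' @param landscapes list of `binary_landscape`, ordered by year.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_largest_patch_pngs <- function(landscapes, dir = ".") {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("PNG export requires the 'png' package")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(landscapes), function(i) {
    land <- as_binary_landscape(landscapes[[i]])
    labels <- .ccl_label(land$mask, FALSE)
    img <- matrix(0, nrow(land$mask), ncol(land$mask))
    img[land$mask] <- 0.5
    if (max(labels) > 0L) {
      sizes <- tabulate(labels, nbins = max(labels))
      img[labels == which.max(sizes)] <- 1
    }
    path <- file.path(dir, sprintf("largest_patch_%03d.png", i))
    png::writePNG(img, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a patch-size file (one size per line)
#'
#' @param path file of sizes, one per line. Region/year/threshold are parsed
#'   from a `<region>_<year>_<threshold>.csv` filename when possible.
#' @return a `patch_census`.
#' @export
read_patch_sizes <- function(path) {
  sizes <- scan(path, what = numeric(), quiet = TRUE)
  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  region <- parts[1]
  year <- suppressWarnings(as.integer(parts[2]))
  threshold <- suppressWarnings(as.numeric(parts[3]))
  new_patch_census(sizes, threshold = threshold,
                   region_id = if (is.na(region)) "region" else region,
                   year = year)
}
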