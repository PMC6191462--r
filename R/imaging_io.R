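# Volumes, masks, ROIs and their on-disk formats.
#
# Geometry convention used throughout the package: voxel indices are 0-based
# and the world coordinate (mm) of voxel (i,j,k) is origin + index * spacing.
# All metric computation downstream happens in world mm, never in voxel units.

#' Construct a 3D scalar volume in Hounsfield units
#'
#' @param values numeric 3D array (HU); all values must be finite.
#' @param spacing numeric length-3 voxel spacing in mm, all `> 0`.
#' @param origin numeric length-3 world coordinate (mm) of voxel `(0,0,0)`.
#' @return An object of class `image_volume` with fields `values`,
#'   `spacing`, `origin`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (!all(is.finite(values))) stopf("image_volume: non-finite voxel values")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary mask aligned to an image volume
#'
#' @param values logical 3D array.
#' @param spacing,origin geometry, as in [image_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  storage.mode(values) <- "logical"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.2f%%)\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stopf("grids are not aligned (shape/spacing/origin mismatch)")
  }
  invisible(TRUE)
}

#' Half-open voxel region of interest
#'
#' Bounds are 0-based voxel indices; `lower` is inclusive, `upper` exclusive,
#' so the box contains `prod(upper - lower)` voxels.
#'
#' @param lower,upper integer length-3 bounds with `lower < upper` per axis.
#' @return An object of class `roi`.
#' @export
roi <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(lower < 0)) stopf("roi: negative lower bound")
  if (any(upper <= lower)) stopf("roi: upper must exceed lower on every axis")
  structure(list(lower = lower, upper = upper), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> [%s) x [%s) x [%s) voxels\n",
              paste(c(x$lower[1], x$upper[1]), collapse = ", "),
              paste(c(x$lower[2], x$upper[2]), collapse = ", "),
              paste(c(x$lower[3], x$upper[3]), collapse = ", ")))
  invisible(x)
}

roi_n_voxels <- function(r) prod(r$upper - r$lower)

roi_volume_mm3 <- function(r, spacing) prod((r$upper - r$lower) * spacing)

# logical index array for an roi
roi_index <- function(r) {
  list(x = (r$lower[1] + 1L):r$upper[1],
       y = (r$lower[2] + 1L):r$upper[2],
       z = (r$lower[3] + 1L):r$upper[3])
}

# NIfTI -----------------------------------------------------------------------

#' Read a volume from NIfTI or a DICOM series directory
#'
#' For NIfTI, spacing is taken from `pixdim` and the origin from the stored
#' transform. For a DICOM series directory, slices are sorted by their
#' position along the slice normal, checked for gaps, and stored values are
#' rescaled to HU via RescaleSlope/RescaleIntercept.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory containing one DICOM
#'   series (explicit VR little endian).
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stopf("read_volume: no such file: %s", path)
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stopf("read_volume: unknown format for '%s' (expected .nii/.nii.gz or DICOM directory)", path)
  }
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(spacing))) > 1e-3 * max(spacing)) {
    warning("read_volume: non axis-aligned transform; using pixdim spacing and translation only")
  }
  image_volume(vals, spacing, origin)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param vol an [image_volume()] or [binary_mask()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  if (is.logical(vals)) storage.mode(vals) <- "integer"
  attr(vals, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(vals, datatype = if (is.integer(vals)) "int32" else "double")
  mat <- diag(4)
  mat[1, 1] <- vol$spacing[1]; mat[2, 2] <- vol$spacing[2]; mat[3, 3] <- vol$spacing[3]
  mat[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Nonzero voxels become foreground.
#' @param path NIfTI path.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values != 0, v$spacing, v$origin)
}

# DICOM series ---------------------------------------------------------------
# Minimal reader for uncompressed explicit-VR little-endian series (no R DICOM
# package is available in the stack; only the handful of tags the pipeline
# needs are interpreted).

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_uint16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
read_uint32 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256 * as.integer(raw[off + 2L]) +
    65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM") {
    stopf("not a DICOM part-10 file: %s", path)
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  off <- 132L
  out <- list()
  n <- length(raw)
  while (off + 8L <= n) {
    group <- read_uint16(raw, off); elem <- read_uint16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (vr %in% long_vrs) {
      len <- read_uint32(raw, off + 8L)
      voff <- off + 12L
    } else {
      len <- read_uint16(raw, off + 6L)
      voff <- off + 8L
    }
    if (len < 0 || voff + len > n) break
    val <- raw[(voff + 1L):(voff + len)]
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") {
      out$transfer_syntax <- sub("\\s+$", "", rawToChar(val[val != as.raw(0)]))
    } else if (key == "0020,0032") {
      out$position <- as.numeric(strsplit(rawToChar(val), "\\\\")[[1]])
    } else if (key == "0020,0037") {
      out$orientation <- as.numeric(strsplit(rawToChar(val), "\\\\")[[1]])
    } else if (key == "0028,0010") {
      out$rows <- read_uint16(val, 0L)
    } else if (key == "0028,0011") {
      out$cols <- read_uint16(val, 0L)
    } else if (key == "0028,0030") {
      out$pixel_spacing <- as.numeric(strsplit(rawToChar(val), "\\\\")[[1]])
    } else if (key == "0028,0100") {
      out$bits <- read_uint16(val, 0L)
    } else if (key == "0028,0103") {
      out$pixrep <- read_uint16(val, 0L)
    } else if (key == "0028,1052") {
      out$intercept <- as.numeric(rawToChar(val))
    } else if (key == "0028,1053") {
      out$slope <- as.numeric(rawToChar(val))
    } else if (key == "7fe0,0010") {
      out$pixel_raw <- val
    }
    off <- voff + len
  }
  if (!is.null(out$transfer_syntax) && out$transfer_syntax != TS_EXPLICIT_LE) {
    stopf("unsupported DICOM transfer syntax '%s' in %s", out$transfer_syntax, path)
  }
  for (need in c("rows", "cols", "pixel_spacing", "position", "pixel_raw")) {
    if (is.null(out[[need]])) stopf("DICOM file %s lacks required element (%s)", path, need)
  }
  if (!is.null(out$bits) && out$bits != 16L) {
    stopf("only 16-bit DICOM pixel data supported (%s)", path)
  }
  signed <- isTRUE((out$pixrep %||% 0L) == 1L)
  px <- readBin(out$pixel_raw, what = "integer", size = 2L,
                n = out$rows * out$cols, signed = signed, endian = "little")
  # pixel data is row-major: first `cols` values form image row 0 (along x)
  out$pixels <- matrix(px, nrow = out$cols, ncol = out$rows)
  out$pixel_raw <- NULL
  out
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stopf("read_volume: empty DICOM directory %s", dir)
  slices <- lapply(sort(files), parse_dicom_file)

  ref <- slices[[1]]
  orient <- ref$orientation %||% c(1, 0, 0, 0, 1, 0)
  for (s in slices) {
    if (!is.null(s$orientation) && max(abs(s$orientation - orient)) > 1e-4) {
      stopf("mixed-orientation DICOM series in %s", dir)
    }
    if (s$rows != ref$rows || s$cols != ref$cols) {
      stopf("inconsistent slice dimensions in DICOM series %s", dir)
    }
  }
  r <- orient[1:3]; c3 <- orient[4:6]
  normal <- c(r[2] * c3[3] - r[3] * c3[2],
              r[3] * c3[1] - r[1] * c3[3],
              r[1] * c3[2] - r[2] * c3[1])
  if (max(abs(abs(orient) - c(1, 0, 0, 0, 1, 0))) > 1e-4) {
    stopf("oblique DICOM series unsupported (%s)", dir)
  }
  pos <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  dz <- diff(pos)
  if (length(dz) > 0) {
    med <- median(dz)
    if (med <= 0) stopf("duplicate slice positions in DICOM series %s", dir)
    bad <- which(abs(dz - med) > 0.01 * med)
    if (length(bad) > 0) {
      stopf("missing or unevenly spaced slice between positions %.3f and %.3f mm (step %.3f, expected %.3f)",
            pos[bad[1]], pos[bad[1] + 1L], dz[bad[1]], med)
    }
    dz <- med
  } else {
    dz <- 1
  }
  slope <- ref$slope %||% 1
  intercept <- ref$intercept %||% 0
  vals <- array(0, dim = c(ref$cols, ref$rows, length(slices)))
  for (k in seq_along(slices)) {
    vals[, , k] <- slope * slices[[k]]$pixels + intercept
  }
  spacing <- c(ref$pixel_spacing[2], ref$pixel_spacing[1], dz)
  image_volume(vals, spacing, origin = slices[[1]]$position)
}

# Vessel tree JSON ------------------------------------------------------------

#' Serialize a vessel tree to JSON
#'
#' Branch points are written in mm at full double precision; the round trip
#' through [read_tree()] is exact.
#'
#' @param tree a [vessel_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree"))
  for (b in tree$branches) {
    if (nrow(b) < 2) stopf("write_tree: branch with fewer than 2 points")
  }
  obj <- list(
    branches = lapply(tree$branches, function(b) unname(as.matrix(b))),
    node_types = tree$node_types,
    bifurcations = if (nrow(tree$bifurcations) > 0) unname(tree$bifurcations) else list(),
    degenerate = isTRUE(tree$degenerate)
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a vessel tree from JSON
#'
#' @param path JSON path written by [write_tree()].
#' @return A [vessel_tree()].
#' @export
read_tree <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("read_tree: malformed JSON in %s: %s",
                                            path, conditionMessage(e)))
  branches <- obj$branches
  if (is.null(branches) || length(branches) == 0) {
    return(vessel_tree(list(), degenerate = isTRUE(obj$degenerate)))
  }
  if (is.matrix(branches)) branches <- list(branches)
  branches <- lapply(branches, function(b) matrix(as.numeric(b), ncol = 3))
  nt <- obj$node_types
  if (is.matrix(nt)) nt <- lapply(seq_len(nrow(nt)), function(i) nt[i, ])
  bif <- obj$bifurcations
  bif <- if (length(bif) == 0) matrix(numeric(0), ncol = 3) else matrix(as.numeric(bif), ncol = 3)
  vessel_tree(branches, node_types = nt, bifurcations = bif,
              degenerate = isTRUE(obj$degenerate))
}

# Feature tables --------------------------------------------------------------

#' Write a cohort feature table to CSV
#'
#' Columns are `case_id`, `label`, then the feature columns (canonically the
#' 35 names of [qvt_feature_names()]). Non-finite feature values are written
#' as empty cells.
#'
#' @param rows data.frame with unique `case_id`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  stopifnot(is.data.frame(rows), all(c("case_id", "label") %in% names(rows)))
  if (anyDuplicated(rows$case_id)) stopf("write_feature_table: duplicate case_id")
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  for (cn in names(out)[num]) out[[cn]][!is.finite(out[[cn]])] <- NA
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort feature table from CSV
#'
#' @param path CSV written by [write_feature_table()].
#' @return A data.frame; if any feature cell was missing the result carries
#'   attribute `has_missing = TRUE`.
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(tab$case_id)) stopf("read_feature_table: duplicate case_id")
  feat <- setdiff(names(tab), c("case_id", "label"))
  for (cn in feat) tab[[cn]] <- as.numeric(tab[[cn]])
  if (any(vapply(tab[feat], function(x) any(is.na(x)), logical(1)))) {
    attr(tab, "has_missing") <- TRUE
  }
  tab
}
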