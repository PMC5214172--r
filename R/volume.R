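#' Construct a geometry-aware 3D image volume
#'
#' The container every analysis step consumes: a 3D numeric array plus the
#' physical geometry and acquisition metadata needed for quantitative work.
#' Voxel indices are 0-based in physical formulas; the physical coordinate of
#' voxel `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`, referring
#' to the voxel centre. Axis order is (transaxial-x, transaxial-y, axial-z);
#' the axial axis is the scanner (and phantom cylinder) axis.
#'
#' @param values Numeric 3D array.
#' @param spacing Length-3 positive voxel pitch in mm (x, y, z).
#' @param origin Length-3 physical coordinate in mm of the centre of voxel
#'   `[1, 1, 1]`.
#' @param modality `"PET"` or `"CT"`.
#' @param value_units One of `"Bq/mL"`, `"kBq/mL"`, `"HU"`, `"SUV"`. `"HU"`
#'   is only valid for CT; activity units and SUV only for PET.
#' @param acquisition_datetime `POSIXct` scan start, or `NA`.
#' @param decay_reference_datetime `POSIXct` time to which the PET values are
#'   decay-corrected, or `NA` (PET only).
#' @return An `image_volume` object.
#' @examples
#' v <- image_volume(array(1, dim = c(4, 4, 2)), spacing = c(2.7, 2.7, 3.3),
#'                   origin = c(0, 0, 0), modality = "PET",
#'                   value_units = "kBq/mL")
#' @export
image_volume <- function(values, spacing, origin,
                         modality = c("PET", "CT"),
                         value_units = c("kBq/mL", "Bq/mL", "HU", "SUV"),
                         acquisition_datetime = as.POSIXct(NA),
                         decay_reference_datetime = as.POSIXct(NA)) {
  modality <- match.arg(modality)
  value_units <- match.arg(value_units)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (missing(spacing) || is.null(spacing)) {
    stop("`spacing` is required: geometry is never defaulted", call. = FALSE)
  }
  if (missing(origin) || is.null(origin)) {
    stop("`origin` is required: geometry is never defaulted", call. = FALSE)
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  if (modality == "CT" && value_units != "HU") {
    stop("CT volumes carry HU values", call. = FALSE)
  }
  if (modality == "PET" && value_units == "HU") {
    stop("HU is a CT unit; PET volumes carry activity or SUV values", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality, value_units = value_units,
         acquisition_datetime = acquisition_datetime,
         decay_reference_datetime = decay_reference_datetime),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %s, %d x %d x %d voxels, %s\n",
              x$modality, d[1], d[2], d[3], x$value_units))
  cat(sprintf("  spacing: %g x %g x %g mm, origin: (%g, %g, %g) mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Physical coordinates of voxel centres along one axis
#' @param vol An [image_volume()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of centre coordinates in mm.
#' @export
axis_centers_mm <- function(vol, axis) {
  stopifnot(inherits(vol, "image_volume"), axis %in% 1:3)
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Convert a physical coordinate to a continuous 0-based voxel index
#' @keywords internal
.mm_to_index0 <- function(vol, mm) (mm - vol$origin) / vol$spacing

#' Voxel volume in millilitres
#' @param vol An [image_volume()].
#' @return Scalar mL per voxel.
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000
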