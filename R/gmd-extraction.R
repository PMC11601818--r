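#' @include AllGenerics.R
NULL

#' Construct a GreyMatterMap
#'
#' @param voxels 3D numeric array of non-negative grey-matter values.
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param affine optional 4x4 voxel-to-world transform; defaults to a
#'   diagonal scaling by `voxelSize` centred on the grid.
#' @return a [GreyMatterMap-class].
#' @examples
#' gm <- greyMatterMap(array(0.5, c(4, 4, 4)), voxelSize = 1.5)
#' gm
#' @export
greyMatterMap <- function(voxels, voxelSize = 1.5, affine = NULL) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(affine)) affine <- .defaultAffine(dim(voxels), voxelSize)
  new("GreyMatterMap", voxels = voxels, affine = affine,
      voxelSize = as.numeric(voxelSize))
}

#' Construct a ProbabilisticMask
#'
#' @param weights 3D numeric array of non-negative voxel weights.
#' @param regionName label for the region (default `"Ch4"`).
#' @inheritParams greyMatterMap
#' @return a [ProbabilisticMask-class].
#' @export
probabilisticMask <- function(weights, voxelSize = 1.5, affine = NULL,
                              regionName = "Ch4") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(affine)) affine <- .defaultAffine(dim(weights), voxelSize)
  new("ProbabilisticMask", weights = weights, affine = affine,
      voxelSize = as.numeric(voxelSize), regionName = regionName)
}

# RAS affine with the grid centre at the origin, the usual convention for
# synthetic volumes; real volumes carry their own affine from the header.
.defaultAffine <- function(dims, voxelSize) {
  a <- diag(c(voxelSize, 1))
  a[1:3, 4] <- -voxelSize * (dims - 1) / 2
  a
}

#' Read a grey-matter map or probabilistic mask from a NIfTI-1 file
#'
#' Thin wrappers over [RNifti::readNifti()] that carry the image array,
#' affine and voxel dimensions into the package's containers. Volumes are
#' expected to be already spatially normalized and (for GM maps)
#' modulated; no resampling is ever performed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [GreyMatterMap-class].
#' @export
readGreyMatterMap <- function(path) {
  img <- RNifti::readNifti(path)
  greyMatterMap(array(as.numeric(img), dim(img)),
                voxelSize = RNifti::pixdim(img)[1:3],
                affine = matrix(as.numeric(RNifti::xform(img)), 4L, 4L))
}

#' @rdname readGreyMatterMap
#' @param regionName region label to attach to the mask.
#' @return `readProbabilisticMask`: a [ProbabilisticMask-class].
#' @export
readProbabilisticMask <- function(path, regionName = "Ch4") {
  img <- RNifti::readNifti(path)
  probabilisticMask(array(as.numeric(img), dim(img)),
                    voxelSize = RNifti::pixdim(img)[1:3],
                    affine = matrix(as.numeric(RNifti::xform(img)), 4L, 4L),
                    regionName = regionName)
}

#' Write a map or mask to a NIfTI-1 file
#'
#' @param x a [GreyMatterMap-class] or [ProbabilisticMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeNiftiVolume <- function(x, path) {
  img <- RNifti::asNifti(voxelArray(x))
  RNifti::pixdim(img) <- voxelSize(x)
  RNifti::qform(img) <- structure(affineMatrix(x), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.checkSameGrid <- function(aArr, aAff, bArr, bAff, what_a, what_b,
                           tol = 1e-4) {
  if (!identical(dim(aArr), dim(bArr)))
    stop(sprintf(
      "spatial incompatibility: %s grid %s does not match %s grid %s",
      what_a, paste(dim(aArr), collapse = "x"),
      what_b, paste(dim(bArr), collapse = "x")), call. = FALSE)
  if (max(abs(aAff - bAff)) > tol)
    stop(sprintf(
      "spatial incompatibility: %s and %s affines differ by %.3g (> %g tolerance); refusing to resample silently",
      what_a, what_b, max(abs(aAff - bAff)), tol), call. = FALSE)
  invisible(TRUE)
}

#' @describeIn computeRegionGMD weighted-mean grey-matter density
#'
#' The region GMD is the probabilistic-mask-weighted mean of the
#' grey-matter map: each voxel's grey-matter value is multiplied by the
#' mask weight at that voxel, the products are summed, and the sum is
#' standardized by the total weight in the mask,
#' \eqn{\mathrm{GMD} = \sum_v g_v w_v / \sum_v w_v}. Grids must match
#' exactly (shape equal, affines equal within `tol`); mismatches are an
#' error, never silently interpolated.
#'
#' @param tol absolute per-element affine agreement tolerance.
#' @return a list of class `"RegionGMD"` with elements `value` (the
#'   weighted mean, same units as the map), `total_weight`,
#'   `n_voxels_support` (voxels with positive weight), and `region`.
#' @examples
#' gm <- greyMatterMap(array(c(0.2, 0.6, 0, 0, 0, 0, 0, 0), c(2, 2, 2)))
#' w <- array(0, c(2, 2, 2)); w[1:2] <- c(1, 3)
#' computeRegionGMD(gm, probabilisticMask(w))$value  # (0.2 + 3*0.6)/4 = 0.5
#' @export
setMethod("computeRegionGMD", c("GreyMatterMap", "ProbabilisticMask"),
  function(map, mask, tol = 1e-4) {
    .checkSameGrid(map@voxels, map@affine, mask@weights, mask@affine,
                   "grey-matter map", sprintf("'%s' mask", mask@regionName),
                   tol = tol)
    w <- as.numeric(mask@weights)
    g <- as.numeric(map@voxels)
    tw <- sum(w)
    if (tw <= 0)
      stop(sprintf("degenerate mask '%s': total weight is zero",
                   mask@regionName), call. = FALSE)
    structure(list(value = sum(g * w) / tw,
                   total_weight = tw,
                   n_voxels_support = sum(w > 0),
                   region = mask@regionName),
              class = "RegionGMD")
  })

#' @export
print.RegionGMD <- function(x, ...) {
  cat(sprintf("Region GMD [%s]: %.6g (total weight %.4g over %d voxels)\n",
              x$region, x$value, x$total_weight, x$n_voxels_support))
  invisible(x)
}

#' @describeIn computeTIV tissue-sum TIV estimate
#'
#' Sums the grey-matter, white-matter and CSF tissue fractions over the
#' grid, multiplies by the voxel volume, and reports millilitres. This is
#' a simple tissue-sum estimate intended for self-contained synthetic
#' runs; in a real analysis TIV is usually supplied as a covariate column
#' produced by the segmentation software.
#'
#' @return a list of class `"TIVEstimate"` with element `value` (mL).
#' @export
setMethod("computeTIV", c("GreyMatterMap", "GreyMatterMap", "GreyMatterMap"),
  function(gm, wm, csf) {
    .checkSameGrid(gm@voxels, gm@affine, wm@voxels, wm@affine,
                   "GM map", "WM map")
    .checkSameGrid(gm@voxels, gm@affine, csf@voxels, csf@affine,
                   "GM map", "CSF map")
    tissue <- gm@voxels + wm@voxels + csf@voxels
    if (any(tissue > 1 + 1e-6))
      stop("tissue fractions exceed 1; inputs must be fraction maps",
           call. = FALSE)
    voxvol <- prod(gm@voxelSize)              # mm^3
    total <- sum(tissue) * voxvol / 1000      # mL
    if (total <= 0)
      stop("degenerate input: total tissue volume is zero", call. = FALSE)
    structure(list(value = total), class = "TIVEstimate")
  })

#' @export
print.TIVEstimate <- function(x, ...) {
  cat(sprintf("TIV estimate: %.4g mL\n", x$value))
  invisible(x)
}

#' Append extracted region GMD to a cohort table
#'
#' Convenience wrapper used by the pipeline when GMD is computed from
#' image files rather than ingested from a precomputed column: for each
#' subject, reads the GM volume, applies the shared mask, and stores the
#' result in column `ch4_gmd`.
#'
#' @param cohort data.frame with a `gm_path` column of NIfTI file paths.
#' @param mask a [ProbabilisticMask-class] shared across subjects.
#' @return `cohort` with a `ch4_gmd` column appended.
#' @export
extractCohortGMD <- function(cohort, mask) {
  stopifnot(is.data.frame(cohort), "gm_path" %in% names(cohort))
  cohort$ch4_gmd <- vapply(cohort$gm_path, function(p) {
    computeRegionGMD(readGreyMatterMap(p), mask)$value
  }, numeric(1), USE.NAMES = FALSE)
  cohort
}
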