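#' @include AllClasses.R
NULL

#' Compute region grey-matter density from a map and a probabilistic mask
#'
#' @param map a [GreyMatterMap-class].
#' @param mask a [ProbabilisticMask-class] on the same grid.
#' @param ... further arguments passed to methods.
#' @return see [computeRegionGMD,GreyMatterMap,ProbabilisticMask-method].
#' @export
setGeneric("computeRegionGMD",
  function(map, mask, ...) standardGeneric("computeRegionGMD"))

#' Estimate total intracranial volume from tissue fraction maps
#'
#' @param gm,wm,csf grey-matter, white-matter and CSF fraction maps
#'   ([GreyMatterMap-class]) on a common grid.
#' @param ... further arguments passed to methods.
#' @return see [computeTIV,GreyMatterMap,GreyMatterMap,GreyMatterMap-method].
#' @export
setGeneric("computeTIV",
  function(gm, wm, csf, ...) standardGeneric("computeTIV"))

## accessors ---------------------------------------------------------------

#' @rdname GreyMatterMap-class
#' @param x a `GreyMatterMap` or `ProbabilisticMask`
#' @export
setGeneric("voxelArray", function(x) standardGeneric("voxelArray"))

#' @rdname GreyMatterMap-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname GreyMatterMap-class
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname ProbabilisticMask-class
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' @rdname NormingModel-class
#' @param x a `NormingModel`
#' @export
setGeneric("referenceN", function(x) standardGeneric("referenceN"))

#' @rdname NormingModel-class
#' @export
setGeneric("normRMSE", function(x) standardGeneric("normRMSE"))

#' @rdname NormingModel-class
#' @export
setGeneric("lowCh4Threshold", function(x) standardGeneric("lowCh4Threshold"))

#' @rdname SubtypeThresholds-class
#' @param x a `SubtypeThresholds`
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname SubtypeThresholds-class
#' @export
setGeneric("percentileMatrix",
  function(x) standardGeneric("percentileMatrix"))

setMethod("voxelArray", "GreyMatterMap", function(x) x@voxels)
setMethod("voxelArray", "ProbabilisticMask", function(x) x@weights)
setMethod("voxelSize", "GreyMatterMap", function(x) x@voxelSize)
setMethod("voxelSize", "ProbabilisticMask", function(x) x@voxelSize)
setMethod("affineMatrix", "GreyMatterMap", function(x) x@affine)
setMethod("affineMatrix", "ProbabilisticMask", function(x) x@affine)
setMethod("regionName", "ProbabilisticMask", function(x) x@regionName)
setMethod("referenceN", "NormingModel", function(x) x@nReference)
setMethod("normRMSE", "NormingModel", function(x) x@rmse)
setMethod("lowCh4Threshold", "NormingModel", function(x) x@threshold)
setMethod("binEdges", "SubtypeThresholds", function(x) x@binEdges)
setMethod("percentileMatrix", "SubtypeThresholds", function(x) x@percentiles)

#' @describeIn NormingModel-class regression coefficients (named numeric)
#' @param object a `NormingModel`
#' @param ... ignored
#' @importFrom stats coef
#' @export
setMethod("coef", "NormingModel", function(object, ...) object@coefficients)
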