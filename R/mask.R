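#' Create or read a brain mask
#'
#' \code{brainMask} wraps a 3-D binary array; \code{readBrainMask} reads a
#' NIfTI volume and treats all nonzero voxels as inside the mask.
#'
#' @param volume 3-D array; nonzero voxels are retained.
#' @param affine 4 x 4 voxel-to-world matrix (default identity).
#' @return a \linkS4class{BrainMask}.
#' @export
brainMask <- function(volume, affine = diag(4)) {
  volume <- as.array(volume)
  if (length(dim(volume)) != 3L) stop("mask volume must be 3-D")
  D <- sum(volume != 0)
  if (D == 0L) stop("empty mask")
  new("BrainMask", volume = volume, affine = unname(as.matrix(affine)),
      D = as.integer(D))
}

#' @rdname brainMask
#' @param path path to a NIfTI file.
#' @export
readBrainMask <- function(path) {
  img <- RNifti::readNifti(path)
  brainMask(array(as.numeric(img != 0), dim = dim(img)),
            affine = RNifti::xform(img))
}

#' Vectorize a masked volume / restore a vector into a volume
#'
#' \code{applyMask} extracts the image values at the nonzero mask voxels as
#' a length-D vector; \code{unmask} writes such a vector back into a volume
#' with zeros outside the mask.  The linear order is the array-index
#' (column-major) order of the mask volume: the first axis varies fastest.
#' \code{applyMask(unmask(mask, v), mask)} returns \code{v} exactly.
#'
#' @param image 3-D array or NIfTI image, same shape as the mask.
#' @param mask a \linkS4class{BrainMask}.
#' @param values numeric vector of length \code{mask@D}.
#' @return \code{applyMask}: numeric vector of length D; \code{unmask}: a
#'   3-D array.
#' @export
applyMask <- function(image, mask) {
  stopifnot(is(mask, "BrainMask"))
  image <- as.array(image)
  if (!identical(dim(image), dim(mask@volume)))
    stop(sprintf("image dimensions (%s) do not match mask (%s)",
                 paste(dim(image), collapse = "x"),
                 paste(dim(mask@volume), collapse = "x")))
  as.numeric(image[mask@volume != 0])
}

#' @rdname applyMask
#' @export
unmask <- function(mask, values) {
  stopifnot(is(mask, "BrainMask"))
  if (length(values) != mask@D)
    stop(sprintf("expected %d values, got %d", mask@D, length(values)))
  out <- array(0, dim = dim(mask@volume))
  out[mask@volume != 0] <- values
  out
}

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask: %s volume, %d voxels in mask\n",
              paste(dim(object@volume), collapse = " x "), object@D))
})
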