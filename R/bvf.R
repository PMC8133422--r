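#' Bone volume fraction map from a gradient-echo volume
#'
#' On GRE images trabecular bone is dark and marrow bright, and voxel
#' intensity mixes the two phases approximately linearly. The BVF map inverts
#' that mixture: intensities are scaled affinely so that the pure-bone
#' reference maps to 1 and the pure-marrow reference to 0, then clamped to
#' \eqn{[0, 1]}:
#' \deqn{BVF(x) = \mathrm{clamp}\!\left(\frac{I_{marrow} - I(x)}
#'   {I_{marrow} - I_{bone}},\, 0,\, 1\right).}
#' BVF is stored in `[0, 1]`; any 0-255 display convention is an encoding
#' concern, not a data one.
#'
#' @param v a [volume_image()].
#' @param bone_ref,marrow_ref pure-phase reference intensities;
#'   `marrow_ref > bone_ref` required.
#' @returns A `volume_image` of class `c("bvf_map", "volume_image")`, values
#'   in `[0, 1]`, geometry identical to `v`.
#' @seealso [estimate_references()] for choosing the references from a mask.
#' @export
compute_bvf_map <- function(v, bone_ref, marrow_ref) {
  stopifnot(inherits(v, "volume_image"))
  if (!is.finite(bone_ref) || !is.finite(marrow_ref) || marrow_ref <= bone_ref)
    stop_param("marrow_ref must be strictly greater than bone_ref")
  bvf <- (marrow_ref - v$data) / (marrow_ref - bone_ref)
  bvf <- pmin(pmax(bvf, 0), 1)
  out <- volume_image(array(bvf, dim(v$data)), v$spacing, v$origin)
  class(out) <- c("bvf_map", class(out))
  out
}

#' Estimate pure-phase reference intensities inside a mask
#'
#' The protocol that motivated this package rescales each bone to a fixed
#' pure-bone/pure-marrow range without saying how the anchors were found;
#' here they default to robust percentiles of the intensity distribution
#' inside the bone mask (1st percentile = darkest plausible pure bone, 99th =
#' brightest plausible pure marrow).
#'
#' @param v a [volume_image()].
#' @param mask a non-empty [binary_mask()] congruent with `v`.
#' @param p_lo,p_hi percentiles in `[0, 100]`, `p_lo < p_hi`.
#' @returns Named numeric `c(bone_ref = ..., marrow_ref = ...)`.
#' @export
estimate_references <- function(v, mask, p_lo = 1, p_hi = 99) {
  stopifnot(inherits(v, "volume_image"), inherits(mask, "binary_mask"))
  stopifnot_congruent(v, mask, "volume and mask")
  if (!any(mask$data)) stop_estim("mask is empty")
  if (p_lo < 0 || p_hi > 100 || p_lo >= p_hi)
    stop_param("percentiles must satisfy 0 <= p_lo < p_hi <= 100")
  vals <- v$data[mask$data]
  refs <- unname(stats::quantile(vals, c(p_lo, p_hi) / 100, type = 7))
  if (refs[1] >= refs[2])
    stop_estim("degenerate intensity distribution inside mask")
  c(bone_ref = refs[1], marrow_ref = refs[2])
}
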