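#' Li's intensity correlation quotient (ICQ)
#'
#' For two co-registered single-channel images, ICQ is the fraction of
#' (masked) pixels whose mean-centered intensities vary together —
#' `(A - mean(A)) * (B - mean(B)) > 0` — minus one half. ICQ = 0.5 means
#' complete colocalization between channels, ICQ = -0.5 complete spatial
#' segregation, and independent channels give ICQ near 0. Pixels whose
#' cross product is exactly zero count as non-positive.
#'
#' ICQ is invariant under positive affine rescaling of either channel and
#' symmetric in the two channels.
#'
#' @param a,b Numeric matrices of identical dimensions (or an `idc_image_pair`
#'   list with elements `a` and `b` passed as the first argument).
#' @param mask Optional logical matrix selecting pixels to include.
#' @return Scalar ICQ in \[-0.5, 0.5\].
#' @export
compute_icq <- function(a, b = NULL, mask = NULL) {
  if (is.list(a) && is.null(b)) { b <- a$b; a <- a$a }
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    abort_idc("channels must be numeric matrices of identical shape", "bad_image")
  }
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  av <- a[mask]; bv <- b[mask]
  if (length(av) < 2) abort_idc("mask selects fewer than 2 pixels", "bad_image")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    abort_idc("ICQ is undefined for a constant channel", "bad_image")
  }
  prod <- (av - mean(av)) * (bv - mean(bv))
  mean(prod > 0) - 0.5
}
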