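# Stain colour model shared by the synthetic core generator and the scoring
# code. Brightfield absorbance follows Beer-Lambert: per-channel optical
# density OD = -log10((v + 1)/256) for an 8-bit value v, and a stained pixel's
# OD vector is a non-negative combination of unit stain vectors.

#' Reference haematoxylin/DAB stain vectors
#'
#' Unit optical-density RGB vectors for haematoxylin (blue nuclear
#' counterstain) and DAB (brown chromogen), with a third orthogonal
#' residual vector completing the basis. These are the widely used
#' published H/DAB deconvolution values; the synthetic core generator uses
#' the same matrix, which makes stain separation exactly invertible on
#' noise-free synthetic images.
#'
#' @return a 3 x 3 numeric matrix; rows `hematoxylin`, `dab`, `residual`,
#'   columns R, G, B, each row of unit length.
#' @export
stain_vectors_hdab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.872)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

# 8-bit channel value (0..255) -> optical density.
od_from_value <- function(v) -log10((v + 1) / 256)

# optical density -> 8-bit channel value, the exact inverse up to rounding.
value_from_od <- function(od) pmin(pmax(round(256 * 10^(-od)) - 1, 0), 255)

# Convert an [0,1] RGB array (h x w x 3, png convention) to a pixel x 3
# matrix of per-channel ODs.
rgb_to_od <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("expected an RGB image array (h x w x 3)", call. = FALSE)
  }
  v <- round(image[, , 1:3] * 255)
  matrix(od_from_value(v), ncol = 3L)
}
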