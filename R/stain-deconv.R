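# Color deconvolution (Ruifrok & Johnston style): RGB intensities are mapped
# to optical density (OD) by Beer-Lambert, a = -log(I / I0), and per-pixel
# stain amounts C are recovered by inverting a 3x3 matrix M whose rows are
# the unit OD color vectors of the stains (hematoxylin, eosin, residual).

#' Construct a stain matrix
#'
#' Builds the 3x3 matrix used for color deconvolution. Rows are materials
#' (hematoxylin, eosin, residual), columns are the red, green and blue
#' optical-density components. Rows are normalized to unit Euclidean norm.
#' When no residual row is supplied it is completed with the normalized cross
#' product of the hematoxylin and eosin rows, the standard completion when
#' only two stains are specified.
#'
#' @param h,e Numeric length-3 OD color vectors for hematoxylin and eosin.
#' @param residual Optional length-3 residual row; defaults to the normalized
#'   cross product of `h` and `e`.
#' @param I0 Incident light intensity per channel (255 for 8-bit images).
#' @return An object of class `stain_matrix`: a list with the normalized
#'   matrix `M` and `I0`.
#' @export
stain_matrix <- function(h, e, residual = NULL, I0 = 255) {
  if (I0 <= 0) stopf("I0 must be positive (got %g)", I0)
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stopf("stain vector has zero norm")
    v / n
  }
  h <- unit(as.numeric(h)); e <- unit(as.numeric(e))
  if (is.null(residual)) {
    residual <- c(h[2] * e[3] - h[3] * e[2],
                  h[3] * e[1] - h[1] * e[3],
                  h[1] * e[2] - h[2] * e[1])
    if (sqrt(sum(residual^2)) < 1e-12)
      stopf("hematoxylin and eosin vectors are collinear; cannot complete matrix")
  }
  M <- rbind(hematoxylin = h, eosin = e, residual = unit(as.numeric(residual)))
  colnames(M) <- c("red", "green", "blue")
  sv <- svd(M)$d
  kcond <- if (sv[3] <= sv[1] * 1e-12) Inf else sv[1] / sv[3]
  if (!is.finite(kcond) || kcond > 1e8)
    stopf("stain matrix is singular or ill-conditioned (condition number %.3g)", kcond)
  structure(list(M = M, I0 = I0), class = "stain_matrix")
}

#' Default H&E stain matrix
#'
#' The widely used published H&E OD color vectors (hematoxylin
#' (0.65, 0.70, 0.29), eosin (0.07, 0.99, 0.11)), with the residual row
#' completed by the normalized cross product.
#'
#' @param I0 Incident light intensity per channel.
#' @return A `stain_matrix`.
#' @export
default_stain_matrix <- function(I0 = 255) {
  stain_matrix(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11), I0 = I0)
}

#' Read a stain matrix from a YAML or JSON config
#'
#' The config must contain a 9-element row-major `matrix` field (rows
#' hematoxylin, eosin, residual) and may contain `I0` (default 255).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `stain_matrix`.
#' @export
read_stain_matrix <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  m <- as.numeric(unlist(cfg$matrix))
  if (length(m) != 9) stopf("stain config must hold 9 numbers row-major (got %d)", length(m))
  M <- matrix(m, 3, 3, byrow = TRUE)
  stain_matrix(M[1, ], M[2, ], M[3, ], I0 = if (is.null(cfg$I0)) 255 else cfg$I0)
}

as_stain_matrix <- function(x) {
  if (inherits(x, "stain_matrix")) return(x)
  stopf("expected a 'stain_matrix' object")
}

#' Forward stain composition
#'
#' Converts per-pixel stain amounts to transmitted light intensities through
#' the Beer-Lambert forward model: OD = C M (row-vector convention), then
#' I = I0 * base^(-OD). This is the exact inverse of [deconvolve()] +
#' [to_optical_density()] before quantization.
#'
#' @param stains h x w x 3 array of stain amounts (hematoxylin, eosin,
#'   residual planes).
#' @param sm A [stain_matrix()].
#' @param base Logarithm base of the OD convention (default 10).
#' @return h x w x 3 array of (unquantized) intensities in `[0, I0]`.
#' @export
compose_stains <- function(stains, sm, base = 10) {
  sm <- as_stain_matrix(sm)
  d <- dim(stains)
  if (length(d) != 3L || d[3] != 3L) stopf("stains must be an h x w x 3 array")
  od <- matrix(stains, ncol = 3L) %*% sm$M
  array(sm$I0 * base^(-od), dim = d)
}

#' Convert intensities to optical density
#'
#' Computes `a = -log10(max(I, 1) / I0)` elementwise (the OD convention;
#' intensities are clamped one intensity level above zero so saturated dark
#' pixels map to the finite ceiling `log10(I0)`).
#'
#' @param image h x w x 3 intensity array with values in `[0, I0]`, or a
#'   single-channel matrix.
#' @param I0 Incident intensity (default 255).
#' @param base Logarithm base (default 10; deconvolution results are
#'   invariant to the base up to a global scale).
#' @return Array of the same shape holding optical densities.
#' @export
to_optical_density <- function(image, I0 = 255, base = 10) {
  if (I0 <= 0) stopf("I0 must be positive (got %g)", I0)
  a <- -log(pmax(image, 1) / I0, base = base)
  a
}

#' Unmix stains from an optical-density image
#'
#' Solves `C = a M^-1` per pixel, recovering the amount of each stain.
#' The hematoxylin channel is plane 1 by convention.
#'
#' @param od h x w x 3 optical-density array.
#' @param sm A [stain_matrix()].
#' @return h x w x 3 stain-amount array (`stain_image`).
#' @export
deconvolve <- function(od, sm) {
  sm <- as_stain_matrix(sm)
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stopf("od must be an h x w x 3 array")
  Minv <- solve(sm$M)
  array(matrix(od, ncol = 3L) %*% Minv, dim = d)
}

#' Extract the hematoxylin plane
#'
#' Returns the hematoxylin (nuclear stain) plane of a stain image, with
#' small negative values from numerical noise clipped at zero.
#'
#' @param stain h x w x 3 stain-amount array from [deconvolve()].
#' @return h x w matrix of non-negative hematoxylin amounts.
#' @export
hematoxylin_channel <- function(stain) {
  d <- dim(stain)
  if (length(d) != 3L || d[3] != 3L) stopf("stain must be an h x w x 3 array")
  pmax(stain[, , 1L], 0)
}
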