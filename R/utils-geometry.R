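## Shared resampling and registration primitives.
## Image convention: matrix index 1 is x, index 2 is y; pixel centers sit at
## integer coordinates 1..N (pixel units); the box center is at (N + 1) / 2.
## Positive rotation angles are counter-clockwise in the (x, y) plane.

#' Evaluate an expression with a temporary RNG seed
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}; the caller's RNG state is restored.
#' @keywords internal
withSeed <- function(seed, expr) withr::with_seed(as.integer(seed), expr)

## Derive a deterministic sub-seed below 2^31 from a master seed.
subSeed <- function(seed, offset) {
    as.integer((as.double(seed) * 48271 + 1013 * offset) %% 2147483629)
}

#' Bilinear sampling of a matrix at fractional coordinates
#'
#' @param img numeric matrix.
#' @param xi,yi coordinates in pixel units (1-based pixel centers); points
#'   outside the support contribute 0.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinearSample <- function(img, xi, yi) {
    n1 <- nrow(img); n2 <- ncol(img)
    x0 <- floor(xi); y0 <- floor(yi)
    fx <- xi - x0; fy <- yi - y0
    out <- numeric(length(xi))
    at <- function(ix, iy) {
        ok <- ix >= 1 & ix <= n1 & iy >= 1 & iy <= n2
        v <- numeric(length(ix))
        v[ok] <- img[cbind(ix[ok], iy[ok])]
        v
    }
    out <- at(x0, y0) * (1 - fx) * (1 - fy) +
        at(x0 + 1, y0) * fx * (1 - fy) +
        at(x0, y0 + 1) * (1 - fx) * fy +
        at(x0 + 1, y0 + 1) * fx * fy
    out
}

## Trilinear sampling of a 3D array; coords in voxel units, outside -> 0.
trilinearSample <- function(vol, xi, yi, zi) {
    d <- dim(vol)
    x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
    fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
    at <- function(ix, iy, iz) {
        ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
        v <- numeric(length(ix))
        v[ok] <- vol[cbind(ix[ok], iy[ok], iz[ok])]
        v
    }
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
        at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
        at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
        at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
        at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
        at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
        at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
        at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
}

#' Rotate an image about its center (bilinear, same output size)
#'
#' @param img numeric matrix.
#' @param angleDeg counter-clockwise rotation of the image content, degrees.
#' @return matrix of the same dimensions.
#' @keywords internal
rotateImage <- function(img, angleDeg) {
    if (angleDeg %% 360 == 0) return(img)
    n1 <- nrow(img); n2 <- ncol(img)
    cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
    th <- -angleDeg * pi / 180   # inverse map: output pixel -> input pixel
    g <- expand.grid(x = seq_len(n1), y = seq_len(n2))
    dx <- g$x - cx; dy <- g$y - cy
    xi <- cx + cos(th) * dx - sin(th) * dy
    yi <- cy + sin(th) * dx + cos(th) * dy
    matrix(bilinearSample(img, xi, yi), n1, n2)
}

## Shift image content by (dx, dy) pixels (fractional ok, bilinear).
shiftImage <- function(img, dx, dy) {
    if (dx == 0 && dy == 0) return(img)
    n1 <- nrow(img); n2 <- ncol(img)
    g <- expand.grid(x = seq_len(n1), y = seq_len(n2))
    matrix(bilinearSample(img, g$x - dx, g$y - dy), n1, n2)
}

## Rotate-then-shift applied from the pristine image (single resampling pass).
transformImage <- function(img, rotationDeg, dx, dy) {
    n1 <- nrow(img); n2 <- ncol(img)
    cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
    th <- -rotationDeg * pi / 180
    g <- expand.grid(x = seq_len(n1), y = seq_len(n2))
    px <- g$x - dx - cx; py <- g$y - dy - cy
    xi <- cx + cos(th) * px - sin(th) * py
    yi <- cy + sin(th) * px + cos(th) * py
    matrix(bilinearSample(img, xi, yi), n1, n2)
}

## Signed FFT frequency indices for length n: 0, 1, ..., -1.
fftIndex <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k
}

#' Subpixel image registration by upsampled cross-correlation
#'
#' Finds the translation of \code{b} that best matches \code{a}: the returned
#' shift \code{s} satisfies \code{a(x) ~ b(x - s)}. The integer peak of the
#' FFT cross-correlation is refined on a local grid evaluated by a
#' matrix-multiply discrete Fourier transform at \code{1/upsample} pixel
#' granularity.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param upsample upsampling factor for the refinement grid (default 20).
#' @return list with \code{shift} (dx, dy in pixels) and \code{peak}
#'   (normalized correlation at the optimum).
#' @keywords internal
registerTranslation <- function(a, b, upsample = 20) {
    stopifnot(all(dim(a) == dim(b)))
    n1 <- nrow(a); n2 <- ncol(a)
    Fa <- stats::fft(a); Fb <- stats::fft(b)
    CC <- Fa * Conj(Fb)
    c0 <- Re(stats::fft(CC, inverse = TRUE)) / length(CC)
    pk <- arrayInd(which.max(c0), dim(c0))
    s0 <- c(pk[1] - 1, pk[2] - 1)
    s0[1] <- if (s0[1] > n1 / 2) s0[1] - n1 else s0[1]
    s0[2] <- if (s0[2] > n2 / 2) s0[2] - n2 else s0[2]
    if (upsample > 1) {
        x1 <- seq(s0[1] - 1.5, s0[1] + 1.5, by = 1 / upsample)
        x2 <- seq(s0[2] - 1.5, s0[2] + 1.5, by = 1 / upsample)
        k1 <- fftIndex(n1); k2 <- fftIndex(n2)
        E1 <- exp(2i * pi * outer(x1, k1) / n1)
        E2 <- exp(2i * pi * outer(k2, x2) / n2)
        cf <- Re(E1 %*% CC %*% E2)
        pk <- arrayInd(which.max(cf), dim(cf))
        shift <- c(x1[pk[1]], x2[pk[2]])
        peak <- max(cf) / length(a)
    } else {
        shift <- s0
        peak <- max(c0)
    }
    norm <- sqrt(sum(a^2) * sum(b^2))
    list(shift = shift, peak = if (norm > 0) peak / norm else 0)
}

## Pearson correlation that tolerates zero-variance input.
safeCor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(as.vector(a), as.vector(b))
}
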