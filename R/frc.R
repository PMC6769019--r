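#' @include AllClasses.R accessors.R localization-io.R utils-geometry.R
NULL

#' Fourier ring correlation resolution of a localization dataset
#'
#' The localizations are split randomly into two half-sets, each rendered as a
#' histogram image (default pixel size 10 nm), and the normalized
#' cross-correlation of the two half-images is computed over rings of spatial
#' frequency at \code{nFreq} points (default 90). The resolution is the
#' inverse of the spatial frequency at the first crossing of the threshold
#' (default 1/7), linearly interpolated between frequency points.
#'
#' @param table a corrected \linkS4class{LocalizationTable} (consecutive
#'   localizations merged).
#' @param pixelSize histogram pixel size, nm (default 10).
#' @param nFreq number of spatial-frequency points (default 90).
#' @param threshold FRC threshold (default 1/7).
#' @param seed seed for the random half-set split.
#' @param halves optional list of two \linkS4class{LocalizationTable}s that
#'   override the random split (e.g. to force identical half-sets).
#' @return list with \code{resolution} (nm; \code{NA} when the curve never
#'   crosses the threshold), \code{resolved}, \code{frc} (data.frame with
#'   columns \code{q} in 1/nm and \code{frc}), \code{threshold} and
#'   \code{lastFRC}.
#' @export
frcResolution <- function(table, pixelSize = 10, nFreq = 90, threshold = 1 / 7,
                          seed = 1L, halves = NULL) {
    if (is.null(halves)) {
        n <- length(table)
        if (n < 2) stop("need at least 2 localizations")
        half <- withSeed(seed, stats::runif(n) < 0.5)
        halves <- list(table[half], table[!half])
    }
    allx <- c(locData(halves[[1]])$x, locData(halves[[2]])$x)
    ally <- c(locData(halves[[1]])$y, locData(halves[[2]])$y)
    p <- pixelSize
    b <- c(floor(min(allx) / p) * p, (floor(max(allx) / p) + 1) * p,
           floor(min(ally) / p) * p, (floor(max(ally) / p) + 1) * p)
    n1 <- round((b[2] - b[1]) / p); n2 <- round((b[4] - b[3]) / p)
    N <- max(n1, n2)
    sq <- c(b[1], b[1] + N * p, b[3], b[3] + N * p)
    i1 <- pixelData(renderHistogram(halves[[1]], p, bounds = sq))
    i2 <- pixelData(renderHistogram(halves[[2]], p, bounds = sq))
    F1 <- stats::fft(i1); F2 <- stats::fft(i2)
    fx <- fftIndex(N) / (N * p)
    q <- sqrt(outer(fx^2, fx^2, "+"))
    qmax <- 1 / (2 * p)
    br <- seq(0, qmax, length.out = nFreq + 1)
    bin <- findInterval(q, br, rightmost.closed = TRUE)
    inb <- bin >= 1 & bin <= nFreq
    num <- Re(F1 * Conj(F2)); d1 <- Mod(F1)^2; d2 <- Mod(F2)^2
    sNum <- tapply(num[inb], bin[inb], sum)
    sD1 <- tapply(d1[inb], bin[inb], sum)
    sD2 <- tapply(d2[inb], bin[inb], sum)
    frc <- as.vector(sNum / sqrt(sD1 * sD2))
    qc <- (br[-1] + br[-(nFreq + 1)]) / 2
    qc <- qc[as.integer(names(sNum))]
    below <- which(frc < threshold)
    if (!length(below)) {
        return(list(resolution = NA_real_, resolved = FALSE,
                    frc = data.frame(q = qc, frc = frc),
                    threshold = threshold, lastFRC = frc[length(frc)]))
    }
    k <- below[1]
    qStar <- if (k == 1) qc[1] else {
        # linear interpolation between the bracketing frequency points
        qc[k - 1] + (threshold - frc[k - 1]) * (qc[k] - qc[k - 1]) /
            (frc[k] - frc[k - 1])
    }
    list(resolution = 1 / qStar, resolved = TRUE,
         frc = data.frame(q = qc, frc = frc), threshold = threshold,
         lastFRC = frc[length(frc)])
}
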