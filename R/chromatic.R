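#' @include AllClasses.R accessors.R
NULL

chromaticDesign <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Evaluate a chromatic shift field
#'
#' @param model a \linkS4class{ChromaticModel}.
#' @param x,y coordinates in nm.
#' @return n x 2 matrix of (dx, dy) shifts in nm.
#' @export
evalChromatic <- function(model, x, y) {
    chromaticDesign(x, y) %*% chromaticCoefficients(model)
}

#' Fit a chromatic-aberration model from bead pairs
#'
#' Least-squares fit of the channel shift (non-reference minus reference
#' position) against the full 2nd-order bivariate polynomial
#' \code{(1, x, y, x^2, xy, y^2)} of the reference-channel position, per axis.
#'
#' @param beads a two-channel \linkS4class{LocalizationTable} where matching
#'   ids pair the same bead across channels (as produced by
#'   \code{\link{simulateBeads}}).
#' @param referenceChannel the channel left unchanged by the correction.
#' @return A \linkS4class{ChromaticModel}.
#' @export
fitChromatic <- function(beads, referenceChannel = 1L) {
    d <- locData(beads)
    chans <- sort(unique(d$channel))
    if (length(chans) != 2) stop("bead table must contain exactly 2 channels")
    other <- setdiff(chans, referenceChannel)
    a <- d[d$channel == referenceChannel, ]
    b <- d[d$channel == other, ]
    b <- b[match(a$id, b$id), ]
    ok <- !is.na(b$id)
    a <- a[ok, ]; b <- b[ok, ]
    if (nrow(a) < 6)
        stop("need at least 6 bead pairs for the 6-coefficient polynomial fit")
    X <- chromaticDesign(a$x, a$y)
    qrX <- qr(X)
    if (qrX$rank < 6)
        stop("rank-deficient bead design (collinear bead positions); ",
             "spread the beads over the field")
    coef <- qr.coef(qrX, cbind(b$x - a$x, b$y - a$y))
    ChromaticModel(coef, referenceChannel = as.integer(referenceChannel))
}

#' Correct chromatic aberration in a localization table
#'
#' Subtracts the evaluated polynomial shift from the localizations of the
#' non-reference channel; reference-channel records are returned bit-identical.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param model a \linkS4class{ChromaticModel}.
#' @return A corrected \linkS4class{LocalizationTable}.
#' @export
applyChromatic <- function(table, model) {
    d <- locData(table)
    sel <- d$channel != referenceChannel(model)
    if (any(sel)) {
        shift <- evalChromatic(model, d$x[sel], d$y[sel])
        d$x[sel] <- d$x[sel] - shift[, 1]
        d$y[sel] <- d$y[sel] - shift[, 2]
    }
    new("LocalizationTable", data = d)
}

#' Serialize / restore correction models as JSON
#'
#' @param x a \linkS4class{DriftTrajectory} or \linkS4class{ChromaticModel}.
#' @param path file path.
#' @return \code{writeCorrectionJSON}: the path, invisibly;
#'   \code{readCorrectionJSON}: the restored object.
#' @export
writeCorrectionJSON <- function(x, path) {
    payload <- if (is(x, "DriftTrajectory")) {
        list(type = "DriftTrajectory", shifts = driftShifts(x))
    } else if (is(x, "ChromaticModel")) {
        list(type = "ChromaticModel",
             coefficients = chromaticCoefficients(x),
             referenceChannel = referenceChannel(x))
    } else stop("unsupported object")
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeCorrectionJSON
#' @export
readCorrectionJSON <- function(path) {
    p <- jsonlite::fromJSON(path)
    switch(p$type,
           DriftTrajectory = DriftTrajectory(p$shifts),
           ChromaticModel = ChromaticModel(p$coefficients,
                                           as.integer(p$referenceChannel)),
           stop("unknown serialized type: ", p$type))
}
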