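#' @include AllClasses.R accessors.R
NULL

CANONICAL_HEADER <- c("id", "frame", "x_nm", "y_nm", "z_nm", "photons",
                      "channel", "sigma_nm")

#' Read a localization table from CSV
#'
#' The canonical dialect is a comma-separated UTF-8 file with the header
#' \code{id,frame,x_nm,y_nm,z_nm,photons,channel,sigma_nm}; an empty z field
#' marks 2D data. A reader shim for ThunderSTORM-style headers (columns such
#' as \code{"x [nm]"}, \code{"intensity [photon]"}) is also provided. Unknown
#' columns are preserved as opaque extras and survive a round trip.
#'
#' @param path file path.
#' @param dialect "canonical" or "thunderstorm".
#' @param unit unit of the coordinate columns, "nm" (default) or "um";
#'   micrometre coordinates are converted to nm on read.
#' @return A \linkS4class{LocalizationTable}.
#' @export
readLocalizations <- function(path, dialect = c("canonical", "thunderstorm"),
                              unit = c("nm", "um")) {
    dialect <- match.arg(dialect)
    unit <- match.arg(unit)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (dialect == "thunderstorm") {
        nm <- names(raw)
        pick <- function(pat) {
            hit <- grep(pat, nm, ignore.case = TRUE)
            if (length(hit)) nm[hit[1]] else NA_character_
        }
        map <- c(id = pick("^id$"), frame = pick("^frame$"),
                 x_nm = pick("^x\\b"), y_nm = pick("^y\\b"), z_nm = pick("^z\\b"),
                 photons = pick("^intensity"), channel = pick("^channel"),
                 sigma_nm = pick("^(uncertainty|sigma)"))
        out <- data.frame(row.names = seq_len(nrow(raw)))
        for (col in CANONICAL_HEADER) {
            src <- map[[col]]
            out[[col]] <- if (!is.na(src)) raw[[src]] else NA
        }
        extras <- raw[setdiff(nm, stats::na.omit(map))]
        raw <- cbind(out, extras)
    }
    miss <- setdiff(c("id", "frame", "x_nm", "y_nm", "photons", "channel"),
                    names(raw))
    if (length(miss))
        stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    num <- function(col) {
        v <- raw[[col]]
        if (is.null(v)) return(rep(NA_real_, nrow(raw)))
        v[!nzchar(trimws(ifelse(is.na(v), "", v)))] <- NA
        x <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & is.na(x))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                         v[bad[1]], col, bad[1] + 1L))
        x
    }
    scale <- if (unit == "um") 1000 else 1
    d <- data.frame(id = as.integer(num("id")),
                    frame = as.integer(num("frame")),
                    x = num("x_nm") * scale, y = num("y_nm") * scale,
                    z = num("z_nm") * scale,
                    photons = num("photons"),
                    channel = as.integer(num("channel")),
                    sigma = num("sigma_nm") * scale)
    d$photons[is.na(d$photons)] <- 0
    d$channel[is.na(d$channel)] <- 1L
    extras <- raw[setdiff(names(raw), CANONICAL_HEADER)]
    if (ncol(extras)) d <- cbind(d, extras)
    new("LocalizationTable", data = d)
}

#' Write a localization table to canonical CSV
#'
#' Records are stably sorted by (frame, id) on write; a second read returns
#' identical values for all fields.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLocalizations <- function(table, path) {
    d <- locData(table)
    d <- d[order(d$frame, d$id), , drop = FALSE]
    out <- d
    names(out)[match(c("x", "y", "z", "sigma"), names(out))] <-
        c("x_nm", "y_nm", "z_nm", "sigma_nm")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Render a 2D histogram image from localizations
#'
#' Reconstructs the SMLM image in histogram mode: the value of pixel (i, j) is
#' the number of localizations whose coordinates fall in the half-open square
#' \code{[origin + (k) p, origin + (k + 1) p)}. Rendering conserves counts:
#' the pixel sum equals the number of in-bounds localizations.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param pixelSize pixel edge in nm (20 nm is the usual rendering scale).
#' @param bounds optional numeric c(xmin, xmax, ymin, ymax) nm; mandatory for
#'   empty tables. Default: tight bounds snapped to the pixel grid.
#' @param channel optional channel filter.
#' @param axes which coordinate axes to project on (1 = x, 2 = y, 3 = z);
#'   default c(1, 2). Axis 3 requires 3D data.
#' @return A \linkS4class{PixelImage}.
#' @export
renderHistogram <- function(table, pixelSize, bounds = NULL, channel = NULL,
                            axes = c(1, 2)) {
    stopifnot(pixelSize > 0, length(axes) == 2)
    d <- locData(table)
    if (!is.null(channel)) d <- d[d$channel %in% channel, , drop = FALSE]
    if (max(axes) == 3 && all(is.na(d$z)))
        stop("axis 3 requested but the table has no z coordinates")
    cc <- cbind(d$x, d$y, d$z)
    u <- cc[, axes[1]]; v <- cc[, axes[2]]
    if (is.null(bounds)) {
        if (!nrow(d))
            stop("cannot render an empty table without explicit bounds")
        bounds <- c(floor(min(u) / pixelSize) * pixelSize,
                    (floor(max(u) / pixelSize) + 1) * pixelSize,
                    floor(min(v) / pixelSize) * pixelSize,
                    (floor(max(v) / pixelSize) + 1) * pixelSize)
    }
    n1 <- max(1L, as.integer(round((bounds[2] - bounds[1]) / pixelSize)))
    n2 <- max(1L, as.integer(round((bounds[4] - bounds[3]) / pixelSize)))
    img <- matrix(0, n1, n2)
    if (length(u)) {
        i <- floor((u - bounds[1]) / pixelSize) + 1
        j <- floor((v - bounds[3]) / pixelSize) + 1
        ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
        if (any(ok)) {
            t <- table(factor(i[ok], levels = seq_len(n1)),
                       factor(j[ok], levels = seq_len(n2)))
            img <- matrix(as.numeric(t), n1, n2)
        }
    }
    PixelImage(img, pixelSize, origin = c(bounds[1], bounds[3]))
}

#' Write / read a PixelImage as 32-bit float TIFF
#'
#' Pixel values are stored scaled to [0, 1]; the scale factor, pixel size and
#' origin travel in a JSON sidecar file (\code{<path>.json}), so the round
#' trip restores physical values and geometry.
#'
#' @param image a \linkS4class{PixelImage}.
#' @param path file path.
#' @return \code{writePixelImage}: the path, invisibly; \code{readPixelImage}:
#'   a \linkS4class{PixelImage}.
#' @export
writePixelImage <- function(image, path) {
    px <- pixelData(image)
    lo <- min(px, 0)
    scale <- max(px - lo, 1e-300)
    jsonlite::write_json(list(pixel_size_nm = pixelSize(image),
                              origin_nm = imageOrigin(image),
                              offset = lo, scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    suppressWarnings(tiff::writeTIFF((t(px) - lo) / scale, path,
                                     bits.per.sample = 32L,
                                     reduce = FALSE, compression = "none"))
    invisible(path)
}

#' @rdname writePixelImage
#' @export
readPixelImage <- function(path) {
    img <- tiff::readTIFF(path)
    meta <- jsonlite::fromJSON(paste0(path, ".json"))
    PixelImage(t(img) * meta$scale + meta$offset, meta$pixel_size_nm,
               meta$origin_nm)
}

#' Write / read a Volume3D in MRC format
#'
#' Minimal MRC2014 mode-2 (float32, little-endian) I/O. The voxel size is
#' stored in the cell dimensions (in Angstrom, 1 nm = 10 A).
#'
#' @param volume a \linkS4class{Volume3D}.
#' @param path file path.
#' @return \code{writeVolumeMRC}: the path, invisibly; \code{readVolumeMRC}: a
#'   \linkS4class{Volume3D}.
#' @export
writeVolumeMRC <- function(volume, path) {
    v <- voxelData(volume)
    d <- dim(v)
    con <- file(path, "wb")
    on.exit(close(con))
    wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
    wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
    wInt(d)                     # nx ny nz
    wInt(2)                     # mode 2: float32
    wInt(c(0, 0, 0))            # nxstart
    wInt(d)                     # mx my mz
    wFlt(d * pixelSize(volume) * 10)  # cell (A)
    wFlt(c(90, 90, 90))         # cell angles
    wInt(c(1, 2, 3))            # axis mapping
    wFlt(c(min(v), max(v), mean(v)))
    wInt(c(0, 0))               # ispg, nsymbt
    wInt(rep(0, 25))            # extra
    wFlt(imageOrigin(volume) * 10)    # origin (A)
    writeChar("MAP ", con, nchars = 4, eos = NULL)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
    wFlt(stats::sd(v))
    wInt(0)                     # nlabl
    writeBin(raw(800), con)
    wFlt(as.vector(v))
    invisible(path)
}

#' @rdname writeVolumeMRC
#' @export
readVolumeMRC <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    rInt <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
    rFlt <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
    d <- rInt(3)
    mode <- rInt(1)
    if (mode != 2) stop("only MRC mode 2 (float32) is supported")
    rInt(3); rInt(3)
    cell <- rFlt(3)
    rFlt(3); rInt(3); rFlt(3); rInt(2); rInt(25)
    origin <- rFlt(3) / 10
    seek(con, 1024)
    v <- array(rFlt(prod(d)), dim = d)
    Volume3D(v, voxelSize = cell[1] / d[1] / 10, origin = origin)
}
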