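#' @include AllClasses.R accessors.R
NULL

#' Merge consecutive localizations of the same fluorophore
#'
#' A blinking fluorophore that stays on over several camera frames produces a
#' chain of localizations. For each original localization N on frame n,
#' localizations within \code{radius} of N on frame n + 1 are searched for; if
#' found, the search continues on frame n + 2, and stops at the first frame
#' without a candidate. All chain members are merged into a single record
#' assigned to frame n whose coordinates are the unweighted average of the
#' chain and whose photon count is the sum. Distances are always measured to
#' the chain's origin localization N; chains are seeded in (frame, id) order,
#' a localization belongs to at most one chain, and only localizations of the
#' same channel are chained. When several candidates fall within the radius
#' the nearest is taken, ties broken by the lower id.
#'
#' @param table a \linkS4class{LocalizationTable}, sorted by frame.
#' @param radius search radius in nm (default 50).
#' @param autoSort sort an unsorted table with a warning instead of failing.
#' @return The merged \linkS4class{LocalizationTable}; total photons are
#'   conserved exactly and the localization count never increases.
#' @export
mergeConsecutive <- function(table, radius = 50, autoSort = FALSE) {
    stopifnot(radius > 0)
    d <- locData(table)
    if (is.unsorted(d$frame)) {
        if (!autoSort) stop("table must be sorted by frame ",
                            "(or pass autoSort = TRUE)")
        warning("auto-sorting localization table by (frame, id) before merging")
        d <- d[order(d$frame, d$id), , drop = FALSE]
    }
    n <- nrow(d)
    if (n <= 1) return(new("LocalizationTable", data = d))
    use3d <- !all(is.na(d$z))
    byFrame <- split(seq_len(n), d$frame)
    frameKey <- names(byFrame)
    available <- rep(TRUE, n)
    ord <- order(d$frame, d$id)
    chainOf <- integer(n)           # chain id per localization
    nextChain <- 0L
    for (o in ord) {
        if (!available[o]) next
        available[o] <- FALSE
        nextChain <- nextChain + 1L
        chainOf[o] <- nextChain
        f <- d$frame[o]
        repeat {
            f <- f + 1L
            cand <- byFrame[[as.character(f)]]
            if (is.null(cand)) break
            cand <- cand[available[cand] & d$channel[cand] == d$channel[o]]
            if (!length(cand)) break
            dist2 <- (d$x[cand] - d$x[o])^2 + (d$y[cand] - d$y[o])^2
            if (use3d) dist2 <- dist2 + (d$z[cand] - d$z[o])^2
            within <- dist2 <= radius^2
            if (!any(within)) break
            cand <- cand[within]; dist2 <- dist2[within]
            pick <- cand[order(dist2, d$id[cand])][1]
            available[pick] <- FALSE
            chainOf[pick] <- nextChain
        }
    }
    first <- match(seq_len(nextChain), chainOf[ord])   # origin = chain seed
    origin <- ord[first]
    k <- tabulate(chainOf, nextChain)
    out <- d[origin, , drop = FALSE]
    out$x <- as.vector(tapply(d$x, chainOf, mean))
    out$y <- as.vector(tapply(d$y, chainOf, mean))
    if (use3d) out$z <- as.vector(tapply(d$z, chainOf, mean))
    out$photons <- as.vector(tapply(d$photons, chainOf, sum))
    out$sigma <- as.vector(tapply(d$sigma, chainOf, mean)) / sqrt(k)
    out <- out[order(out$frame, out$id), , drop = FALSE]
    rownames(out) <- NULL
    new("LocalizationTable", data = out)
}
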