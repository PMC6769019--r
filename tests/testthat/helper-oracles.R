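# Independent brute-force oracles and shared fixture builders.

# Literal chain tracer for consecutive-localization merging, written directly
# from the stated rule and independent of the package implementation: for
# each origin localization N (visited in (frame, id) order), search frame
# n + 1 for unconsumed same-channel localizations within `radius` of N, take
# the nearest (ties: lower id), continue on n + 2, stop at the first frame
# without a hit; merge the chain to (first frame, mean coords, summed
# photons).
bruteForceMerge <- function(df, radius = 50) {
    df <- df[order(df$frame, df$id), , drop = FALSE]
    n <- nrow(df)
    consumed <- rep(FALSE, n)
    out <- NULL
    use3d <- !all(is.na(df$z))
    for (o in seq_len(n)) {
        if (consumed[o]) next
        consumed[o] <- TRUE
        chain <- o
        f <- df$frame[o]
        repeat {
            f <- f + 1
            cand <- which(!consumed & df$frame == f &
                          df$channel == df$channel[o])
            if (!length(cand)) break
            dd <- sqrt((df$x[cand] - df$x[o])^2 + (df$y[cand] - df$y[o])^2 +
                       if (use3d) (df$z[cand] - df$z[o])^2 else 0)
            hit <- cand[dd <= radius]
            if (!length(hit)) break
            ddh <- dd[dd <= radius]
            best <- hit[order(ddh, df$id[hit])][1]
            consumed[best] <- TRUE
            chain <- c(chain, best)
        }
        out <- rbind(out, data.frame(
            id = df$id[o], frame = df$frame[o],
            x = mean(df$x[chain]), y = mean(df$y[chain]),
            z = if (use3d) mean(df$z[chain]) else NA_real_,
            photons = sum(df$photons[chain]), channel = df$channel[o]))
    }
    out[order(out$frame, out$id), , drop = FALSE]
}

# Random localization table for merge property tests: events concentrated so
# that chains actually form.
randomEventTable <- function(n = 200, seed = 1, nFrames = 20, extent = 400) {
    withr::with_seed(seed, {
        LocalizationTable(x = runif(n, 0, extent), y = runif(n, 0, extent),
                          frame = sort(sample.int(nFrames, n, replace = TRUE)),
                          photons = rpois(n, 800),
                          channel = sample(1:2, n, replace = TRUE))
    })
}

# A small shell-cluster field with ground truth, shared across tests.
shellField <- function(nClusters = 5, nMol = 400, seed = 3, sigma = 10,
                       kind = "shell", dims = 2, fieldNm = 3000,
                       background = 1e-3, nFrames = 5000, channel = 1L,
                       subcluster = 0L) {
    centers <- withr::with_seed(seed + 1000, {
        k <- ceiling(sqrt(nClusters))
        pitch <- fieldNm / (k + 1)
        idx <- seq_len(nClusters) - 1
        cbind(pitch * (idx %% k + 1) + runif(nClusters, -60, 60),
              pitch * (idx %/% k + 1) + runif(nClusters, -60, 60),
              300 + runif(nClusters, -50, 50))
    })
    models <- lapply(seq_len(nClusters), function(i)
        ClusterModel(kind, 280, 100, nMolecules = nMol, center = centers[i, ],
                     channel = channel, subclusterCount = subcluster))
    acq <- AcquisitionModel(nFrames = nFrames, meanOnFrames = 3,
                            locPrecision = sigma, meanPhotons = 1000,
                            backgroundDensity = background,
                            fieldSize = c(fieldNm, fieldNm, 600), seed = seed)
    sim <- simulateField(models, acq, dims = dims)
    sim$centers <- centers
    sim
}
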