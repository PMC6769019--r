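#' @include AllClasses.R accessors.R
NULL

#' Per-localization Voronoi densities
#'
#' Builds the Voronoi tessellation of the localization coordinates and derives
#' a local density for every localization as the inverse of its cell measure.
#' The first-rank averaged density (mean of 1/measure over the cell and its
#' Delaunay neighbours, finite cells only) is a smoother estimator and is the
#' default used by rendering and segmentation. Unbounded border cells are
#' flagged and excluded from density statistics.
#'
#' In 2D the tessellation is exact (deldir). In 3D a discrete Voronoi diagram
#' is computed on a voxel grid: every voxel is assigned to its nearest
#' localization, cell volumes are voxel counts times the voxel volume, and
#' adjacency is face-sharing of discrete cells, which approximates the
#' Delaunay adjacency at voxel resolution.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param dims 2 or 3 (default: dimensionality of the table).
#' @param voxelSize 3D only: edge of the discretization voxel in nm
#'   (default: chosen so the grid stays below \code{maxVoxels}).
#' @param maxVoxels 3D only: cap on the grid size (default 4e6).
#' @return A \linkS4class{VoronoiDensity}.
#' @export
voronoiDensities <- function(table, dims = locDims(table), voxelSize = NULL,
                             maxVoxels = 4e6) {
    cc <- locCoords(table)
    n <- nrow(cc)
    if (n < dims + 2)
        stop("need at least dims + 2 localizations for a tessellation")
    if (dims == 2) {
        x <- cc[, 1]; y <- cc[, 2]
        if (anyDuplicated(cbind(x, y)))
            stop("duplicate coordinates; merge or jitter before tessellating")
        ext <- c(diff(range(x)), diff(range(y)))
        if (any(ext == 0) ||
            qr(sweep(cbind(x, y), 2, c(mean(x), mean(y))))$rank < 2)
            stop("degenerate collinear input")
        pad <- 0.05 * ext
        rw <- c(min(x) - pad[1], max(x) + pad[1], min(y) - pad[2], max(y) + pad[2])
        dd <- deldir::deldir(x, y, rw = rw)
        measure <- dd$summary$dir.area
        finite <- dd$summary$nbpt == 0
        edges <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
    } else {
        if (all(is.na(locData(table)$z))) stop("3D tessellation needs z data")
        lo <- apply(cc, 2, min); hi <- apply(cc, 2, max)
        if (any(hi - lo == 0)) stop("degenerate coplanar input")
        if (is.null(voxelSize))
            voxelSize <- max(2, (prod(hi - lo + 4) / maxVoxels)^(1 / 3))
        lo <- lo - 2 * voxelSize; hi <- hi + 2 * voxelSize
        nd <- pmax(2L, ceiling((hi - lo) / voxelSize))
        # group coincident-voxel points; tessellate group representatives
        pix <- floor(sweep(cc, 2, lo) / voxelSize)
        key <- pix[, 1] + nd[1] * (pix[, 2] + nd[2] * pix[, 3])
        grp <- match(key, unique(key))
        rep1 <- match(seq_len(max(grp)), grp)
        pts <- cc[rep1, , drop = FALSE]
        ax <- lapply(1:3, function(a) lo[a] + (seq_len(nd[a]) - 0.5) * voxelSize)
        vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
        lab <- RANN::nn2(pts, vox, k = 1)$nn.idx[, 1]
        labArr <- array(lab, nd)
        counts <- tabulate(lab, nbins = nrow(pts))
        groupSize <- tabulate(grp, nbins = nrow(pts))
        measure <- counts[grp] * voxelSize^3 / groupSize[grp]
        # cells reaching the grid boundary are unbounded
        bnd <- unique(c(labArr[1, , ], labArr[nd[1], , ], labArr[, 1, ],
                        labArr[, nd[2], ], labArr[, , 1], labArr[, , nd[3]]))
        finite <- !(grp %in% bnd)
        pairUp <- function(a, b) {
            keep <- a != b
            cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
        }
        e <- rbind(pairUp(labArr[-nd[1], , ], labArr[-1, , ]),
                   pairUp(labArr[, -nd[2], ], labArr[, -1, ]),
                   pairUp(labArr[, , -nd[3]], labArr[, , -1]))
        e <- unique(e)
        # map representative adjacency back to localization indices and add
        # intra-group edges
        full <- cbind(rep1[e[, 1]], rep1[e[, 2]])
        extra <- which(grp != seq_along(grp) | duplicated(grp))
        if (length(extra)) {
            more <- cbind(extra, rep1[grp[extra]])
            more <- more[more[, 1] != more[, 2], , drop = FALSE]
            full <- rbind(full, more)
        }
        edges <- full
    }
    density <- ifelse(finite & measure > 0, 1 / measure, NA_real_)
    nbr <- vector("list", n)
    adjDensitySum <- numeric(n); adjDensityN <- integer(n)
    addSide <- function(a, b) {
        v <- density[b]
        ok <- !is.na(v)
        s <- tapply(v[ok], a[ok], sum)
        k <- tapply(rep(1L, sum(ok)), a[ok], sum)
        i <- as.integer(names(s))
        adjDensitySum[i] <<- adjDensitySum[i] + as.vector(s)
        adjDensityN[i] <<- adjDensityN[i] + as.vector(k)
    }
    if (nrow(edges)) {
        addSide(edges[, 1], edges[, 2])
        addSide(edges[, 2], edges[, 1])
    }
    self <- !is.na(density)
    adjDensitySum[self] <- adjDensitySum[self] + density[self]
    adjDensityN[self] <- adjDensityN[self] + 1L
    densityAvg <- ifelse(adjDensityN > 0, adjDensitySum / adjDensityN, NA_real_)
    new("VoronoiDensity",
        stats = data.frame(measure = measure, density = density,
                           densityAvg = densityAvg, finite = finite),
        edges = edges, dims = as.integer(dims))
}

#' Render a Voronoi density map
#'
#' Every pixel (or voxel) takes the first-rank averaged density of the
#' localization whose Voronoi cell contains its center (nearest-localization
#' assignment); empty regions beyond \code{maxDistance} from any localization
#' are set to 0.
#'
#' @param vd a \linkS4class{VoronoiDensity} computed from \code{table}.
#' @param table the corresponding \linkS4class{LocalizationTable}.
#' @param pixelSize output pixel/voxel edge, nm.
#' @param bounds optional bounds (c(xmin, xmax, ymin, ymax[, zmin, zmax])).
#' @param maxDistance cutoff distance in nm (default: 5x the median
#'   nearest-neighbour distance).
#' @return A \linkS4class{PixelImage} (2D) or \linkS4class{Volume3D} (3D).
#' @export
renderDensityMap <- function(vd, table, pixelSize, bounds = NULL,
                             maxDistance = NULL) {
    cc <- locCoords(table)
    dims <- vd@dims
    cc <- cc[, seq_len(dims), drop = FALSE]
    if (is.null(maxDistance)) {
        nnd <- RANN::nn2(cc, cc, k = 2)$nn.dists[, 2]
        maxDistance <- 5 * stats::median(nnd)
    }
    if (is.null(bounds)) {
        lo <- apply(cc, 2, min); hi <- apply(cc, 2, max)
        bounds <- as.vector(rbind(floor(lo / pixelSize) * pixelSize,
                                  ceiling(hi / pixelSize) * pixelSize))
    }
    lo <- bounds[seq(1, 2 * dims, 2)]; hi <- bounds[seq(2, 2 * dims, 2)]
    nd <- pmax(1L, round((hi - lo) / pixelSize))
    ax <- lapply(seq_len(dims),
                 function(a) lo[a] + (seq_len(nd[a]) - 0.5) * pixelSize)
    grid <- as.matrix(do.call(expand.grid, ax))
    nn <- RANN::nn2(cc, grid, k = 1)
    val <- densityStats(vd)$densityAvg[nn$nn.idx[, 1]]
    val[is.na(val)] <- 0
    val[nn$nn.dists[, 1] > maxDistance] <- 0
    if (dims == 2) PixelImage(matrix(val, nd[1], nd[2]), pixelSize, lo)
    else Volume3D(array(val, nd), pixelSize, lo)
}

#' Segment clusters by density threshold
#'
#' Localizations whose first-rank averaged Voronoi density exceeds a threshold
#' are linked through Delaunay edges (both endpoints above threshold) into
#' connected components; components smaller than \code{minSize} are dropped to
#' background. The threshold is either given absolutely or derived by a
#' Monte-Carlo rule: the density exceeded by at most \code{alpha} of the
#' localizations of matched uniform simulations (same count, same bounding
#' extent).
#'
#' @param vd a \linkS4class{VoronoiDensity} for \code{table}.
#' @param table the corresponding \linkS4class{LocalizationTable}.
#' @param threshold absolute density threshold (nm^-2 / nm^-3); \code{NULL}
#'   (default) selects the Monte-Carlo rule.
#' @param alpha Monte-Carlo tail probability (default 0.05).
#' @param nSim number of uniform simulations (default 10).
#' @param minSize minimum cluster size in localizations (default 25).
#' @param seed seed for the Monte-Carlo simulations.
#' @param maxEdge maximum length (nm) of a Delaunay edge that may link two
#'   above-threshold localizations; longer edges span empty space between
#'   distinct clusters and are cut. Default: 5x the median nearest-neighbour
#'   distance.
#' @return A \linkS4class{SegmentationResult}; cluster labels are 1, 2, ... in
#'   decreasing cluster size, 0 marks background. Equivalent diameters use
#'   the robust occupied measure (member count times the median member cell
#'   measure), which is insensitive to the huge border cells of a cluster.
#' @export
segmentClusters <- function(vd, table, threshold = NULL, alpha = 0.05,
                            nSim = 10, minSize = 25L, seed = 1L,
                            maxEdge = NULL) {
    cc <- locCoords(table)[, seq_len(vd@dims), drop = FALSE]
    n <- nrow(cc)
    if (is.null(maxEdge)) {
        nnd <- RANN::nn2(cc, cc, k = 2)$nn.dists[, 2]
        maxEdge <- 5 * stats::median(nnd)
    }
    if (is.null(threshold)) {
        lo <- apply(cc, 2, min); hi <- apply(cc, 2, max)
        simDens <- withSeed(seed, {
            unlist(lapply(seq_len(nSim), function(i) {
                u <- vapply(seq_len(ncol(cc)),
                            function(a) stats::runif(n, lo[a], hi[a]),
                            numeric(n))
                ut <- LocalizationTable(x = u[, 1], y = u[, 2],
                                        z = if (ncol(u) == 3) u[, 3] else NULL)
                sv <- voronoiDensities(ut, dims = vd@dims)
                stats::na.omit(densityStats(sv)$densityAvg)
            }))
        })
        threshold <- stats::quantile(simDens, 1 - alpha, names = FALSE)
    }
    v <- densityStats(vd)$densityAvg
    above <- !is.na(v) & v >= threshold
    labels <- integer(n)
    if (any(above)) {
        e <- vd@edges
        elen <- sqrt(rowSums((cc[e[, 1], , drop = FALSE] -
                              cc[e[, 2], , drop = FALSE])^2))
        keep <- above[e[, 1]] & above[e[, 2]] & elen <= maxEdge
        g <- igraph::make_empty_graph(n = n, directed = FALSE)
        if (any(keep))
            g <- igraph::add_edges(g, t(e[keep, , drop = FALSE]))
        comp <- igraph::components(g)$membership
        comp[!above] <- NA
        sizes <- base::table(comp)
        big <- as.integer(names(sizes)[sizes >= minSize])
        ord <- big[order(-sizes[as.character(big)])]
        relabel <- integer(max(comp, na.rm = TRUE))
        relabel[ord] <- seq_along(ord)
        labels[above] <- relabel[comp[above]]
    }
    ks <- sort(unique(labels[labels > 0]))
    clusters <- do.call(rbind, lapply(ks, function(k) {
        idx <- which(labels == k)
        ctr <- colMeans(cc[idx, , drop = FALSE])
        meas <- densityStats(vd)$measure[idx]
        meas <- meas[densityStats(vd)$finite[idx]]
        tot <- length(idx) * stats::median(meas)
        eq <- if (vd@dims == 2) 2 * sqrt(tot / pi) else 2 * (3 * tot / (4 * pi))^(1 / 3)
        data.frame(label = k, n = length(idx),
                   cx = ctr[1], cy = ctr[2],
                   cz = if (vd@dims == 3) ctr[3] else NA_real_,
                   eqDiameter = eq)
    }))
    if (is.null(clusters))
        clusters <- data.frame(label = integer(0), n = integer(0),
                               cx = numeric(0), cy = numeric(0),
                               cz = numeric(0), eqDiameter = numeric(0))
    new("SegmentationResult", labels = labels, clusters = clusters,
        threshold = as.numeric(threshold))
}

#' Write a segmentation as canonical CSV with a cluster column
#'
#' @param table the segmented \linkS4class{LocalizationTable}.
#' @param seg the matching \linkS4class{SegmentationResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSegmentation <- function(table, seg, path) {
    d <- locData(table)
    d$cluster <- clusterLabels(seg)
    writeLocalizations(new("LocalizationTable", data = d), path)
}
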