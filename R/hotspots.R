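#' Otsu threshold for a one-dimensional expression vector
#'
#' Splits the values into a low and a high class at the boundary that
#' minimizes the total within-class variance (equivalently, maximizes the
#' between-class variance). Candidate thresholds are the midpoints between
#' consecutive distinct sorted values, so the procedure is exact and
#' histogram-free for continuous data. The high mask uses strict inequality.
#'
#' @param values Non-negative numeric vector with at least 2 distinct values.
#' @return A list with `threshold` and logical `mask` (`values > threshold`).
#' @export
otsu_threshold <- function(values) {
    values <- as.numeric(values)
    u <- sort(unique(values))
    if (length(u) < 2) stopf("cannot threshold a constant vector")
    cnt <- tabulate(match(values, u), length(u))
    csum <- cumsum(cnt * u)
    ccnt <- cumsum(cnt)
    n <- length(values)
    total <- csum[length(u)]
    k <- seq_len(length(u) - 1L)          # split after the k-th distinct value
    w0 <- ccnt[k]
    w1 <- n - w0
    mu0 <- csum[k] / w0
    mu1 <- (total - csum[k]) / w1
    between <- w0 * w1 * (mu0 - mu1)^2
    best <- which.max(between)            # ties: lowest threshold
    thr <- (u[best] + u[best + 1L]) / 2
    list(threshold = thr, mask = values > thr)
}

#' Hotspot detection configuration
#'
#' @param epsilon Density-clustering radius, in the dataset's spatial units.
#'   For spot arrays, set just above the distance between adjacent spots; for
#'   single-cell data, choose so that most cells have 10-15 neighbors within
#'   `epsilon`.
#' @param local_density Fraction in (0, 1]; the DBSCAN `min_samples` is
#'   `round(local_density * mean neighbor count)` over the high-expression
#'   points (floor 2). Recommended 0.5 for multi-cell resolution, 0.2 for
#'   single-cell resolution.
#' @param hotspot_min_size Minimum number of cells to keep a hotspot.
#' @param closure Apply alpha-shape closure to each hotspot (recommended for
#'   multi-cell spot arrays; off by default since it is not tractable at
#'   single-cell resolution).
#' @return A `hotspot_config` list.
#' @export
hotspot_config <- function(epsilon, local_density = 0.5,
                           hotspot_min_size = 10L, closure = FALSE) {
    stopifnot(epsilon > 0, local_density > 0, local_density <= 1,
              hotspot_min_size >= 1)
    structure(list(epsilon = epsilon, local_density = local_density,
                   hotspot_min_size = as.integer(hotspot_min_size),
                   closure = isTRUE(closure)),
              class = "hotspot_config")
}

new_gene_hotspot <- function(gene, members, closed = FALSE, source_layer = NA_integer_,
                             threshold = NA_real_) {
    structure(list(gene = gene, members = as.integer(members), closed = closed,
                   source_layer = source_layer, threshold = threshold),
              class = "gene_hotspot")
}

#' @exportS3Method print gene_hotspot
print.gene_hotspot <- function(x, ...) {
    cat(sprintf("gene_hotspot %s: %d cells%s%s\n", x$gene, length(x$members),
                if (x$closed) " (closed)" else "",
                if (!is.na(x$source_layer)) sprintf(" [layer %d]", x$source_layer) else ""))
    invisible(x)
}

# DBSCAN on a precomputed epsilon-neighbor edge list (both directions).
# `deg_ref` gives each point's total neighbor count in the reference
# universe (all dataset cells); min_samples = round(density * mean reference
# neighbor count over the high points), floor 2, so that core points are
# those where roughly a `local_density` fraction of nearby cells is high.
# Returns a list of integer vectors (cluster members, global indices),
# ordered by smallest member index. Border points join the cluster of their
# lowest-indexed core neighbor.
dbscan_on_edges <- function(n, ei, ej, mask, local_density, min_size,
                            deg_ref = NULL) {
    if (!any(mask)) return(list())
    keep <- mask[ei] & mask[ej]
    ei <- ei[keep]; ej <- ej[keep]
    deg <- tabulate(ei, n)                    # other in-radius high points
    if (is.null(deg_ref)) deg_ref <- deg
    ms <- max(2L, as.integer(round(local_density * mean(deg_ref[mask]))))
    core <- mask & deg >= ms
    if (!any(core)) return(list())
    cc <- core[ei] & core[ej]
    lab <- uf_components(n, ei[cc], ej[cc])   # labels over all n nodes
    lab[!core] <- NA_integer_
    # border points: non-core high points adjacent to a core point
    bsel <- !core[ei] & mask[ei] & core[ej]
    if (any(bsel)) {
        bi <- ei[bsel]; bj <- ej[bsel]
        o <- order(bi, bj)                    # fixed scan order: lowest core idx
        first <- !duplicated(bi[o])
        lab[bi[o][first]] <- lab[bj[o][first]]
    }
    cl <- split(seq_len(n)[!is.na(lab)], lab[!is.na(lab)])
    cl <- cl[vapply(cl, length, 1L) >= min_size]
    if (!length(cl)) return(list())
    cl <- unname(cl)
    cl[order(vapply(cl, min, 1L))]
}

#' Density-based clustering of high-expression points into hotspots
#'
#' DBSCAN over a set of 2D points: core points have at least `min_samples`
#' other points within radius `epsilon`, core points within `epsilon` of each
#' other are connected, and non-core points adjacent to a core point join the
#' cluster of their lowest-indexed core neighbor. `min_samples` is
#' `cfg$local_density` times the mean neighbor count within `epsilon` (floor
#' 2); when `ref_coords` is supplied (the full dataset's cells), neighbors
#' are counted in that universe, so core points are those where roughly a
#' `local_density` fraction of the surrounding cells is high-expression.
#' Clusters smaller than `cfg$hotspot_min_size` are discarded.
#'
#' @param points Numeric matrix of point coordinates (rows = points).
#' @param cfg A [hotspot_config()].
#' @param gene Label attached to the resulting hotspots.
#' @param point_index Optional integer vector mapping rows of `points` to
#'   cell indices in a dataset (defaults to row numbers).
#' @param source_layer Optional layer index recorded on the hotspots.
#' @param ref_coords Optional coordinates of the reference universe used for
#'   the `min_samples` neighbor count (defaults to `points` themselves).
#' @return List of `gene_hotspot` objects.
#' @export
dbscan_hotspots <- function(points, cfg, gene = NA_character_,
                            point_index = NULL, source_layer = NA_integer_,
                            ref_coords = NULL) {
    stopifnot(inherits(cfg, "hotspot_config"))
    points <- as.matrix(points)
    np <- nrow(points)
    if (np == 0) return(list())
    if (is.null(point_index)) point_index <- seq_len(np)
    pr <- radius_pairs(points, cfg$epsilon)
    deg_ref <- NULL
    if (!is.null(ref_coords)) {
        nn <- RANN::nn2(as.matrix(ref_coords), points,
                        searchtype = "radius", radius = cfg$epsilon,
                        k = min(nrow(ref_coords), 256L))
        deg_ref_pts <- rowSums(nn$nn.idx != 0) - 1  # exclude self
        deg_ref <- numeric(np)
        deg_ref[] <- deg_ref_pts
    }
    cl <- dbscan_on_edges(np, pr$i, pr$j, rep(TRUE, np),
                          cfg$local_density, cfg$hotspot_min_size, deg_ref)
    lapply(cl, function(m) new_gene_hotspot(gene, point_index[m],
                                            source_layer = source_layer))
}

#' Compute single-gene hotspots for every gene of a dataset
#'
#' For each gene: binarize with [otsu_threshold()], run density clustering on
#' the high-expression cells, keep clusters of at least
#' `cfg$hotspot_min_size` cells, and optionally close each hotspot with an
#' alpha shape. Constant genes and genes yielding no cluster contribute
#' nothing, so this step doubles as a spatially-variable gene filter. For
#' layered (3D) data the procedure runs per layer and records the source
#' layer on each hotspot.
#'
#' @param d A preprocessed [spatial_dataset()].
#' @param cfg A [hotspot_config()].
#' @param genes Optional subset of gene names to process.
#' @return List of `gene_hotspot` objects (all genes concatenated).
#' @export
compute_all_gene_hotspots <- function(d, cfg, genes = NULL) {
    stopifnot(inherits(d, "spatial_dataset"), inherits(cfg, "hotspot_config"))
    if (is.null(genes)) genes <- colnames(d$expression)
    layers <- if (is.null(d$layer_index)) list(seq_len(n_cells(d)))
              else split(seq_len(n_cells(d)), d$layer_index)
    out <- list()
    n_constant <- 0L
    for (lname in seq_along(layers)) {
        cells <- layers[[lname]]
        lay <- if (is.null(d$layer_index)) NA_integer_
               else unique(d$layer_index[cells])[1]
        pr <- radius_pairs(d$coords[cells, , drop = FALSE], cfg$epsilon)
        n <- length(cells)
        deg_all <- tabulate(pr$i, n)          # neighbor count among all cells
        for (g in genes) {
            v <- d$expression[cells, g]
            ot <- tryCatch(otsu_threshold(v), error = function(e) NULL)
            if (is.null(ot)) { n_constant <- n_constant + 1L; next }
            if (sum(ot$mask) < cfg$hotspot_min_size) next
            cl <- dbscan_on_edges(n, pr$i, pr$j, ot$mask,
                                  cfg$local_density, cfg$hotspot_min_size,
                                  deg_all)
            for (m in cl) {
                out[[length(out) + 1L]] <- new_gene_hotspot(
                    g, cells[m], source_layer = lay, threshold = ot$threshold)
            }
        }
    }
    if (n_constant > 0) {
        warnf("%d constant gene/layer combination(s) skipped", n_constant)
    }
    if (cfg$closure) out <- lapply(out, close_hotspot, d = d)
    out
}

#' Export hotspots as a flat table
#'
#' @param hotspots List of `gene_hotspot` objects.
#' @param d The originating [spatial_dataset()].
#' @param file Optional CSV path to write.
#' @return A data frame with columns `hotspot_id`, `gene`, `cell_id`.
#' @export
hotspot_table <- function(hotspots, d, file = NULL) {
    tab <- data.frame(
        hotspot_id = rep(seq_along(hotspots) - 1L,
                         vapply(hotspots, function(h) length(h$members), 1L)),
        gene = rep(vapply(hotspots, function(h) h$gene, ""),
                   vapply(hotspots, function(h) length(h$members), 1L)),
        cell_id = rownames(d$expression)[unlist(lapply(hotspots, function(h) h$members))])
    if (!is.null(file)) data.table::fwrite(tab, file)
    tab
}
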