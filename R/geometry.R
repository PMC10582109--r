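# Planar geometry helpers: Delaunay triangulation (via deldir), alpha-shape
# selection by bisection, and point-in-triangle membership tests.

# Delaunay triangles of a 2D point set. Returns a list with `tri` (m x 3
# vertex indices into the input) and `circumradius` (length m), or NULL for
# degenerate (collinear / < 3 point) input.
delaunay_triangles <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 3) return(NULL)
    dd <- tryCatch(
        suppressMessages(deldir::deldir(coords[, 1], coords[, 2],
                                        suppressMsge = TRUE)),
        error = function(e) NULL)
    if (is.null(dd)) return(NULL)
    tl <- tryCatch(deldir::triang.list(dd), error = function(e) NULL)
    if (is.null(tl) || !length(tl)) return(NULL)
    tri <- t(vapply(tl, function(t) as.integer(t$ptNum), integer(3)))
    a <- coords[tri[, 1], , drop = FALSE]
    b <- coords[tri[, 2], , drop = FALSE]
    c_ <- coords[tri[, 3], , drop = FALSE]
    la <- sqrt(rowSums((b - c_)^2))
    lb <- sqrt(rowSums((a - c_)^2))
    lc <- sqrt(rowSums((a - b)^2))
    area2 <- abs((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                 (c_[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
    ok <- area2 > 0
    if (!any(ok)) return(NULL)
    list(tri = tri[ok, , drop = FALSE],
         circumradius = (la * lb * lc)[ok] / (2 * area2[ok]))
}

# Are the points inside (or on the boundary of) any of the given triangles?
# Vectorized barycentric test per triangle with a bounding-box prefilter.
points_in_triangles <- function(pts, coords, tri, tol = 1e-9) {
    pts <- as.matrix(pts)
    inside <- rep(FALSE, nrow(pts))
    for (t in seq_len(nrow(tri))) {
        a <- coords[tri[t, 1], ]; b <- coords[tri[t, 2], ]; c_ <- coords[tri[t, 3], ]
        cand <- which(!inside &
                      pts[, 1] >= min(a[1], b[1], c_[1]) - tol &
                      pts[, 1] <= max(a[1], b[1], c_[1]) + tol &
                      pts[, 2] >= min(a[2], b[2], c_[2]) - tol &
                      pts[, 2] <= max(a[2], b[2], c_[2]) + tol)
        if (!length(cand)) next
        det <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
        l1 <- ((b[2] - c_[2]) * (pts[cand, 1] - c_[1]) +
               (c_[1] - b[1]) * (pts[cand, 2] - c_[2])) / det
        l2 <- ((c_[2] - a[2]) * (pts[cand, 1] - c_[1]) +
               (a[1] - c_[1]) * (pts[cand, 2] - c_[2])) / det
        l3 <- 1 - l1 - l2
        eps <- tol * (1 + abs(det))
        inside[cand[l1 >= -eps & l2 >= -eps & l3 >= -eps]] <- TRUE
    }
    inside
}

# Validity of an alpha-complex triangle subset: non-empty, every source point
# is a vertex of a kept triangle, the kept triangles are edge-connected, and
# the boundary edges (edges on exactly one kept triangle) form one simple
# cycle (every boundary vertex has boundary degree 2, one component).
alpha_complex_valid <- function(tri_keep, n_points) {
    if (!nrow(tri_keep)) return(FALSE)
    if (length(unique(as.vector(tri_keep))) < n_points) return(FALSE)
    edges <- rbind(tri_keep[, c(1, 2)], tri_keep[, c(2, 3)], tri_keep[, c(1, 3)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    # edge-connectivity of triangles: union-find on shared-edge incidence
    m <- nrow(tri_keep)
    if (m > 1) {
        tid <- rep(seq_len(m), 3)
        byedge <- split(tid, ekey)
        li <- integer(0); lj <- integer(0)
        for (g in byedge) {
            if (length(g) > 1) { li <- c(li, g[-length(g)]); lj <- c(lj, g[-1]) }
        }
        lab <- uf_components(m, li, lj)
        if (length(unique(lab)) > 1) return(FALSE)
    }
    bnd <- edges[ekey %in% names(which(table(ekey) == 1)), , drop = FALSE]
    if (!nrow(bnd)) return(FALSE)
    degs <- table(as.vector(bnd))
    if (any(degs != 2)) return(FALSE)
    verts <- as.integer(names(degs))
    lab <- uf_components(length(verts),
                         match(bnd[, 1], verts), match(bnd[, 2], verts))
    length(unique(lab)) == 1
}

#' Close a hotspot with an alpha-shape boundary
#'
#' Draws an alpha-shape around the hotspot's member cells and replaces the
#' member set with all dataset cells inside (or on) the boundary; the
#' original members are always retained. The alpha shape generalizes the
#' convex hull: alpha = 0 is the hull, larger alpha values tighten the
#' boundary (the alpha-complex keeps Delaunay triangles with circumradius
#' <= 1/alpha) until it becomes invalid. The largest valid alpha is selected
#' by bisection, where "valid" means a single edge-connected triangle set
#' whose boundary is one simple cycle covering all members. Closure makes
#' the Jaccard similarity between hotspots correspond to overlap in area.
#'
#' @param h A `gene_hotspot`.
#' @param d The [spatial_dataset()] the hotspot belongs to.
#' @return The closed hotspot (degenerate geometry returns the input
#'   unchanged, with a warning).
#' @export
close_hotspot <- function(h, d) {
    stopifnot(inherits(h, "gene_hotspot"), inherits(d, "spatial_dataset"))
    if (h$closed) return(h)
    mem <- h$members
    pts <- d$coords[mem, , drop = FALSE]
    dt <- delaunay_triangles(pts)
    if (is.null(dt)) {
        warnf("hotspot for gene %s has degenerate geometry; closure skipped", h$gene)
        return(h)
    }
    valid_at <- function(alpha) {
        keep <- if (alpha <= 0) rep(TRUE, nrow(dt$tri))
                else dt$circumradius <= 1 / alpha
        alpha_complex_valid(dt$tri[keep, , drop = FALSE], nrow(pts))
    }
    if (!valid_at(0)) {
        warnf("hotspot for gene %s has no valid boundary; closure skipped", h$gene)
        return(h)
    }
    lo <- 0                                  # known valid
    hi <- 1 / min(dt$circumradius) * 1.001   # beyond this the complex is empty
    for (iter in 1:40) {
        mid <- (lo + hi) / 2
        if (valid_at(mid)) lo <- mid else hi <- mid
    }
    keep <- if (lo <= 0) rep(TRUE, nrow(dt$tri)) else dt$circumradius <= 1 / lo
    tri <- dt$tri[keep, , drop = FALSE]
    others <- setdiff(seq_len(n_cells(d)), mem)
    if (length(others)) {
        inside <- points_in_triangles(d$coords[others, , drop = FALSE], pts, tri)
        mem <- sort(c(mem, others[inside]))
    }
    new_gene_hotspot(h$gene, mem, closed = TRUE, source_layer = h$source_layer,
                     threshold = h$threshold)
}
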