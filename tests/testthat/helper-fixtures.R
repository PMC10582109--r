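# Fixtures built in code: small planted datasets used across test files.

# Square grid of side `side`, spacing 1.
grid_coords <- function(side) {
    as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
}

# Dataset with gene expression planted inside rectangular regions.
# regions: named list of list(x = c(lo, hi), y = c(lo, hi), genes = k).
# Planted genes are high (counts ~ 5 + Pois(2)) inside their region and
# mostly zero outside; `n_noise` uniform sparse genes are appended, plus a
# ubiquitous baseline gene so every cell has a positive library size.
make_planted_dataset <- function(side = 20, regions, n_noise = 5, seed = 1) {
    coords <- grid_coords(side)
    n <- nrow(coords)
    withr_seed <- function(expr) { set.seed(seed); expr }
    mats <- withr_seed({
        cols <- list()
        for (rn in names(regions)) {
            r <- regions[[rn]]
            inside <- coords[, 1] >= r$x[1] & coords[, 1] <= r$x[2] &
                      coords[, 2] >= r$y[1] & coords[, 2] <= r$y[2]
            for (g in seq_len(r$genes)) {
                v <- rpois(n, 0.05)
                v[inside] <- 5 + rpois(sum(inside), 2)
                cols[[paste0(rn, "_g", g)]] <- v
            }
        }
        for (g in seq_len(n_noise)) {
            cols[[paste0("noise_g", g)]] <- rpois(n, 0.3)
        }
        cols[["base_g"]] <- 1L + rpois(n, 2)
        do.call(cbind, cols)
    })
    d <- spatial_dataset(mats, coords, units_hint = "grid")
    suppressWarnings(preprocess(d, preprocessing_config()))
}

region_cells <- function(side, x, y) {
    coords <- grid_coords(side)
    which(coords[, 1] >= x[1] & coords[, 1] <= x[2] &
          coords[, 2] >= y[1] & coords[, 2] <= y[2])
}

# Two disjoint gene-coherent square regions with redundant gene sets.
make_two_region_fixture <- function(genes_per_region = 10, side = 20, seed = 1) {
    make_planted_dataset(side, list(
        A = list(x = c(1, 8), y = c(1, 8), genes = genes_per_region),
        B = list(x = c(12, 20), y = c(12, 20), genes = genes_per_region)),
        n_noise = 5, seed = seed)
}

small_det_cfg <- function(min_size = 10) {
    hotspot_config(epsilon = 1.5, local_density = 0.5, hotspot_min_size = min_size)
}

# Independent naive DBSCAN oracle: explicit O(n^2) loops, no shared code
# with the implementation. min_samples counts other points within eps.
naive_dbscan <- function(points, eps, min_samples, min_size) {
    n <- nrow(points)
    if (n == 0) return(list())
    D <- as.matrix(dist(points))
    core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) - 1L >= min_samples,
                   TRUE)
    lab <- rep(0L, n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (!core[i] || lab[i] != 0L) next
        cl <- cl + 1L
        queue <- i
        lab[i] <- cl
        while (length(queue)) {
            p <- queue[1]; queue <- queue[-1]
            nb <- which(D[p, ] <= eps & seq_len(n) != p)
            for (q in nb) {
                if (lab[q] == 0L) {
                    lab[q] <- cl
                    if (core[q]) queue <- c(queue, q)
                }
            }
        }
    }
    out <- split(seq_len(n), lab)
    out <- out[names(out) != "0"]
    out <- out[vapply(out, length, 1L) >= min_size]
    unname(out)
}

# Exhaustive Otsu oracle: try every midpoint threshold, recompute both class
# variances directly.
naive_otsu <- function(values) {
    u <- sort(unique(values))
    cands <- (u[-length(u)] + u[-1]) / 2
    wvar <- vapply(cands, function(t) {
        lo <- values[values <= t]; hi <- values[values > t]
        v <- 0
        if (length(lo) > 1) v <- v + length(lo) * mean((lo - mean(lo))^2)
        if (length(hi) > 1) v <- v + length(hi) * mean((hi - mean(hi))^2)
        v
    }, 1)
    cands[which.min(wvar)]
}

# Brute-force pairwise overlap oracle.
naive_overlap <- function(hotspots) {
    nh <- length(hotspots)
    O <- matrix(0, nh, nh)
    for (a in seq_len(nh)) {
        for (b in seq_len(nh)) {
            if (a != b) O[a, b] <- length(intersect(hotspots[[a]]$members,
                                                    hotspots[[b]]$members))
        }
    }
    O
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of group
# assignments (recomputes ranks for every assignment).
naive_mw_p <- function(x, y) {
    n1 <- length(x); N <- n1 + length(y)
    pooled <- c(x, y)
    ustat <- function(idx) {
        r <- rank(pooled)
        sum(r[idx]) - n1 * (n1 + 1) / 2
    }
    u_obs <- ustat(seq_len(n1))
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2, ustat)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Best assignment score over all permutations (LSA oracle, <= 7 regions).
naive_best_assignment <- function(J) {
    stopifnot(nrow(J) <= ncol(J))
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v)) {
            for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
        }
        out
    }
    best <- -Inf
    for (p in perms(seq_len(ncol(J)))) {
        s <- sum(J[cbind(seq_len(nrow(J)), p[seq_len(nrow(J))])])
        best <- max(best, s)
    }
    best
}

# Sender disc in one corner, receptor expressed everywhere nearby; a second
# far-away sender with no receptor around it.
make_cci_fixture <- function(side = 20, seed = 20) {
    coords <- grid_coords(side)
    n <- nrow(coords)
    sender <- region_cells(side, c(3, 6), c(3, 6))
    far_sender <- region_cells(side, c(16, 19), c(16, 19))
    receptor_zone <- region_cells(side, c(1, 11), c(1, 11))
    set.seed(seed)
    lig <- rpois(n, 0.02)
    lig[c(sender, far_sender)] <- 8 + rpois(length(sender) * 2, 2)
    rec <- rpois(n, 0.02)
    rec[receptor_zone] <- 6 + rpois(length(receptor_zone), 2)
    other <- rpois(n, 1)
    d <- spatial_dataset(cbind(LigA = lig, RecA = rec, other = other), coords)
    d <- suppressWarnings(preprocess(d, preprocessing_config()))
    list(d = d, sender = sender, far_sender = far_sender,
         receptor_zone = receptor_zone)
}

# Two stacked copies of the same layer: matching should pair same-(x, y)
# cells and 3D hotspots should project exactly onto the per-layer ones.
make_stacked_fixture <- function(side = 14, seed = 25) {
    coords1 <- grid_coords(side)
    coords <- rbind(coords1, coords1)
    n1 <- nrow(coords1)
    layer <- rep(1:2, each = n1)
    blobA <- region_cells(side, c(2, 6), c(2, 6))
    blobB <- region_cells(side, c(9, 13), c(9, 13))
    set.seed(seed)
    lig <- rpois(2 * n1, 0.02)
    rec <- rpois(2 * n1, 0.02)
    for (off in c(0, n1)) {
        lig[blobA + off] <- 8 + rpois(length(blobA), 2)
        lig[blobB + off] <- 8 + rpois(length(blobB), 2)
        rec[blobA + off] <- 6 + rpois(length(blobA), 2)
        rec[blobB + off] <- 6 + rpois(length(blobB), 2)
    }
    d <- spatial_dataset(cbind(LigA = lig, RecA = rec), coords,
                         z = layer * 10, layer_index = layer)
    d <- suppressWarnings(preprocess(d, preprocessing_config()))
    list(d = d, blobA = blobA, blobB = blobB, n1 = n1)
}
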