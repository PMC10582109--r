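# 3D extensions: matching active cells across serial sections, multilayer
# community detection over intra-layer proximity graphs plus matched
# inter-layer edges, and 3D region segmentation.

#' Spatial, expression and mixed affinities for 3D region graphs
#'
#' `space_affinity` is `exp(-d / scale)` over spatial distance;
#' `expr_affinity` is `exp(-dz / scale)` over the Euclidean distance between
#' PCA embeddings; `mix_affinity` blends them as
#' `alpha * space + (1 - alpha) * expr`.
#'
#' @param d,dz Distances (spatial; embedding).
#' @param scale Decay scale (defaults 0.04 spatial, 2 embedding — tuned to
#'   the coordinate and embedding scales of imaging-based 3D datasets; set
#'   to match your units).
#' @param space,expr Affinities to blend.
#' @param alpha Spatial weight in the blend (default 0.2).
#' @return Numeric affinity values.
#' @export
space_affinity <- function(d, scale = 0.04) exp(-d / scale)

#' @rdname space_affinity
#' @export
expr_affinity <- function(dz, scale = 2) exp(-dz / scale)

#' @rdname space_affinity
#' @export
mix_affinity <- function(space, expr, alpha = 0.2) alpha * space + (1 - alpha) * expr

# k-nearest-neighbor edges within a point set: unique undirected pairs
# (local indices) with distances.
knn_edges <- function(coords, k) {
    n <- nrow(coords)
    if (n < 2) return(list(i = integer(0), j = integer(0), d = numeric(0)))
    kk <- min(k + 1L, n)
    nn <- RANN::nn2(coords, k = kk)
    i <- rep(seq_len(n), kk - 1L)
    j <- as.vector(nn$nn.idx[, -1])
    dd <- as.vector(nn$nn.dists[, -1])
    lo <- pmin(i, j); hi <- pmax(i, j)
    keep <- !duplicated(cbind(lo, hi))
    list(i = lo[keep], j = hi[keep], d = dd[keep],
         knn = nn$nn.idx[, -1, drop = FALSE])
}

# Linear-sum-assignment matching between two point sets under squared
# Euclidean cost; matches min(n1, n2) pairs. Returns a two-column matrix of
# (index into a, index into b).
lsa_match <- function(a, b) {
    n1 <- nrow(a); n2 <- nrow(b)
    if (n1 == 0 || n2 == 0) return(cbind(integer(0), integer(0)))
    cost <- outer(seq_len(n1), seq_len(n2), function(i, j)
        (a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
    if (n1 <= n2) {
        sol <- clue::solve_LSAP(cost)
        cbind(seq_len(n1), as.integer(sol))
    } else {
        sol <- clue::solve_LSAP(t(cost))
        cbind(as.integer(sol), seq_len(n2))
    }
}

# Greedy multilayer community detection: maximizes
#   sum_l [ sum_{intra edges l} w delta  -  gamma/(2 m_l) sum_{i,j in l} k_i k_j delta ]
#   + sum_{inter edges} w delta
# i.e. an RB-modularity quality per layer slice plus a plain (CPM at
# resolution zero) reward on inter-layer edges. Local moving from singleton
# communities in seed-shuffled order, alternated with greedy community
# merges, until neither improves.
multilayer_communities <- function(n, layer, intra, inter, gamma, seed = 0L) {
    if (n == 0) return(integer(0))
    layers <- sort(unique(layer))
    lidx <- match(layer, layers)
    k <- numeric(n)
    m_l <- numeric(length(layers))
    if (length(intra$i)) {
        for (e in seq_along(intra$i)) {
            w <- intra$w[e]
            k[intra$i[e]] <- k[intra$i[e]] + w
            k[intra$j[e]] <- k[intra$j[e]] + w
            m_l[lidx[intra$i[e]]] <- m_l[lidx[intra$i[e]]] + w
        }
    }
    # combined adjacency list (intra + inter count equally as edge reward)
    ei <- c(intra$i, intra$j, inter$i, inter$j)
    ej <- c(intra$j, intra$i, inter$j, inter$i)
    ew <- c(intra$w, intra$w, inter$w, inter$w)
    adj <- split(data.frame(j = ej, w = ew), factor(ei, levels = seq_len(n)))
    comm <- seq_len(n)
    Kcl <- matrix(0, n, length(layers))        # community x layer strength
    Kcl[cbind(seq_len(n), lidx)] <- k
    pen <- function(node, com) {
        l <- lidx[node]
        if (m_l[l] <= 0) return(0)
        gamma / (2 * m_l[l]) * k[node] * Kcl[com, l]
    }
    ord <- with_seed(seed, sample.int(n))
    repeat {
        moved <- FALSE
        repeat {
            any_move <- FALSE
            for (i in ord) {
                nb <- adj[[i]]
                if (!nrow(nb)) next
                c0 <- comm[i]
                wto <- tapply(nb$w, comm[nb$j], sum)
                cands <- as.integer(names(wto))
                base <- if (as.character(c0) %in% names(wto))
                            wto[[as.character(c0)]] else 0
                # gain of leaving c0 (without i) and joining c
                Kcl[c0, lidx[i]] <- Kcl[c0, lidx[i]] - k[i]
                gains <- vapply(seq_along(cands), function(t) {
                    c2 <- cands[t]
                    (wto[[t]] - base) - (pen(i, c2) - pen(i, c0))
                }, 1)
                best <- which.max(gains)
                if (gains[best] > 1e-12 && cands[best] != c0) {
                    comm[i] <- cands[best]
                    Kcl[cands[best], lidx[i]] <- Kcl[cands[best], lidx[i]] + k[i]
                    any_move <- TRUE
                } else {
                    Kcl[c0, lidx[i]] <- Kcl[c0, lidx[i]] + k[i]
                }
            }
            if (!any_move) break
            moved <- TRUE
        }
        # greedy pairwise community merges over connected community pairs
        merged <- FALSE
        repeat {
            cu <- comm[ei]; cv <- comm[ej]
            sel <- cu != cv
            if (!any(sel)) break
            key <- paste(pmin(cu[sel], cv[sel]), pmax(cu[sel], cv[sel]))
            wsum <- tapply(ew[sel], key, sum) / 2   # both directions present
            prs <- do.call(rbind, strsplit(names(wsum), " "))
            c1 <- as.integer(prs[, 1]); c2 <- as.integer(prs[, 2])
            mgain <- vapply(seq_along(wsum), function(t) {
                p <- sum(ifelse(m_l > 0,
                                gamma / (2 * m_l) * Kcl[c1[t], ] * Kcl[c2[t], ],
                                0))
                wsum[[t]] - p
            }, 1)
            b <- which.max(mgain)
            if (mgain[b] <= 1e-12) break
            comm[comm == c2[b]] <- c1[b]
            Kcl[c1[b], ] <- Kcl[c1[b], ] + Kcl[c2[b], ]
            Kcl[c2[b], ] <- 0
            merged <- TRUE
        }
        if (!moved && !merged) break
    }
    as.integer(factor(comm, levels = unique(comm)))
}

#' Link per-layer interaction hotspots into 3D hotspots
#'
#' Active cells of all per-layer hotspots become nodes of a multilayer
#' network: each cell is connected to its k nearest neighbors in the same
#' layer with weight `exp(-intra_decay * d)`, and to its matched cell in
#' each adjacent layer (matching by linear sum assignment under squared
#' Euclidean cost) with weight `inter_base * a^2`, where `a` counts the
#' cell's k nearest neighbors whose matched partners are k nearest
#' neighbors of the partner — so spatially consistent matchings get more
#' weight. Communities of this network (RB quality at resolution `gamma`
#' on intra-layer edges, plain edge reward on inter-layer edges) are the
#' combined 3D hotspots. Run separately per interaction.
#'
#' @param per_layer_hotspots List of `gene_hotspot` objects with
#'   `source_layer` set (e.g. from [cci_hotspots()] on layered data).
#' @param coords Full dataset n x 2 coordinate matrix.
#' @param k Within-layer nearest-neighbor count (default 20).
#' @param intra_decay Intra-layer weight decay rate (default 0.04).
#' @param inter_base Inter-layer weight scale (default 0.001).
#' @param gamma Intra-layer resolution (default 0.02).
#' @param seed RNG seed for the community search.
#' @param min_size Drop 3D hotspots smaller than this (default 2 cells).
#' @return List of 3D hotspots: each a list with `members` (cell indices),
#'   `layers`, and `interaction` (label of the first constituent).
#' @export
link_3d_hotspots <- function(per_layer_hotspots, coords, k = 20L,
                             intra_decay = 0.04, inter_base = 0.001,
                             gamma = 0.02, seed = 0L, min_size = 2L) {
    hs <- per_layer_hotspots
    if (!length(hs)) return(list())
    layer_of <- vapply(hs, `[[`, 1L, "source_layer")
    if (anyNA(layer_of)) stopf("per-layer hotspots must carry source_layer")
    nodes <- unique(unlist(lapply(hs, `[[`, "members")))
    node_layer <- integer(length(nodes))
    for (h in hs) node_layer[match(h$members, nodes)] <- h$source_layer
    layers <- sort(unique(node_layer))
    n <- length(nodes)
    xy <- coords[nodes, , drop = FALSE]
    intra <- list(i = integer(0), j = integer(0), w = numeric(0))
    knn_of <- vector("list", n)
    for (l in layers) {
        sel <- which(node_layer == l)
        ke <- knn_edges(xy[sel, , drop = FALSE], k)
        intra$i <- c(intra$i, sel[ke$i])
        intra$j <- c(intra$j, sel[ke$j])
        intra$w <- c(intra$w, exp(-intra_decay * ke$d))
        if (length(sel) >= 2) {
            for (r in seq_along(sel)) knn_of[[sel[r]]] <- sel[ke$knn[r, ]]
        }
    }
    match_of <- rep(NA_integer_, n)            # partner in the next layer up
    inter <- list(i = integer(0), j = integer(0), w = numeric(0))
    for (t in seq_len(length(layers) - 1L)) {
        s1 <- which(node_layer == layers[t])
        s2 <- which(node_layer == layers[t + 1L])
        if (!length(s1) || !length(s2)) next   # empty layer: skipped in the chain
        mm <- lsa_match(xy[s1, , drop = FALSE], xy[s2, , drop = FALSE])
        match_of[s1[mm[, 1]]] <- s2[mm[, 2]]
        for (r in seq_len(nrow(mm))) {
            i <- s1[mm[r, 1]]; j <- s2[mm[r, 2]]
            a <- sum(match_of[knn_of[[i]]] %in% knn_of[[j]], na.rm = TRUE)
            w <- inter_base * a^2
            if (w > 0) {
                inter$i <- c(inter$i, i); inter$j <- c(inter$j, j)
                inter$w <- c(inter$w, w)
            }
        }
    }
    comm <- multilayer_communities(n, node_layer, intra, inter, gamma, seed)
    label <- if (!is.null(hs[[1]]$gene)) hs[[1]]$gene else NA_character_
    out <- lapply(split(seq_len(n), comm), function(idx) {
        list(members = sort(nodes[idx]), layers = sort(unique(node_layer[idx])),
             interaction = label)
    })
    out <- out[vapply(out, function(h) length(h$members), 1L) >= min_size]
    out <- unname(out)
    out[order(-vapply(out, function(h) length(h$members), 1L))]
}

#' Three-dimensional region segmentation of a layered dataset
#'
#' Builds a multilayer graph over all cells: within each layer, k-nearest-
#' neighbor edges weighted by a blend of spatial proximity
#' (`exp(-d / space_scale)`) and transcriptional similarity
#' (`exp(-dz / expr_scale)` over distances between `n_pcs`-dimensional PCA
#' embeddings), mixed as `alpha_mix * space + (1 - alpha_mix) * expr`;
#' between adjacent layers, linear-sum-assignment matched pairs under
#' squared Euclidean cost (plain edge reward, no resolution penalty). Leiden-
#' style community labels of this graph are the 3D regions.
#'
#' @param d A preprocessed, layered [spatial_dataset()].
#' @param alpha_mix Spatial weight in the intra-layer blend (default 0.2).
#' @param n_pcs PCA dimensions (default 8; reduced with a warning when the
#'   dataset has fewer genes).
#' @param k Within-layer nearest-neighbor count (default 20).
#' @param space_scale,expr_scale Affinity decay scales (defaults 0.04, 2).
#' @param resolution Intra-layer RB resolution (default 1).
#' @param seed RNG seed.
#' @return Integer region label per cell.
#' @export
regions_3d <- function(d, alpha_mix = 0.2, n_pcs = 8L, k = 20L,
                       space_scale = 0.04, expr_scale = 2,
                       resolution = 1, seed = 0L) {
    stopifnot(inherits(d, "spatial_dataset"))
    if (is.null(d$layer_index) || length(unique(d$layer_index)) < 2) {
        stopf("regions_3d requires a dataset with at least 2 layers")
    }
    if (ncol(d$expression) < n_pcs) {
        warnf("only %d genes: reducing n_pcs from %d", ncol(d$expression), n_pcs)
        n_pcs <- ncol(d$expression)
    }
    emb <- prcomp(d$expression, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
    n <- n_cells(d)
    layers <- sort(unique(d$layer_index))
    intra <- list(i = integer(0), j = integer(0), w = numeric(0))
    for (l in layers) {
        sel <- which(d$layer_index == l)
        ke <- knn_edges(d$coords[sel, , drop = FALSE], k)
        if (!length(ke$i)) next
        dz <- sqrt(rowSums((emb[sel[ke$i], , drop = FALSE] -
                            emb[sel[ke$j], , drop = FALSE])^2))
        intra$i <- c(intra$i, sel[ke$i])
        intra$j <- c(intra$j, sel[ke$j])
        intra$w <- c(intra$w, mix_affinity(space_affinity(ke$d, space_scale),
                                           expr_affinity(dz, expr_scale),
                                           alpha_mix))
    }
    inter <- list(i = integer(0), j = integer(0), w = numeric(0))
    for (t in seq_len(length(layers) - 1L)) {
        s1 <- which(d$layer_index == layers[t])
        s2 <- which(d$layer_index == layers[t + 1L])
        mm <- lsa_match(d$coords[s1, , drop = FALSE], d$coords[s2, , drop = FALSE])
        inter$i <- c(inter$i, s1[mm[, 1]])
        inter$j <- c(inter$j, s2[mm[, 2]])
        inter$w <- c(inter$w, rep(1, nrow(mm)))
    }
    multilayer_communities(n, d$layer_index, intra, inter, resolution, seed)
}
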