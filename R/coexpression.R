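#' Coexpression configuration
#'
#' @param jaccard_threshold Minimum Jaccard similarity (strict) to draw an
#'   edge in the hotspot similarity network. Recommended 0.6 with hotspot
#'   closure, 0.3 without.
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param min_genes Minimum number of constituent single-gene hotspots for a
#'   community to become a coexpression hotspot (default 3).
#' @param membership_cutoff Cells contained in strictly more than this
#'   fraction of a community's hotspots are members (default 0.3).
#' @param chunk_grid Integer pair: the spatial chunking grid used for overlap
#'   counting (default `c(10, 10)`; the result is independent of it).
#' @param seed Seed for the Leiden community step.
#' @return A `coexpression_config` list.
#' @export
coexpression_config <- function(jaccard_threshold = 0.3, resolution = 1.0,
                                min_genes = 3L, membership_cutoff = 0.3,
                                chunk_grid = c(10L, 10L), seed = 0L) {
    stopifnot(jaccard_threshold > 0, jaccard_threshold < 1,
              membership_cutoff > 0, membership_cutoff < 1,
              min_genes >= 1, length(chunk_grid) == 2, all(chunk_grid >= 1))
    structure(list(jaccard_threshold = jaccard_threshold, resolution = resolution,
                   min_genes = as.integer(min_genes),
                   membership_cutoff = membership_cutoff,
                   chunk_grid = as.integer(chunk_grid), seed = as.integer(seed)),
              class = "coexpression_config")
}

# Sparse cells x hotspots membership indicator.
membership_matrix <- function(hotspots, n_cells) {
    len <- vapply(hotspots, function(h) length(h$members), 1L)
    Matrix::sparseMatrix(i = unlist(lapply(hotspots, `[[`, "members")),
                         j = rep(seq_along(hotspots), len), x = 1,
                         dims = c(n_cells, length(hotspots)))
}

#' Pairwise overlap counts between hotspots via spatial chunking
#'
#' Computes the sparse overlap matrix `O[i, j] = |H_i intersect H_j|` by
#' iterating over cells (not hotspot pairs): each cell contributes one tally
#' to every pair of hotspots containing it, so non-overlapping hotspots cost
#' nothing. Cells are partitioned into a rectangular spatial chunk grid and
#' tallies are accumulated per chunk, then summed; the result is independent
#' of the chunk grid because the tally is additive over any partition of the
#' cells.
#'
#' @param hotspots List of `gene_hotspot` objects.
#' @param n_cells Number of cells in the dataset.
#' @param chunk_grid Integer pair (nx, ny).
#' @param coords Optional n_cells x 2 coordinate matrix used to form spatial
#'   chunks; without it the cells are chunked by index blocks.
#' @return Sparse symmetric `dgCMatrix` of overlap counts, zero diagonal.
#' @export
overlap_counts <- function(hotspots, n_cells, chunk_grid = c(10L, 10L),
                           coords = NULL) {
    nh <- length(hotspots)
    if (nh == 0) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0), dims = c(0, 0)))
    M <- membership_matrix(hotspots, n_cells)
    if (!is.null(coords)) {
        bx <- findInterval(coords[, 1],
                           seq(min(coords[, 1]), max(coords[, 1]),
                               length.out = chunk_grid[1] + 1L),
                           all.inside = TRUE)
        by <- findInterval(coords[, 2],
                           seq(min(coords[, 2]), max(coords[, 2]),
                               length.out = chunk_grid[2] + 1L),
                           all.inside = TRUE)
        chunk <- (bx - 1L) * chunk_grid[2] + by
    } else {
        chunk <- ceiling(seq_len(n_cells) / max(1, ceiling(n_cells / prod(chunk_grid))))
    }
    O <- NULL
    for (cells in split(seq_len(n_cells), chunk)) {
        oc <- Matrix::crossprod(M[cells, , drop = FALSE])
        O <- if (is.null(O)) oc else O + oc
    }
    Matrix::diag(O) <- 0
    methods::as(Matrix::drop0(O), "generalMatrix")
}

#' Hotspot similarity network from overlap counts
#'
#' Converts overlaps to Jaccard similarities,
#' `S[i, j] = O[i, j] / (|H_i| + |H_j| - O[i, j])`, and keeps entries
#' strictly above `threshold` as weighted edges.
#'
#' @param O Sparse overlap matrix from [overlap_counts()].
#' @param sizes Integer vector of hotspot sizes.
#' @param threshold Jaccard edge threshold.
#' @return A `hotspot_network`: list with `n` nodes and a sparse symmetric
#'   `adjacency` of Jaccard weights.
#' @export
jaccard_network <- function(O, sizes, threshold = 0.3) {
    stopifnot(all(sizes > 0))
    n <- length(sizes)
    Ot <- methods::as(Matrix::tril(O), "TsparseMatrix")
    i <- Ot@i + 1L; j <- Ot@j + 1L; o <- Ot@x
    s <- o / (sizes[i] + sizes[j] - o)
    keep <- s > threshold
    adj <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = s[keep],
                                dims = c(n, n), symmetric = FALSE)
    structure(list(n = n, adjacency = adj + Matrix::t(adj)),
              class = "hotspot_network")
}

#' @exportS3Method print hotspot_network
print.hotspot_network <- function(x, ...) {
    cat(sprintf("hotspot_network: %d nodes, %d edges\n", x$n,
                length(Matrix::tril(x$adjacency)@x)))
    invisible(x)
}

#' Leiden communities of the hotspot similarity network
#'
#' Weighted modularity-based Leiden clustering at the given resolution;
#' deterministic for a fixed seed. Isolated nodes form singleton
#' communities.
#'
#' @param net A `hotspot_network` from [jaccard_network()].
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @return Integer community label per node (empty network: `integer(0)`).
#' @export
leiden_communities <- function(net, resolution = 1.0, seed = 0L) {
    stopifnot(inherits(net, "hotspot_network"))
    if (net$n == 0) return(integer(0))
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                             weighted = TRUE)
    part <- with_seed(seed,
        igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = 3L))
    as.integer(igraph::membership(part))
}

#' Collapse hotspot communities into coexpression hotspots
#'
#' Each community with at least `min_genes` constituent single-gene hotspots
#' becomes a coexpression hotspot whose members are the cells contained in
#' strictly more than `membership_cutoff` of the constituents. Hotspots are
#' numbered `CH0, CH1, ...` in decreasing order of member count (ties broken
#' by lowest constituent hotspot index).
#'
#' @param partition Integer community label per hotspot.
#' @param hotspots The single-gene hotspots the partition covers.
#' @param cfg A [coexpression_config()].
#' @param n_cells Number of cells in the dataset.
#' @return List of `coexpression_hotspot` objects.
#' @export
form_coexpression_hotspots <- function(partition, hotspots, cfg, n_cells) {
    stopifnot(length(partition) == length(hotspots))
    groups <- split(seq_along(hotspots), partition)
    groups <- groups[vapply(groups, length, 1L) >= cfg$min_genes]
    if (!length(groups)) return(list())
    chs <- lapply(groups, function(idx) {
        counts <- tabulate(unlist(lapply(hotspots[idx], `[[`, "members")), n_cells)
        members <- which(counts / length(idx) > cfg$membership_cutoff)
        list(members = members, gene_hotspots = idx,
             genes = unique(vapply(hotspots[idx], `[[`, "", "gene")))
    })
    sizes <- vapply(chs, function(c) length(c$members), 1L)
    lowest <- vapply(chs, function(c) min(c$gene_hotspots), 1L)
    ord <- order(-sizes, lowest)
    chs <- chs[ord]
    lapply(seq_along(chs), function(k) {
        structure(list(id = k - 1L, members = chs[[k]]$members,
                       gene_hotspots = chs[[k]]$gene_hotspots,
                       genes = chs[[k]]$genes,
                       membership_cutoff = cfg$membership_cutoff),
                  class = "coexpression_hotspot")
    })
}

#' @exportS3Method print coexpression_hotspot
print.coexpression_hotspot <- function(x, ...) {
    cat(sprintf("CH%d: %d cells, %d genes (%d constituent hotspots)\n",
                x$id, length(x$members), length(x$genes), length(x$gene_hotspots)))
    invisible(x)
}

#' Run the full coexpression-hotspot pipeline
#'
#' Single-gene hotspots -> chunked overlap counts -> Jaccard similarity
#' network -> Leiden communities -> coexpression hotspots. The result is the
#' list of coexpression hotspots; the intermediate single-gene hotspots,
#' network and partition are attached as attributes `"hotspots"`,
#' `"network"` and `"partition"`. A cell may belong to one coexpression
#' hotspot, several, or none.
#'
#' @param d A preprocessed [spatial_dataset()].
#' @param det_cfg A [hotspot_config()].
#' @param coex_cfg A [coexpression_config()].
#' @return List of `coexpression_hotspot` objects (with attributes).
#' @export
run_coexpression <- function(d, det_cfg, coex_cfg = coexpression_config()) {
    hotspots <- compute_all_gene_hotspots(d, det_cfg)
    if (!length(hotspots)) {
        out <- list()
        attr(out, "hotspots") <- hotspots
        return(out)
    }
    O <- overlap_counts(hotspots, n_cells(d), coex_cfg$chunk_grid, d$coords)
    sizes <- vapply(hotspots, function(h) length(h$members), 1L)
    net <- jaccard_network(O, sizes, coex_cfg$jaccard_threshold)
    part <- leiden_communities(net, coex_cfg$resolution, coex_cfg$seed)
    chs <- form_coexpression_hotspots(part, hotspots, coex_cfg, n_cells(d))
    attr(chs, "hotspots") <- hotspots
    attr(chs, "network") <- net
    attr(chs, "partition") <- part
    chs
}

#' Export the hotspot similarity network as a weighted edge list
#'
#' @param net A `hotspot_network`.
#' @param hotspots The single-gene hotspots backing the nodes (for labels).
#' @param file Output CSV path with columns `from`, `to`, `gene_from`,
#'   `gene_to`, `jaccard`.
#' @return Invisibly, `file`.
#' @export
export_network <- function(net, hotspots, file) {
    tl <- methods::as(Matrix::tril(net$adjacency), "TsparseMatrix")
    genes <- vapply(hotspots, `[[`, "", "gene")
    tab <- data.frame(from = tl@i + 1L, to = tl@j + 1L,
                      gene_from = genes[tl@i + 1L], gene_to = genes[tl@j + 1L],
                      jaccard = tl@x)
    data.table::fwrite(tab[order(tab$from, tab$to), ], file)
    invisible(file)
}

#' Export coexpression hotspots
#'
#' @param chs List of `coexpression_hotspot` objects.
#' @param d The originating [spatial_dataset()].
#' @param membership_file Optional CSV path for (ch_id, cell_id) rows.
#' @param summary_file Optional JSON path for per-hotspot summaries.
#' @return Invisibly, the membership data frame.
#' @export
export_coexpression <- function(chs, d, membership_file = NULL,
                                summary_file = NULL) {
    mem <- data.frame(
        ch_id = rep(vapply(chs, `[[`, 1L, "id"),
                    vapply(chs, function(c) length(c$members), 1L)),
        cell_id = rownames(d$expression)[unlist(lapply(chs, `[[`, "members"))])
    if (!is.null(membership_file)) data.table::fwrite(mem, membership_file)
    if (!is.null(summary_file)) {
        summ <- lapply(chs, function(c) list(ch_id = c$id,
                                             n_cells = length(c$members),
                                             n_genes = length(c$genes),
                                             genes = c$genes))
        jsonlite::write_json(summ, summary_file, auto_unbox = TRUE)
    }
    invisible(mem)
}
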