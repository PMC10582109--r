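new_score_field <- function(score, kind) {
    structure(list(score = score, kind = kind), class = "cell_score_field")
}

#' @exportS3Method print cell_score_field
print.cell_score_field <- function(x, ...) {
    cat(sprintf("cell_score_field (%s): %d cells, max %.3f\n",
                x$kind, length(x$score), max(x$score)))
    invisible(x)
}

max_normalize <- function(v) {
    m <- max(v)
    if (m > 0) v / m else v
}

#' Spatial coherence score
#'
#' Counts, for every cell, how many coexpression-hotspot-constituent
#' single-gene hotspots contain it, then normalizes the counts to `[0, 1]`
#' by the maximum. Because the counting runs over constituent single-gene
#' hotspots rather than the collapsed coexpression hotspots, the score
#' varies smoothly across hotspot boundaries.
#'
#' @param chs List of `coexpression_hotspot` objects.
#' @param all_gene_hotspots The single-gene hotspots the CHs were built from.
#' @param n_cells Number of cells in the dataset.
#' @return A `cell_score_field` of kind `"coherence"`.
#' @export
coherence_score <- function(chs, all_gene_hotspots, n_cells) {
    used <- unique(unlist(lapply(chs, `[[`, "gene_hotspots")))
    if (!length(used)) {
        warnf("no coexpression hotspots: coherence score is all zero")
        return(new_score_field(numeric(n_cells), "coherence"))
    }
    counts <- tabulate(unlist(lapply(all_gene_hotspots[used], `[[`, "members")),
                       n_cells)
    new_score_field(max_normalize(counts), "coherence")
}

#' Unique expression score
#'
#' Same counting and normalization as [coherence_score()], but restricted to
#' single-gene hotspots whose gene contributes to exactly one coexpression
#' hotspot: genes with hotspots in two or more different CHs (repeated
#' structures) are excluded entirely, so the score highlights structures
#' with their own private gene program.
#'
#' @inheritParams coherence_score
#' @return A `cell_score_field` of kind `"uniqueness"`.
#' @export
uniqueness_score <- function(chs, all_gene_hotspots, n_cells) {
    used <- unique(unlist(lapply(chs, `[[`, "gene_hotspots")))
    if (!length(used)) {
        warnf("no coexpression hotspots: uniqueness score is all zero")
        return(new_score_field(numeric(n_cells), "uniqueness"))
    }
    hs_gene <- vapply(all_gene_hotspots, `[[`, "", "gene")
    ch_of_hs <- rep(NA_integer_, length(all_gene_hotspots))
    for (c in chs) ch_of_hs[c$gene_hotspots] <- c$id
    n_chs_per_gene <- vapply(split(ch_of_hs[used], hs_gene[used]),
                             function(v) length(unique(v)), 1L)
    uni_genes <- names(n_chs_per_gene)[n_chs_per_gene == 1L]
    keep <- used[hs_gene[used] %in% uni_genes]
    counts <- tabulate(unlist(lapply(all_gene_hotspots[keep], `[[`, "members")),
                       n_cells)
    new_score_field(max_normalize(counts), "uniqueness")
}

#' Similarity map of a coexpression hotspot on a target sample
#'
#' For each cell of the target dataset, the fraction of the hotspot's genes
#' for which the cell lies inside some single-gene hotspot of that gene on
#' the target. On the source sample this is high inside the hotspot and
#' inside any repetition of the same gene program elsewhere; on a different
#' sample (gene hotspots recomputed there) it transfers the structure
#' across samples. The mean of the map over a region gives an inter-sample
#' average similarity.
#'
#' @param ch A `coexpression_hotspot`.
#' @param target The target [spatial_dataset()] (may be the source).
#' @param target_hotspots Optional precomputed single-gene hotspots of the
#'   target; computed from `det_cfg` when absent.
#' @param det_cfg A [hotspot_config()] used when `target_hotspots` is NULL.
#' @return A `cell_score_field` of kind `"similarity_map"` (values are
#'   fractions in `[0, 1]`, not re-normalized).
#' @export
similarity_map <- function(ch, target, target_hotspots = NULL, det_cfg = NULL) {
    genes <- intersect(ch$genes, colnames(target$expression))
    if (!length(genes)) stopf("CH%d shares no genes with the target dataset", ch$id)
    if (length(genes) < length(ch$genes)) {
        warnf("CH%d: %d gene(s) absent from the target dropped",
              ch$id, length(ch$genes) - length(genes))
    }
    if (is.null(target_hotspots)) {
        stopifnot(!is.null(det_cfg))
        target_hotspots <- compute_all_gene_hotspots(target, det_cfg, genes = genes)
    }
    hs_gene <- vapply(target_hotspots, `[[`, "", "gene")
    n <- n_cells(target)
    hit <- numeric(n)
    for (g in genes) {
        members <- unique(unlist(lapply(target_hotspots[hs_gene == g], `[[`,
                                        "members")))
        if (length(members)) hit[members] <- hit[members] + 1
    }
    new_score_field(hit / length(genes), "similarity_map")
}

#' Greedy decomposition of a gene's hotspots into coexpression hotspots
#'
#' Let H be the union of the gene's single-gene hotspots. Each step selects
#' the coexpression hotspot maximizing the match score
#' `MS_j = |H ∩ CH_j| - |H-complement ∩ CH_j|` (complement within all
#' dataset cells), adds it, and removes its cells from H; selection stops
#' when no coexpression hotspot scores positive.
#'
#' @param gene Gene name (recorded on the result).
#' @param gene_hotspots The gene's own `gene_hotspot` objects (>= 1).
#' @param chs List of `coexpression_hotspot` objects.
#' @param n_cells Number of cells in the dataset.
#' @return A `decomposition`: list with `gene`, `selected` (CH ids in greedy
#'   order), `match_scores` (per step), and `residual` (uncovered spot
#'   count).
#' @export
decompose_gene <- function(gene, gene_hotspots, chs, n_cells) {
    stopifnot(length(gene_hotspots) >= 1)
    H <- unique(unlist(lapply(gene_hotspots, `[[`, "members")))
    selected <- integer(0)
    scores <- numeric(0)
    remaining <- chs
    while (length(remaining)) {
        ms <- vapply(remaining, function(c) {
            inH <- sum(c$members %in% H)
            2 * inH - length(c$members)      # |H int CH| - |Hbar int CH|
        }, 1)
        if (max(ms) <= 0) break
        best <- which(ms == max(ms))[1]      # ties: lowest CH id (sorted order)
        selected <- c(selected, remaining[[best]]$id)
        scores <- c(scores, ms[best])
        H <- setdiff(H, remaining[[best]]$members)
        remaining <- remaining[-best]
    }
    structure(list(gene = gene, selected = selected, match_scores = scores,
                   residual = length(H)),
              class = "decomposition")
}

#' @exportS3Method print decomposition
print.decomposition <- function(x, ...) {
    cat(sprintf("decomposition of %s: CHs [%s], residual %d spots\n", x$gene,
                paste(x$selected, collapse = ", "), x$residual))
    invisible(x)
}

#' Pairwise coexpression-hotspot similarity with dendrogram ordering
#'
#' The directed similarity from hotspot a to hotspot b is the mean, over a's
#' genes, of the mean similarity-map value of those genes inside b's member
#' cells; the matrix is symmetrized by averaging. Leaf order comes from
#' average-linkage hierarchical clustering on `1 - similarity`.
#'
#' @param chs List of at least two `coexpression_hotspot` objects.
#' @param d The [spatial_dataset()] the hotspots live on.
#' @param all_gene_hotspots The dataset's single-gene hotspots.
#' @return List with `similarity` (symmetric matrix, CH ids as dimnames)
#'   and `order` (dendrogram leaf order, indices into `chs`).
#' @export
ch_similarity_matrix <- function(chs, d, all_gene_hotspots) {
    stopifnot(length(chs) >= 2)
    k <- length(chs)
    hs_gene <- vapply(all_gene_hotspots, `[[`, "", "gene")
    gene_field <- new.env()
    per_gene_hit <- function(g) {
        if (!is.null(gene_field[[g]])) return(gene_field[[g]])
        members <- unique(unlist(lapply(all_gene_hotspots[hs_gene == g], `[[`,
                                        "members")))
        v <- numeric(n_cells(d))
        v[members] <- 1
        gene_field[[g]] <- v
        v
    }
    S <- matrix(0, k, k)
    for (a in seq_len(k)) {
        for (b in seq_len(k)) {
            vals <- vapply(chs[[a]]$genes, function(g)
                mean(per_gene_hit(g)[chs[[b]]$members]), 1)
            S[a, b] <- mean(vals)
        }
    }
    S <- (S + t(S)) / 2
    dimnames(S) <- rep(list(paste0("CH", vapply(chs, `[[`, 1L, "id"))), 2)
    hc <- hclust(as.dist(1 - S), method = "average")
    list(similarity = S, order = hc$order, hclust = hc)
}

#' Export gene decompositions as JSON
#'
#' @param decomps List of [decompose_gene()] results.
#' @param file Output JSON path.
#' @return Invisibly, `file`.
#' @export
export_decompositions <- function(decomps, file) {
    obj <- lapply(decomps, function(d) list(gene = d$gene,
                                            selected_chs = d$selected,
                                            match_scores = d$match_scores,
                                            residual = d$residual))
    jsonlite::write_json(obj, file, auto_unbox = TRUE)
    invisible(file)
}

#' Export a per-cell score field as CSV
#'
#' @param field A `cell_score_field`.
#' @param d The [spatial_dataset()] it was computed on.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
export_score_field <- function(field, d, file) {
    data.table::fwrite(data.frame(cell_id = rownames(d$expression),
                                  score = field$score), file)
    invisible(file)
}
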