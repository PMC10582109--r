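#' Containment tree over coexpression hotspots
#'
#' A hotspot whose member set is contained (at fraction >= `threshold`) in
#' another hotspot becomes a child of that hotspot; its parent is the
#' smallest hotspot containing it, so multiple levels of nesting produce a
#' tree. Hotspots with no qualifying container are roots (layer 1); each
#' child's layer is its parent's plus one. Two equal-sized hotspots that
#' mutually contain each other are resolved deterministically (the larger id
#' becomes the child) with a warning.
#'
#' @param chs List of `coexpression_hotspot` objects.
#' @param threshold Containment fraction (default 0.75, applied as `>=`).
#' @return A `hierarchy_tree`: list with integer vectors `parent` (NA for
#'   roots) and `layer`, indexed by CH id + 1, and the `threshold`.
#' @export
build_tree <- function(chs, threshold = 0.75) {
    stopifnot(length(chs) >= 1, threshold > 0, threshold <= 1)
    k <- length(chs)
    ids <- vapply(chs, `[[`, 1L, "id")
    sizes <- vapply(chs, function(c) length(c$members), 1L)
    parent <- rep(NA_integer_, k)
    for (a in seq_len(k)) {
        frac <- vapply(seq_len(k), function(b) {
            if (b == a) return(0)
            length(intersect(chs[[a]]$members, chs[[b]]$members)) / sizes[a]
        }, 1)
        cand <- which(frac >= threshold)
        # containers must be larger; equal sizes resolved by id order
        eq <- cand[sizes[cand] == sizes[a]]
        if (length(eq)) {
            mutual <- eq[vapply(eq, function(b)
                length(intersect(chs[[a]]$members, chs[[b]]$members)) / sizes[b] >=
                    threshold, TRUE)]
            if (length(mutual) && ids[a] < ids[mutual[1]]) {  # warn once per pair
                warnf("mutual containment between CH%d and CH%d; larger id becomes child",
                      ids[a], ids[mutual[1]])
            }
            cand <- setdiff(cand, eq[ids[eq] > ids[a]])
        }
        cand <- cand[sizes[cand] > sizes[a] |
                     (sizes[cand] == sizes[a] & ids[cand] < ids[a])]
        if (length(cand)) {
            best <- cand[order(sizes[cand], ids[cand])][1]  # smallest container
            parent[a] <- ids[best]
        }
    }
    layer <- rep(NA_integer_, k)
    layer[is.na(parent)] <- 1L
    while (anyNA(layer)) {
        todo <- which(is.na(layer))
        for (a in todo) {
            pl <- layer[match(parent[a], ids)]
            if (!is.na(pl)) layer[a] <- pl + 1L
        }
        if (identical(which(is.na(layer)), todo)) {
            stopf("containment relation contains a cycle")  # unreachable by construction
        }
    }
    structure(list(parent = stats::setNames(parent, paste0("CH", ids)),
                   layer = stats::setNames(layer, paste0("CH", ids)),
                   ids = ids, threshold = threshold),
              class = "hierarchy_tree")
}

#' @exportS3Method print hierarchy_tree
print.hierarchy_tree <- function(x, ...) {
    cat(sprintf("hierarchy_tree: %d hotspots, depth %d (containment >= %.2f)\n",
                length(x$ids), max(x$layer), x$threshold))
    invisible(x)
}

# Mann-Whitney U (x vs y) with two-sided p value. Exact when the pooled
# size is <= `exact_max` (tie-free case via the exact U distribution; ties
# via enumeration of all group assignments), else a normal approximation
# with tie correction and no continuity correction.
mw_test <- function(x, y, exact_max = 20L) {
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    if (n1 == 0 || n2 == 0) return(list(u = NA_real_, p = NA_real_))
    pooled <- c(x, y)
    r <- rank(pooled)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- any(duplicated(pooled))
    if (N <= exact_max) {
        if (!ties) {
            p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
        } else {
            combs <- combn(N, n1)
            us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
            p <- 2 * min(mean(us <= u), mean(us >= u))
        }
        return(list(u = u, p = min(1, p)))
    }
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) return(list(u = u, p = 1))
    p <- 2 * pnorm(-abs((u - mu) / sqrt(sig2)))
    list(u = u, p = min(1, p))
}

#' Per-gene Mann-Whitney tests with Benjamini-Hochberg correction
#'
#' Two-sided Wilcoxon rank-sum tests of group A versus group B, one per
#' gene (matrix column), with BH FDR correction across genes. Exact p
#' values (enumeration / exact U distribution) are used when the pooled
#' group size is small; otherwise a normal approximation with tie
#' correction.
#'
#' @param a,b Numeric matrices (cells x genes) with identical gene columns.
#' @return Data frame with `gene`, `u_statistic`, `raw_p`, `fdr_q` and
#'   `direction` (sign of mean(A) - mean(B)).
#' @export
mannwhitney_bh <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    stopifnot(ncol(a) == ncol(b))
    genes <- colnames(a)
    if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(a)))
    res <- vapply(seq_len(ncol(a)), function(g) {
        t <- mw_test(a[, g], b[, g])
        c(t$u, t$p)
    }, numeric(2))
    out <- data.frame(gene = genes, u_statistic = res[1, ], raw_p = res[2, ],
                      fdr_q = p.adjust(res[2, ], method = "BH"),
                      direction = sign(colMeans(a) - colMeans(b)))
    rownames(out) <- NULL
    out
}

ch_relatives <- function(ch, chs, tree) {
    ids <- tree$ids
    id <- ch$id
    pid <- tree$parent[match(id, ids)]
    kids <- ids[which(tree$parent == id)]
    sibs <- if (is.na(pid)) ids[is.na(tree$parent) & ids != id]
            else ids[!is.na(tree$parent) & tree$parent == pid & ids != id]
    rel <- list()
    if (!is.na(pid)) rel[[length(rel) + 1L]] <- list(kind = "parent", id = pid)
    for (s in sibs) rel[[length(rel) + 1L]] <- list(kind = "sibling", id = s)
    for (k in kids) rel[[length(rel) + 1L]] <- list(kind = "child", id = k)
    rel
}

#' Hierarchical marker genes
#'
#' For each coexpression hotspot, tests every gene against each parent,
#' sibling and child hotspot in the containment tree. Parent/sibling
#' comparisons test the focal cells against the relative's cells minus the
#' focal cells; child comparisons test the focal cells minus the child's
#' cells against the child's cells. A gene is a hierarchical marker of a
#' hotspot when it is enriched (higher mean on the focal side) with
#' `raw_p < p_cut` in every comparison. A hotspot with no relatives falls
#' back to a single comparison against all non-member cells (labeled
#' `"custom"`).
#'
#' @param d A preprocessed [spatial_dataset()].
#' @param chs List of `coexpression_hotspot` objects.
#' @param tree A [build_tree()] result over `chs`.
#' @param p_cut Raw p-value cutoff (default 0.001).
#' @return Data frame of all per-comparison results (`ch_id`, `gene`,
#'   `comparison`, `relative_id`, `u_statistic`, `raw_p`, `fdr_q`,
#'   `direction`, `marker`); `attr(, "marker_genes")` holds the marker gene
#'   list per hotspot.
#' @export
hierarchical_markers <- function(d, chs, tree, p_cut = 0.001) {
    stopifnot(inherits(tree, "hierarchy_tree"))
    by_id <- stats::setNames(chs, vapply(chs, `[[`, 1L, "id"))
    all_rows <- list()
    marker_genes <- list()
    for (ch in chs) {
        rel <- ch_relatives(ch, chs, tree)
        if (!length(rel)) {
            others <- setdiff(seq_len(n_cells(d)), ch$members)
            rel <- list(list(kind = "custom", id = NA_integer_, cells = others))
        }
        per_comp <- list()
        for (r in rel) {
            if (r$kind == "child") {
                kid <- by_id[[as.character(r$id)]]
                A <- setdiff(ch$members, kid$members)
                B <- kid$members
            } else if (r$kind == "custom") {
                A <- ch$members
                B <- r$cells
            } else {
                other <- by_id[[as.character(r$id)]]
                A <- ch$members
                B <- setdiff(other$members, ch$members)
            }
            if (!length(A) || !length(B)) {
                warnf("CH%d vs %s CH%s: empty comparison group, skipped",
                      ch$id, r$kind, r$id)
                next
            }
            tab <- mannwhitney_bh(d$expression[A, , drop = FALSE],
                                  d$expression[B, , drop = FALSE])
            tab$ch_id <- ch$id
            tab$comparison <- r$kind
            tab$relative_id <- r$id
            per_comp[[length(per_comp) + 1L]] <- tab
        }
        if (!length(per_comp)) next
        pass <- Reduce(`&`, lapply(per_comp, function(t)
            t$direction > 0 & t$raw_p < p_cut))
        for (t in seq_along(per_comp)) per_comp[[t]]$marker <- pass
        marker_genes[[paste0("CH", ch$id)]] <- per_comp[[1]]$gene[pass]
        all_rows <- c(all_rows, per_comp)
    }
    out <- do.call(rbind, all_rows)
    attr(out, "marker_genes") <- marker_genes
    out
}

#' Pairwise differential expression between two coexpression hotspots
#'
#' Cells in both hotspots are excluded from both sides, then every gene is
#' tested (Mann-Whitney, BH). The fold change is the difference of group
#' means on the stored (typically log) scale, positive toward `ch_a`.
#'
#' @param d A preprocessed [spatial_dataset()].
#' @param ch_a,ch_b `coexpression_hotspot` objects.
#' @return Data frame (`gene`, `lfc`, `u_statistic`, `raw_p`, `fdr_q`)
#'   ordered by increasing p then decreasing `|lfc|`.
#' @export
pairwise_de <- function(d, ch_a, ch_b) {
    overlap <- intersect(ch_a$members, ch_b$members)
    A <- setdiff(ch_a$members, overlap)
    B <- setdiff(ch_b$members, overlap)
    if (!length(A) || !length(B)) {
        stopf("overlap exclusion empties CH%d vs CH%d", ch_a$id, ch_b$id)
    }
    tab <- mannwhitney_bh(d$expression[A, , drop = FALSE],
                          d$expression[B, , drop = FALSE])
    tab$lfc <- colMeans(d$expression[A, , drop = FALSE]) -
        colMeans(d$expression[B, , drop = FALSE])
    tab <- tab[order(tab$raw_p, -abs(tab$lfc)), c("gene", "lfc", "u_statistic",
                                                  "raw_p", "fdr_q")]
    rownames(tab) <- NULL
    tab
}

#' Export marker-gene results as a per-hotspot summary table
#'
#' One row per (hotspot, marker gene): the number of comparisons the gene
#' passed, its worst-case raw p and BH q across them.
#'
#' @param markers Result of [hierarchical_markers()].
#' @param file Optional CSV path.
#' @return The summary data frame (`ch_id`, `gene`, `comparisons_passed`,
#'   `max_p`, `max_q`), invisibly when written to file.
#' @export
export_markers <- function(markers, file = NULL) {
    mk <- markers[markers$marker, , drop = FALSE]
    key <- interaction(mk$ch_id, mk$gene, drop = TRUE)
    tab <- do.call(rbind, lapply(split(mk, key), function(g)
        data.frame(ch_id = g$ch_id[1], gene = g$gene[1],
                   comparisons_passed = nrow(g),
                   max_p = max(g$raw_p), max_q = max(g$fdr_q))))
    if (is.null(tab)) tab <- data.frame(ch_id = integer(0), gene = character(0),
                                        comparisons_passed = integer(0),
                                        max_p = numeric(0), max_q = numeric(0))
    tab <- tab[order(tab$ch_id, tab$max_p, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    if (!is.null(file)) { data.table::fwrite(tab, file); return(invisible(tab)) }
    tab
}

#' Export a containment tree as JSON
#'
#' @param tree A [build_tree()] result.
#' @param file Output JSON path.
#' @return Invisibly, `file`.
#' @export
export_tree <- function(tree, file) {
    obj <- list(threshold = tree$threshold,
                nodes = lapply(seq_along(tree$ids), function(i) list(
                    ch_id = tree$ids[i],
                    parent = if (is.na(tree$parent[i])) NULL else tree$parent[i],
                    layer = tree$layer[i])))
    jsonlite::write_json(obj, file, auto_unbox = TRUE)
    invisible(file)
}
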