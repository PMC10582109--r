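# Spatial ligand-receptor interaction model: transport matrices, Hill
# activity, permutation significance and interaction hotspots.

#' Load a ligand-receptor interaction database
#'
#' Reads a delimited table with ligand gene, receptor gene, pathway and type
#' annotation columns (the schema of curated interaction databases), keeps
#' only secreted-signaling and cell-cell-contact interactions, and — when a
#' dataset is supplied — drops pairs whose ligand or receptor gene is absent
#' from it, reporting the counts.
#'
#' @param path Delimited file.
#' @param dataset Optional [spatial_dataset()] used to filter analyzable pairs.
#' @param cols Named character vector mapping the required fields to column
#'   names in the file.
#' @param annotations Annotation classes to keep (case-insensitive).
#' @return Data frame of class `lr_database` with columns `ligand`,
#'   `receptor`, `pathway`, `annotation`; dropped-pair counts in attributes.
#' @export
load_lr_database <- function(path, dataset = NULL,
                             cols = c(ligand = "ligand", receptor = "receptor",
                                      pathway = "pathway", annotation = "annotation"),
                             annotations = c("secreted signaling", "cell-cell contact")) {
    tab <- as.data.frame(data.table::fread(path))
    miss <- setdiff(unname(cols), names(tab))
    if (length(miss)) stopf("ligand-receptor table lacks column(s): %s",
                            paste(miss, collapse = ", "))
    db <- data.frame(ligand = as.character(tab[[cols["ligand"]]]),
                     receptor = as.character(tab[[cols["receptor"]]]),
                     pathway = as.character(tab[[cols["pathway"]]]),
                     annotation = as.character(tab[[cols["annotation"]]]))
    keep <- tolower(db$annotation) %in% tolower(annotations)
    n_class_dropped <- sum(!keep)
    db <- db[keep, , drop = FALSE]
    n_missing <- 0L
    if (!is.null(dataset)) {
        present <- db$ligand %in% colnames(dataset$expression) &
            db$receptor %in% colnames(dataset$expression)
        n_missing <- sum(!present)
        db <- db[present, , drop = FALSE]
    }
    if (!nrow(db)) warnf("no analyzable ligand-receptor pairs")
    rownames(db) <- NULL
    structure(db, class = c("lr_database", "data.frame"),
              n_class_dropped = n_class_dropped, n_missing_genes = n_missing)
}

new_transport <- function(A, model, cutoff) {
    structure(list(A = A, model = model, cutoff = cutoff),
              class = "transport_matrix")
}

#' @exportS3Method print transport_matrix
print.transport_matrix <- function(x, ...) {
    cat(sprintf("transport_matrix (%s, cutoff %g): %d cells\n",
                x$model, x$cutoff, nrow(x$A)))
    invisible(x)
}

row_normalize <- function(A) {
    rs <- Matrix::rowSums(A)
    rs[rs == 0] <- 1
    Matrix::Diagonal(x = 1 / rs) %*% A
}

#' Diffusion transport matrix for secreted signaling
#'
#' Distributes each cell's ligand to all neighbors within `cutoff` (the cell
#' itself included, at distance zero) with a truncated Gaussian kernel,
#' `w = exp(-d^2 / (2 sigma^2))` with `sigma = cutoff / 2`, then normalizes
#' every row to sum to one (a first-order correction for cell size). Works
#' in 2D or 3D depending on the coordinate dimension.
#'
#' @param coords n x 2 or n x 3 coordinate matrix.
#' @param cutoff Diffusion cutoff distance (default 100, in data units).
#' @return A `transport_matrix` (row-stochastic sparse matrix).
#' @export
diffusion_transport <- function(coords, cutoff = 100) {
    stopifnot(cutoff > 0)
    coords <- as.matrix(coords)
    n <- nrow(coords)
    sigma <- cutoff / 2
    pr <- radius_pairs(coords, cutoff)
    w <- exp(-pr$d^2 / (2 * sigma^2))
    A <- Matrix::sparseMatrix(i = c(pr$i, seq_len(n)), j = c(pr$j, seq_len(n)),
                              x = c(w, rep(1, n)), dims = c(n, n))
    new_transport(row_normalize(A), "diffusion", cutoff)
}

#' Contact transport matrix for cell-cell contact signaling
#'
#' Adjacency from the Delaunay triangulation (an edge means no other cell
#' lies between the pair) with edges longer than `max_edge` removed, plus
#' self-contact; every neighbor receives equal weight and rows are
#' normalized to sum to one.
#'
#' @param coords n x 2 coordinate matrix, at least 3 non-collinear points.
#' @param max_edge Maximum contact edge length (default 20, in data units).
#' @return A `transport_matrix` (row-stochastic sparse matrix).
#' @export
contact_transport <- function(coords, max_edge = 20) {
    stopifnot(max_edge > 0)
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    n <- nrow(coords)
    if (n < 3 || qr(cbind(1, coords))$rank < 3) {
        stopf("degenerate geometry: need at least 3 non-collinear points")
    }
    dd <- tryCatch(
        suppressMessages(deldir::deldir(coords[, 1], coords[, 2],
                                        suppressMsge = TRUE)),
        error = function(e) NULL)
    if (is.null(dd)) stopf("degenerate geometry: Delaunay triangulation failed")
    seg <- dd$delsgs
    len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
    keep <- len <= max_edge
    i <- c(seg$ind1[keep], seg$ind2[keep], seq_len(n))
    j <- c(seg$ind2[keep], seg$ind1[keep], seq_len(n))
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
    new_transport(row_normalize(A), "contact", max_edge)
}

# Max-normalized expression vector for one gene (assumes the dataset is
# already log-normalized; see cci_activity).
max_norm_gene <- function(d, gene) {
    v <- unname(d$expression[, gene])
    m <- max(v)
    if (m > 0) v / m else v
}

compute_activity <- function(L, R, A, K_h) {
    Lt <- as.numeric(Matrix::crossprod(A, L))   # transported ligand at each cell
    x <- Lt * R
    x / (K_h + x)
}

#' Cell-level ligand-receptor activity
#'
#' The ligand vector is max-normalized to 1 and spread through the transport
#' matrix; the receptor vector is max-normalized; each cell's activity is
#' the Hill function `LR / (K_h + LR)` of the product of its transported
#' ligand and its receptor expression. The dataset is expected to be
#' log-normalized (see [preprocess()]); activity always lies in `[0, 1)`.
#'
#' @param d A preprocessed [spatial_dataset()].
#' @param pair One-row data frame (or list) with `ligand` and `receptor`.
#' @param A A `transport_matrix` over the dataset's cells.
#' @param K_h Hill constant (default 0.5). Because the Hill function is
#'   monotone, the permutation-derived active set does not depend on it.
#' @return An `activity_field`: list with `interaction`, `activity`, `K_h`.
#' @export
cci_activity <- function(d, pair, A, K_h = 0.5) {
    stopifnot(inherits(A, "transport_matrix"))
    for (g in c(pair$ligand, pair$receptor)) {
        if (!g %in% colnames(d$expression)) stopf("gene %s absent from dataset", g)
    }
    L <- max_norm_gene(d, pair$ligand)
    R <- max_norm_gene(d, pair$receptor)
    if (max(L) == 0 || max(R) == 0) {
        warnf("all-zero %s for %s-%s: activity is zero everywhere",
              if (max(L) == 0) "ligand" else "receptor", pair$ligand, pair$receptor)
    }
    structure(list(interaction = list(ligand = pair$ligand, receptor = pair$receptor),
                   activity = compute_activity(L, R, A$A, K_h), K_h = K_h),
              class = "activity_field")
}

#' @exportS3Method print activity_field
print.activity_field <- function(x, ...) {
    cat(sprintf("activity_field %s -> %s: %d cells, max activity %.3f\n",
                x$interaction$ligand, x$interaction$receptor,
                length(x$activity), max(x$activity)))
    if (!is.null(x$cutoff_value)) {
        cat(sprintf("  cutoff %.4f, %d active cells\n", x$cutoff_value,
                    sum(x$active)))
    }
    invisible(x)
}

#' Permutation significance cutoff for an interaction
#'
#' Builds a null distribution by shuffling expression across cells (the same
#' permutation applied to ligand and receptor, spatial positions fixed),
#' recomputing transported activity for each of `n_perm` permutations, and
#' pooling the permuted activities over all cells. The significance cutoff
#' is the `1 - alpha` quantile of the pool; cells whose observed activity
#' strictly exceeds it are active. For layered (3D) data, cells are permuted
#' only within their own layer.
#'
#' @inheritParams cci_activity
#' @param n_perm Number of permutations (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed.
#' @param layer_index Optional per-cell layer labels restricting permutations.
#' @param permutations Optional explicit list of cell permutations (integer
#'   vectors) used instead of random draws, e.g. the full enumeration on a
#'   tiny dataset; overrides `n_perm` and `seed`.
#' @return The `activity_field` augmented with `cutoff_value`, `active`,
#'   `n_perm` and `alpha`.
#' @export
permutation_cutoff <- function(d, pair, A, K_h = 0.5, n_perm = 100L,
                               alpha = 0.05, seed = 0L, layer_index = NULL,
                               permutations = NULL) {
    stopifnot(n_perm >= 1, alpha > 0, alpha <= 1)
    if (is.null(layer_index)) layer_index <- d$layer_index
    field <- cci_activity(d, pair, A, K_h)
    L <- max_norm_gene(d, pair$ligand)
    R <- max_norm_gene(d, pair$receptor)
    n <- length(L)
    groups <- if (is.null(layer_index)) list(seq_len(n))
              else split(seq_len(n), layer_index)
    null_pool <- if (!is.null(permutations)) {
        n_perm <- length(permutations)
        vapply(permutations, function(perm)
            compute_activity(L[perm], R[perm], A$A, K_h), numeric(n))
    } else with_seed(seed, {
        vapply(seq_len(n_perm), function(p) {
            perm <- integer(n)
            for (g in groups) perm[g] <- g[sample.int(length(g))]
            compute_activity(L[perm], R[perm], A$A, K_h)
        }, numeric(n))
    })
    cutoff <- quantile(as.numeric(null_pool), 1 - alpha, names = FALSE)
    # alpha = 1 is degenerate (the 0-quantile is the pool minimum, which any
    # nonzero score trivially exceeds): no cell is called active
    if (alpha >= 1) cutoff <- max(c(null_pool, field$activity))
    field$cutoff_value <- cutoff
    field$active <- field$activity > cutoff
    field$n_perm <- n_perm
    field$alpha <- alpha
    field
}

#' Spatial hotspots of ligand-receptor activity
#'
#' Density-clusters the active cells exactly as gene-expression hotspots are
#' clustered (per layer for layered data), with the interaction label in
#' place of a gene name.
#'
#' @param d The [spatial_dataset()].
#' @param field An `activity_field` from [permutation_cutoff()].
#' @param det_cfg A [hotspot_config()].
#' @return List of `gene_hotspot`-shaped objects labeled
#'   `"ligand-receptor"`.
#' @export
cci_hotspots <- function(d, field, det_cfg) {
    stopifnot(!is.null(field$active))
    label <- paste0(field$interaction$ligand, "-", field$interaction$receptor)
    active <- which(field$active)
    if (!length(active)) return(list())
    layers <- if (is.null(d$layer_index)) list(active)
              else split(active, d$layer_index[active])
    out <- list()
    for (cells in layers) {
        lay <- if (is.null(d$layer_index)) NA_integer_
               else unique(d$layer_index[cells])[1]
        universe <- if (is.na(lay)) d$coords
                    else d$coords[d$layer_index == lay, , drop = FALSE]
        hs <- dbscan_hotspots(d$coords[cells, , drop = FALSE], det_cfg,
                              gene = label, point_index = cells,
                              source_layer = lay, ref_coords = universe)
        out <- c(out, hs)
    }
    out
}

#' Export per-interaction activity and hotspot assignments
#'
#' @param d The [spatial_dataset()].
#' @param field An `activity_field` (with cutoff).
#' @param hotspots Output of [cci_hotspots()] for this interaction.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
export_cci <- function(d, field, hotspots, file) {
    hs_id <- rep(NA_integer_, n_cells(d))
    for (k in seq_along(hotspots)) hs_id[hotspots[[k]]$members] <- k - 1L
    tab <- data.frame(cell_id = rownames(d$expression),
                      activity = field$activity, active = field$active,
                      hotspot_id = hs_id,
                      layer = if (is.null(d$layer_index)) NA_integer_
                              else d$layer_index)
    data.table::fwrite(tab, file)
    invisible(file)
}
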