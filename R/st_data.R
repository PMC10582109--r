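#' Construct a spatial expression dataset
#'
#' The universal input container: a cells-by-genes expression matrix with
#' per-cell 2D coordinates in physical units, an optional z coordinate /
#' layer index for serial-section (3D) data, and optional per-cell
#' annotations such as cell type or sample label.
#'
#' @param expression Numeric cells x genes matrix (raw counts or normalized);
#'   sparse `Matrix` input is densified. Values must be finite and >= 0.
#' @param coords Numeric n x 2 matrix or data frame of (x, y) positions, in
#'   the same row order as `expression`.
#' @param z Optional numeric z coordinate per cell (micrometres).
#' @param layer_index Optional integer slice label per cell. All cells of one
#'   layer must share a single z value when both are given.
#' @param gene_names,cell_ids Unique identifiers; default to dimnames or
#'   generated labels.
#' @param annotations Optional data frame of per-cell categorical labels.
#' @param units_hint Free-text descriptor of the spatial unit (default "um").
#' @return An object of class `spatial_dataset` with elements `expression`,
#'   `coords`, `z`, `layer_index`, `annotations`, `units_hint` and a
#'   `processing` record. Genes with zero total expression are retained but
#'   listed in `attr(d, "zero_genes")`.
#' @export
spatial_dataset <- function(expression, coords, z = NULL, layer_index = NULL,
                            gene_names = NULL, cell_ids = NULL,
                            annotations = NULL, units_hint = "um") {
    expression <- as.matrix(expression)
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    storage.mode(expression) <- "double"
    storage.mode(coords) <- "double"
    if (nrow(coords) != nrow(expression)) {
        stopf("dimension error: %d expression rows but %d coordinate rows",
              nrow(expression), nrow(coords))
    }
    if (is.null(gene_names)) {
        gene_names <- colnames(expression)
        if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(expression)))
    }
    if (is.null(cell_ids)) {
        cell_ids <- rownames(expression)
        if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(expression)))
    }
    gene_names <- as.character(gene_names)
    cell_ids <- as.character(cell_ids)
    if (anyDuplicated(gene_names)) stopf("validation error: duplicate gene names")
    if (anyDuplicated(cell_ids)) stopf("validation error: duplicate cell ids")
    if (length(gene_names) != ncol(expression) || length(cell_ids) != nrow(expression)) {
        stopf("dimension error: id vectors do not match the expression matrix")
    }
    if (any(!is.finite(expression))) stopf("validation error: non-finite expression values")
    if (any(expression < 0)) stopf("validation error: negative expression values")
    dimnames(expression) <- list(cell_ids, gene_names)
    colnames(coords) <- c("x", "y")
    rownames(coords) <- cell_ids
    if (!is.null(z)) {
        z <- as.numeric(z)
        if (length(z) != nrow(expression)) stopf("dimension error: z length mismatch")
    }
    if (!is.null(layer_index)) {
        layer_index <- as.integer(layer_index)
        if (length(layer_index) != nrow(expression)) {
            stopf("dimension error: layer_index length mismatch")
        }
        if (!is.null(z)) {
            nz <- vapply(split(z, layer_index), function(v) length(unique(v)), 1L)
            if (any(nz != 1L)) {
                stopf("validation error: cells within one layer must share one z value")
            }
        }
    }
    if (!is.null(annotations)) {
        annotations <- as.data.frame(annotations)
        if (nrow(annotations) != nrow(expression)) {
            stopf("dimension error: annotation rows do not match cells")
        }
    }
    d <- structure(
        list(expression = expression, coords = coords, z = z,
             layer_index = layer_index, annotations = annotations,
             units_hint = units_hint,
             processing = list(normalized = FALSE, logged = FALSE, smoothed = FALSE)),
        class = "spatial_dataset")
    attr(d, "zero_genes") <- gene_names[colSums(expression) == 0]
    d
}

#' @exportS3Method print spatial_dataset
print.spatial_dataset <- function(x, ...) {
    cat(sprintf("spatial_dataset: %d cells x %d genes (%s)\n",
                nrow(x$expression), ncol(x$expression), x$units_hint))
    if (!is.null(x$layer_index)) {
        cat(sprintf("  layers: %d\n", length(unique(x$layer_index))))
    }
    p <- x$processing
    cat(sprintf("  normalized: %s, logged: %s, smoothed: %s\n",
                p$normalized, p$logged, p$smoothed))
    invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expression)

n_cells <- function(d) nrow(d$expression)
n_genes <- function(d) ncol(d$expression)

#' Preprocessing configuration
#'
#' @param do_normalize Scale each cell's counts to the median per-cell total.
#' @param do_log Apply `log(1 + x)` after normalization.
#' @param smoothing_radius Optional radius (same units as the coordinates)
#'   for quantile smoothing; `NULL` disables smoothing.
#' @param smoothing_quantiles Two fractions in `[0, 1]`, low <= high; each
#'   smoothed value is the average of these two neighborhood quantiles.
#' @return A `preprocessing_config` list.
#' @export
preprocessing_config <- function(do_normalize = TRUE, do_log = TRUE,
                                 smoothing_radius = NULL,
                                 smoothing_quantiles = c(0.20, 0.80)) {
    stopifnot(length(smoothing_quantiles) == 2,
              smoothing_quantiles[1] <= smoothing_quantiles[2],
              all(smoothing_quantiles >= 0), all(smoothing_quantiles <= 1))
    if (!is.null(smoothing_radius)) stopifnot(smoothing_radius > 0)
    structure(list(do_normalize = do_normalize, do_log = do_log,
                   smoothing_radius = smoothing_radius,
                   smoothing_quantiles = smoothing_quantiles),
              class = "preprocessing_config")
}

#' Normalize, log-transform and optionally smooth a dataset
#'
#' Applies, in fixed order: per-cell total-count normalization to the median
#' per-cell total (taken over non-empty cells), `log(1 + x)`, then quantile
#' smoothing (when a radius is configured). Cells with zero total count are
#' kept as all-zero rows with a warning.
#'
#' @param d A [spatial_dataset()].
#' @param cfg A [preprocessing_config()].
#' @return The processed dataset; `d$processing` records which steps ran.
#' @export
preprocess <- function(d, cfg = preprocessing_config()) {
    stopifnot(inherits(d, "spatial_dataset"), inherits(cfg, "preprocessing_config"))
    x <- d$expression
    if (cfg$do_normalize) {
        totals <- rowSums(x)
        if (any(totals == 0)) {
            warnf("%d cell(s) with zero total count left as zeros", sum(totals == 0))
        }
        # target: median library size among non-empty cells (a zero target
        # would annihilate the matrix on very sparse toy inputs)
        target <- median(totals[totals > 0])
        scale <- ifelse(totals > 0, target / totals, 0)
        x <- x * scale
        d$processing$normalized <- TRUE
    }
    if (cfg$do_log) {
        x <- log1p(x)
        d$processing$logged <- TRUE
    }
    d$expression <- x
    if (!is.null(cfg$smoothing_radius)) {
        d <- quantile_smooth(d, cfg$smoothing_radius,
                             cfg$smoothing_quantiles[1], cfg$smoothing_quantiles[2])
    }
    d
}

#' Quantile smoothing of expression over spatial neighborhoods
#'
#' Each cell's value for each gene is replaced by the average of the
#' `q_lo` and `q_hi` quantiles (linear-interpolation definition) of that
#' gene over all cells within Euclidean distance `radius`, the focal cell
#' included. Intended for platforms with near-cellular resolution but high
#' spatial noise.
#'
#' @param d A [spatial_dataset()].
#' @param radius Neighborhood radius, same units as the coordinates.
#' @param q_lo,q_hi Quantile fractions, `q_lo <= q_hi`.
#' @return The smoothed dataset.
#' @export
quantile_smooth <- function(d, radius, q_lo = 0.20, q_hi = 0.80) {
    stopifnot(inherits(d, "spatial_dataset"), radius > 0, q_lo <= q_hi)
    x <- d$expression
    nb <- radius_pairs(d$coords, radius)
    nbr <- split(nb$j, factor(nb$i, levels = seq_len(nrow(x))))
    out <- x
    for (i in seq_len(nrow(x))) {
        rows <- c(i, nbr[[i]])
        if (length(rows) == 1L) next  # singleton neighborhood: unchanged
        sub <- x[rows, , drop = FALSE]
        qs <- apply(sub, 2L, quantile, probs = c(q_lo, q_hi), names = FALSE)
        out[i, ] <- (qs[1L, ] + qs[2L, ]) / 2
    }
    d$expression <- out
    d$processing$smoothed <- TRUE
    d
}

#' Automatic clustering radius from the sample's vertical extent
#'
#' A simple heuristic for choosing the density-clustering radius on large
#' sections: a fixed fraction (default 0.02) of the sample's extent along
#' the y axis.
#'
#' @param d A [spatial_dataset()].
#' @param scale_factor Fraction of the vertical extent (default 0.02).
#' @return Length in the dataset's spatial units.
#' @export
auto_epsilon <- function(d, scale_factor = 0.02) {
    stopifnot(inherits(d, "spatial_dataset"))
    ext <- max(d$coords[, "y"]) - min(d$coords[, "y"])
    if (ext <= 0) stopf("degenerate sample: zero vertical extent")
    scale_factor * ext
}
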