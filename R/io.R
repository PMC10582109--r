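# Readers and writers for the standard on-disk forms of a spatial dataset:
# matrix-market triplets + label tables, delimited dense tables, and the
# HDF5 annotated-matrix (h5ad dialect) container.

read_coords_table <- function(path, coord_cols = c("x", "y", "z"),
                              layer_col = "layer", id_col = "cell_id") {
    tab <- as.data.frame(data.table::fread(path))
    miss <- setdiff(coord_cols[1:2], names(tab))
    if (length(miss)) stopf("coordinate column(s) %s not found in %s",
                            paste(miss, collapse = ", "), path)
    list(coords = as.matrix(tab[, coord_cols[1:2]]),
         z = if (length(coord_cols) >= 3 && coord_cols[3] %in% names(tab))
                 tab[[coord_cols[3]]] else NULL,
         layer = if (layer_col %in% names(tab)) as.integer(tab[[layer_col]]) else NULL,
         ids = if (id_col %in% names(tab)) as.character(tab[[id_col]]) else NULL,
         extra = tab[, setdiff(names(tab), c(coord_cols, layer_col, id_col)),
                     drop = FALSE])
}

#' Read a spatial dataset
#'
#' One entry point for the three supported on-disk forms.
#'
#' * `format = "mtx"`: a matrix-market triplet file plus one-column gene and
#'   cell label files and a delimited coordinate table.
#' * `format = "delim"`: a dense delimited table (cells in rows, first column
#'   cell ids) plus a coordinate table.
#' * `format = "h5ad"`: an HDF5 annotated-matrix container with coordinates
#'   under `obsm/<spatial_key>` (requires the `rhdf5` package).
#'
#' @param path Main file: the `.mtx`, the dense table, or the `.h5ad`.
#' @param format One of `"mtx"`, `"delim"`, `"h5ad"`.
#' @param coords_file Delimited coordinate table with columns named by
#'   `coord_cols` (plus optional `layer` and `cell_id` columns); required for
#'   `"mtx"` and `"delim"`.
#' @param genes_file,cells_file One-label-per-line files (mtx format).
#' @param genes_in_rows For mtx input, whether the matrix is genes x cells
#'   (the common convention; default `TRUE`).
#' @param coord_cols Names of the x, y (and optional z) columns.
#' @param spatial_key Name of the coordinate slot in the h5ad container.
#' @param units_hint Spatial unit descriptor stored on the dataset.
#' @return A [spatial_dataset()].
#' @export
load_dataset <- function(path, format = c("mtx", "delim", "h5ad"),
                         coords_file = NULL, genes_file = NULL,
                         cells_file = NULL, genes_in_rows = TRUE,
                         coord_cols = c("x", "y", "z"),
                         spatial_key = "spatial", units_hint = "um") {
    format <- match.arg(format)
    if (!file.exists(path)) stopf("input file not found: %s", path)
    if (format == "h5ad") return(read_spatial_h5ad(path, spatial_key, units_hint))
    if (is.null(coords_file)) stopf("coords_file is required for %s input", format)
    ct <- read_coords_table(coords_file, coord_cols)
    if (format == "mtx") {
        m <- Matrix::readMM(path)
        if (genes_in_rows) m <- Matrix::t(m)
        genes <- if (!is.null(genes_file)) readLines(genes_file) else NULL
        cells <- if (!is.null(cells_file)) readLines(cells_file) else NULL
        spatial_dataset(as.matrix(m), ct$coords, z = ct$z, layer_index = ct$layer,
                        gene_names = genes,
                        cell_ids = if (!is.null(cells)) cells else ct$ids,
                        units_hint = units_hint)
    } else {
        tab <- as.data.frame(data.table::fread(path))
        ids <- as.character(tab[[1]])
        expr <- as.matrix(tab[, -1, drop = FALSE])
        spatial_dataset(expr, ct$coords, z = ct$z, layer_index = ct$layer,
                        gene_names = colnames(expr), cell_ids = ids,
                        units_hint = units_hint)
    }
}

#' Write a spatial dataset as flat delimited files
#'
#' Writes `expression.csv` (cells x genes, first column `cell_id`) and
#' `coords.csv` (`cell_id`, `x`, `y`, optional `z`, `layer`).
#'
#' @param d A [spatial_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_spatial_csv <- function(d, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ef <- file.path(dir, "expression.csv")
    cf <- file.path(dir, "coords.csv")
    data.table::fwrite(data.table::data.table(cell_id = rownames(d$expression),
                                              d$expression), ef)
    co <- data.table::data.table(cell_id = rownames(d$coords),
                                 x = d$coords[, 1], y = d$coords[, 2])
    if (!is.null(d$z)) co$z <- d$z
    if (!is.null(d$layer_index)) co$layer <- d$layer_index
    data.table::fwrite(co, cf)
    invisible(c(expression = ef, coords = cf))
}

#' Write a spatial dataset as matrix-market triplets plus label tables
#'
#' @param d A [spatial_dataset()].
#' @param dir Output directory; writes `matrix.mtx` (genes x cells),
#'   `genes.txt`, `cells.txt`, `coords.csv`.
#' @return Invisibly, the file paths.
#' @export
write_spatial_mtx <- function(d, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mf <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(Matrix::Matrix(t(d$expression), sparse = TRUE), mf)
    writeLines(colnames(d$expression), file.path(dir, "genes.txt"))
    writeLines(rownames(d$expression), file.path(dir, "cells.txt"))
    co <- data.table::data.table(cell_id = rownames(d$coords),
                                 x = d$coords[, 1], y = d$coords[, 2])
    if (!is.null(d$z)) co$z <- d$z
    if (!is.null(d$layer_index)) co$layer <- d$layer_index
    data.table::fwrite(co, file.path(dir, "coords.csv"))
    invisible(c(matrix = mf, genes = file.path(dir, "genes.txt"),
                cells = file.path(dir, "cells.txt"),
                coords = file.path(dir, "coords.csv")))
}

require_rhdf5 <- function() {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
        stopf("the h5ad container requires the 'rhdf5' package")
    }
}

#' Read an HDF5 annotated-matrix (h5ad dialect) container
#'
#' Supports dense `X` and CSR/CSC sparse `X` groups, `obs`/`var` index
#' columns, and coordinates under `obsm/<spatial_key>` (2 or 3 columns).
#'
#' @param path The `.h5ad` file.
#' @param spatial_key Coordinate slot under `obsm` (default `"spatial"`).
#' @param units_hint Spatial unit descriptor.
#' @return A [spatial_dataset()].
#' @export
read_spatial_h5ad <- function(path, spatial_key = "spatial", units_hint = "um") {
    require_rhdf5()
    if (!file.exists(path)) stopf("input file not found: %s", path)
    h5attr1 <- function(obj, name) {
        a <- rhdf5::h5readAttributes(path, obj)
        if (name %in% names(a)) as.character(a[[name]])[1] else NULL
    }
    read_index <- function(group) {
        idx_name <- h5attr1(group, "_index")
        if (is.null(idx_name)) idx_name <- "_index"
        as.character(rhdf5::h5read(path, paste0(group, "/", idx_name)))
    }
    cells <- read_index("obs")
    genes <- read_index("var")
    enc <- h5attr1("X", "encoding-type")
    if (!is.null(enc) && grepl("csr|csc", enc)) {
        data <- as.numeric(rhdf5::h5read(path, "X/data"))
        indices <- as.integer(rhdf5::h5read(path, "X/indices"))
        indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
        if (grepl("csr", enc)) {
            # CSR over cells x genes == column-compressed genes x cells
            m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                      dims = c(length(genes), length(cells)))
            expr <- t(as.matrix(m))
        } else {
            m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                      dims = c(length(cells), length(genes)))
            expr <- as.matrix(m)
        }
    } else {
        expr <- rhdf5::h5read(path, "X")
        # HDF5 stores row-major; anndata writes cells x genes, rhdf5 returns
        # the transposed array
        expr <- t(as.matrix(expr))
    }
    sp <- t(as.matrix(rhdf5::h5read(path, paste0("obsm/", spatial_key))))
    if (nrow(sp) != length(cells)) sp <- t(sp)
    z <- if (ncol(sp) >= 3) as.numeric(sp[, 3]) else NULL
    layer <- tryCatch(as.integer(rhdf5::h5read(path, "obs/layer")),
                      error = function(e) NULL)
    spatial_dataset(expr, sp[, 1:2, drop = FALSE], z = z, layer_index = layer,
                    gene_names = genes, cell_ids = cells, units_hint = units_hint)
}

#' Write a spatial dataset as an HDF5 annotated-matrix container
#'
#' Writes dense `X` (cells x genes), `obs`/`var` with `_index`, and the
#' coordinates under `obsm/spatial` (3 columns when z is present).
#'
#' @param d A [spatial_dataset()].
#' @param path Output `.h5ad` file path (overwritten).
#' @return Invisibly, `path`.
#' @export
write_spatial_h5ad <- function(d, path) {
    require_rhdf5()
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t(d$expression), path, "X")
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5createGroup(path, "obsm")
    rhdf5::h5write(rownames(d$expression), path, "obs/_index")
    rhdf5::h5write(colnames(d$expression), path, "var/_index")
    if (!is.null(d$layer_index)) rhdf5::h5write(d$layer_index, path, "obs/layer")
    sp <- if (!is.null(d$z)) cbind(d$coords, z = d$z) else d$coords
    rhdf5::h5write(t(unname(sp)), path, "obsm/spatial")
    fid <- rhdf5::H5Fopen(path)
    for (grp in c("obs", "var")) {
        gid <- rhdf5::H5Gopen(fid, grp)
        rhdf5::h5writeAttribute("_index", gid, "_index")
        rhdf5::H5Gclose(gid)
    }
    rhdf5::H5Fclose(fid)
    invisible(path)
}
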