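#' @useDynLib hierspot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile median prcomp p.adjust pnorm pwilcox hclust as.dist
#' @importFrom utils combn head write.csv
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Derive a stage-specific child seed from a master seed
#'
#' A single run seed fans out to deterministic per-stage seeds so that any
#' stage can be rerun in isolation and reproduce its in-pipeline behaviour.
#' The result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed Master seed (integer).
#' @param stage Stage label (character) or integer offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
    if (is.character(stage)) {
        stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    }
    as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %%
                   (.Machine$integer.max - 1))
}

# All (i, j) index pairs with Euclidean distance <= radius, i != j, both
# directions. Uses a kd-tree radius query; k grows until no row saturates.
radius_pairs <- function(coords, radius) {
    n <- nrow(coords)
    if (n < 2) {
        return(list(i = integer(0), j = integer(0), d = numeric(0)))
    }
    k <- min(n, 32L)
    repeat {
        nn <- RANN::nn2(coords, searchtype = "radius", radius = radius, k = k)
        saturated <- k < n && any(nn$nn.idx[, k] != 0)
        if (!saturated) break
        k <- min(n, k * 2L)
    }
    idx <- nn$nn.idx
    dmat <- nn$nn.dists
    i <- rep.int(seq_len(n), ncol(idx))
    keep <- idx != 0 & idx != i   # drop padding and self
    list(i = i[keep], j = idx[keep], d = dmat[keep])
}

# Lower-triangular sparse matrix from symmetric pair values: entry (max, min).
pairs_to_sparse <- function(i, j, x, n) {
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    keep <- !duplicated(cbind(lo, hi))
    Matrix::sparseMatrix(i = hi[keep], j = lo[keep], x = x[keep], dims = c(n, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
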