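# Synthetic recursive-halving hierarchy benchmark: a 5-layer nested spatial
# structure with zero-inflated Poisson counts, plus ground-truth scoring by
# linear-sum-assignment Jaccard matching.

#' Configuration of the synthetic nested hierarchy
#'
#' The generator plants a chain of nested regions on a regular grid: layer 1
#' covers the whole domain, and each deeper layer covers half of the
#' previous one (the split axis alternates, so regions stay compact). A
#' chosen number of spatial genes is divided evenly over the layers; each is
#' expressed at rate `lambda_in` inside its region and `lambda_out` outside.
#' Non-spatial genes are spatially uniform at `lambda_out`. Counts follow a
#' zero-inflated Poisson: with probability `zip_pi` a count is forced to
#' zero, otherwise Poisson at the local rate (mean `(1 - zip_pi) * lambda`).
#'
#' @param n_layers Number of nested layers (default 5).
#' @param n_genes Total gene count (default 2048).
#' @param n_spatial_genes Spatially informative genes (default 512), divided
#'   evenly over the layers.
#' @param grid_side Cells per side of the square grid (default 64; spacing 1
#'   spatial unit).
#' @param zip_pi Zero-inflation probability (default 0.3; at much higher
#'   inflation the in-region density of detectable cells drops below the
#'   site-percolation threshold of the grid and planted regions fragment,
#'   which is a property of the geometry rather than of the method).
#' @param lambda_in,lambda_out Poisson rates inside / outside the assigned
#'   region (defaults 8 and 0.3).
#' @param seed RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_layers = 5L, n_genes = 2048L,
                             n_spatial_genes = 512L, grid_side = 64L,
                             zip_pi = 0.3, lambda_in = 8, lambda_out = 0.3,
                             seed = 0L) {
    stopifnot(n_spatial_genes <= n_genes, n_spatial_genes >= 0,
              lambda_in > lambda_out, lambda_out >= 0,
              zip_pi >= 0, zip_pi < 1, n_layers >= 1, grid_side >= 2)
    structure(list(n_layers = as.integer(n_layers), n_genes = as.integer(n_genes),
                   n_spatial_genes = as.integer(n_spatial_genes),
                   grid_side = as.integer(grid_side), zip_pi = zip_pi,
                   lambda_in = lambda_in, lambda_out = lambda_out,
                   seed = as.integer(seed)),
              class = "synthetic_config")
}

# Nested regions by recursive halving with alternating split axis. Returns a
# list of integer cell-index sets, layer 1 = all cells.
halving_regions <- function(coords, n_layers) {
    regions <- vector("list", n_layers)
    regions[[1]] <- seq_len(nrow(coords))
    cur <- regions[[1]]
    for (k in seq_len(n_layers - 1L)) {
        axis <- if (k %% 2 == 1) 1L else 2L   # vertical split first
        v <- coords[cur, axis]
        cut <- median(range(v))
        cur <- cur[v <= cut]
        regions[[k + 1L]] <- cur
    }
    regions
}

rzip <- function(n, pi0, lambda) {
    ifelse(stats::rbinom(n, 1L, 1 - pi0) == 1L, stats::rpois(n, lambda), 0L)
}

#' Generate the synthetic nested-hierarchy dataset
#'
#' Draws zero-inflated Poisson counts on a regular grid per
#' [synthetic_config()], then normalizes and log-transforms the dataset.
#' Bit-reproducible for a fixed `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `dataset` (log-normalized [spatial_dataset()]; raw
#'   counts in `attr(, "raw_counts")`), `truth` (list of nested ground-truth
#'   cell-index sets, outermost first), and `gene_layer` (per-gene layer
#'   assignment, NA for non-spatial genes).
#' @export
generate_hierarchy <- function(cfg = synthetic_config()) {
    stopifnot(inherits(cfg, "synthetic_config"))
    side <- cfg$grid_side
    coords <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
    n <- nrow(coords)
    regions <- halving_regions(coords, cfg$n_layers)
    gene_layer <- rep(NA_integer_, cfg$n_genes)
    if (cfg$n_spatial_genes > 0) {
        gene_layer[seq_len(cfg$n_spatial_genes)] <-
            rep_len(seq_len(cfg$n_layers), cfg$n_spatial_genes)
    }
    counts <- with_seed(cfg$seed, {
        m <- matrix(0L, n, cfg$n_genes)
        for (g in seq_len(cfg$n_genes)) {
            lam <- rep(cfg$lambda_out, n)
            if (!is.na(gene_layer[g])) lam[regions[[gene_layer[g]]]] <- cfg$lambda_in
            m[, g] <- rzip(n, cfg$zip_pi, lam)
        }
        m
    })
    gene_names <- ifelse(is.na(gene_layer),
                         sprintf("noise%04d", seq_len(cfg$n_genes)),
                         sprintf("spatial_L%d_%04d", gene_layer,
                                 seq_len(cfg$n_genes)))
    d <- spatial_dataset(counts, coords, gene_names = gene_names,
                         units_hint = "grid")
    d <- suppressWarnings(preprocess(d, preprocessing_config()))
    attr(d, "raw_counts") <- counts
    list(dataset = d, truth = regions, gene_layer = gene_layer, config = cfg)
}

#' Match detected hotspots to ground-truth regions
#'
#' One-to-one matching between detected coexpression hotspots and ground-
#' truth regions by linear sum assignment maximizing the Jaccard similarity
#' of matched cell sets. Unmatched entries on either side score zero; the
#' summary is the mean over all matched pairs and unmatched entries.
#'
#' @param found List of `coexpression_hotspot` objects (or plain integer
#'   cell-index vectors).
#' @param truth List of ground-truth cell-index sets.
#' @return List with `pairs` (data frame: `found`, `truth_region`,
#'   `jaccard`), `per_region` (best Jaccard per truth region, 0 when
#'   unmatched) and `mean` (the averaged score).
#' @export
match_score <- function(found, truth) {
    sets <- lapply(found, function(f) if (is.list(f)) f$members else f)
    nf <- length(sets); nt <- length(truth)
    if (nf == 0 || nt == 0) {
        return(list(pairs = data.frame(found = integer(0), truth_region = integer(0),
                                       jaccard = numeric(0)),
                    per_region = rep(0, nt),
                    mean = 0))
    }
    J <- matrix(0, nf, nt)
    for (a in seq_len(nf)) {
        for (b in seq_len(nt)) {
            inter <- length(intersect(sets[[a]], truth[[b]]))
            J[a, b] <- inter / (length(sets[[a]]) + length(truth[[b]]) - inter)
        }
    }
    if (nf <= nt) {
        sol <- clue::solve_LSAP(J, maximum = TRUE)
        pairs <- data.frame(found = seq_len(nf), truth_region = as.integer(sol))
    } else {
        sol <- clue::solve_LSAP(t(J), maximum = TRUE)
        pairs <- data.frame(found = as.integer(sol), truth_region = seq_len(nt))
    }
    pairs$jaccard <- J[cbind(pairs$found, pairs$truth_region)]
    per_region <- rep(0, nt)
    per_region[pairs$truth_region] <- pairs$jaccard
    denom <- nf + nt - nrow(pairs)     # matched pairs + unmatched on both sides
    list(pairs = pairs, per_region = per_region,
         mean = sum(pairs$jaccard) / denom)
}

#' Stability of coexpression hotspots under gene subsampling
#'
#' Recomputes coexpression hotspots on random gene subsets and scores, for
#' each original hotspot, the Jaccard similarity to its best-match
#' subsampled hotspot, averaged over replicates. Near 1: the hotspot is
#' robust to losing genes; near 0: it is no longer found.
#'
#' @param d A preprocessed [spatial_dataset()].
#' @param det_cfg,coex_cfg Pipeline configurations.
#' @param fractions Gene fractions to test (default `c(0.5, 0.8)`).
#' @param n_reps Replicates per fraction (default 10).
#' @param seed RNG seed.
#' @param chs Optional precomputed coexpression hotspots of the full dataset.
#' @return Data frame with `ch_id`, `fraction`, `mean_jaccard`.
#' @export
subsample_stability <- function(d, det_cfg, coex_cfg = coexpression_config(),
                                fractions = c(0.5, 0.8), n_reps = 10L,
                                seed = 0L, chs = NULL) {
    if (is.null(chs)) chs <- run_coexpression(d, det_cfg, coex_cfg)
    if (!length(chs)) return(data.frame(ch_id = integer(0), fraction = numeric(0),
                                        mean_jaccard = numeric(0)))
    genes <- colnames(d$expression)
    out <- list()
    for (f in fractions) {
        scores <- matrix(0, length(chs), n_reps)
        for (r in seq_len(n_reps)) {
            sub_genes <- with_seed(derive_seed(seed, r * 1000L + round(f * 100)),
                                   sample(genes, ceiling(f * length(genes))))
            ds <- d
            ds$expression <- d$expression[, sub_genes, drop = FALSE]
            sub <- suppressWarnings(run_coexpression(ds, det_cfg, coex_cfg))
            for (a in seq_along(chs)) {
                best <- 0
                for (s in sub) {
                    inter <- length(intersect(chs[[a]]$members, s$members))
                    j <- inter / (length(chs[[a]]$members) + length(s$members) - inter)
                    best <- max(best, j)
                }
                scores[a, r] <- best
            }
        }
        out[[length(out) + 1L]] <- data.frame(
            ch_id = vapply(chs, `[[`, 1L, "id"), fraction = f,
            mean_jaccard = rowMeans(scores))
    }
    do.call(rbind, out)
}

#' One-at-a-time parameter sensitivity sweep on synthetic hierarchies
#'
#' Starting from default detection and coexpression parameters, varies one
#' parameter at a time over a grid, generating `n_reps` independent
#' synthetic datasets per point, running the full pipeline and scoring with
#' [match_score()] against the planted regions.
#'
#' @param sweep Named list: parameter name (`"epsilon"`, `"local_density"`,
#'   `"jaccard_threshold"`, `"resolution"`) to numeric value grid.
#' @param syn_cfg Generator configuration ([synthetic_config()]).
#' @param det_cfg,coex_cfg Baseline pipeline configurations.
#' @param n_reps Independent datasets per grid point (default 10).
#' @param seed Master seed.
#' @return Data frame with one row per (parameter, value, replicate) and the
#'   matched-Jaccard `score`.
#' @export
parameter_sweep <- function(sweep, syn_cfg = synthetic_config(),
                            det_cfg, coex_cfg = coexpression_config(),
                            n_reps = 10L, seed = 0L) {
    rows <- list()
    for (par in names(sweep)) {
        for (val in sweep[[par]]) {
            dc <- det_cfg; cc <- coex_cfg
            if (par %in% c("epsilon", "local_density")) dc[[par]] <- val
            else if (par %in% c("jaccard_threshold", "resolution")) cc[[par]] <- val
            else stopf("unknown sweep parameter: %s", par)
            for (r in seq_len(n_reps)) {
                sc <- syn_cfg
                sc$seed <- derive_seed(seed, paste(par, val, r))
                gen <- generate_hierarchy(sc)
                chs <- suppressWarnings(run_coexpression(gen$dataset, dc, cc))
                rows[[length(rows) + 1L]] <- data.frame(
                    parameter = par, value = val, replicate = r,
                    score = match_score(chs, gen$truth)$mean)
            }
        }
    }
    do.call(rbind, rows)
}
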