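hs_of <- function(...) {
    sets <- list(...)
    lapply(seq_along(sets), function(i)
        hierspot:::new_gene_hotspot(paste0("g", i), sets[[i]]))
}

test_that("overlap counting matches direct set intersection", {
    hs <- hs_of(c(1, 2, 3), c(2, 3, 4), c(10, 11, 12))
    O <- overlap_counts(hs, 12)
    expect_equal(O[1, 2], 2)
    expect_equal(O[2, 1], 2)
    expect_equal(O[1, 3], 0)
    expect_equal(Matrix::diag(O), rep(0, 3))
})

test_that("chunked overlap counting equals brute force for any chunk grid", {
    set.seed(21)
    n <- 400
    coords <- cbind(x = runif(n, 0, 50), y = runif(n, 0, 50))
    hs <- lapply(1:50, function(i) {
        cx <- runif(1, 0, 50); cy <- runif(1, 0, 50); r <- runif(1, 3, 12)
        m <- which((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2 <= r^2)
        if (!length(m)) m <- sample(n, 3)
        hierspot:::new_gene_hotspot(paste0("g", i), m)
    })
    oracle <- naive_overlap(hs)
    for (grid in list(c(1, 1), c(3, 7), c(10, 10), c(25, 2))) {
        O <- overlap_counts(hs, n, grid, coords)
        expect_equal(unname(as.matrix(O)), oracle,
                     info = paste(grid, collapse = "x"))
    }
})

test_that("jaccard network applies the similarity formula and strict threshold", {
    hs <- hs_of(1:3, 1:3, c(2, 3, 4))
    O <- overlap_counts(hs, 4)
    sizes <- c(3L, 3L, 3L)
    net <- jaccard_network(O, sizes, threshold = 0.3)
    expect_equal(net$adjacency[1, 2], 1)          # identical hotspots
    expect_equal(net$adjacency[1, 3], 0.5)        # 2 / (3 + 3 - 2)
    net6 <- jaccard_network(O, sizes, threshold = 0.6)
    expect_equal(net6$adjacency[1, 3], 0)         # 0.5 excluded at 0.6
    expect_equal(net6$adjacency[1, 2], 1)
    # symmetric, empty diagonal, weights in (threshold, 1]
    expect_true(Matrix::isSymmetric(net$adjacency))
    expect_true(all(Matrix::diag(net$adjacency) == 0))
    w <- net$adjacency@x
    expect_true(all(w > 0.3 & w <= 1))
})

test_that("leiden communities split weakly joined cliques deterministically", {
    # two 5-cliques joined by one weak edge
    n <- 10
    A <- matrix(0, n, n)
    A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1
    diag(A) <- 0
    A[5, 6] <- A[6, 5] <- 0.31
    net <- structure(list(n = n, adjacency = Matrix::Matrix(A, sparse = TRUE)),
                     class = "hotspot_network")
    p <- leiden_communities(net, resolution = 1, seed = 0)
    expect_equal(length(unique(p)), 2L)
    expect_equal(length(unique(p[1:5])), 1L)
    expect_equal(length(unique(p[6:10])), 1L)
    expect_identical(p, leiden_communities(net, resolution = 1, seed = 0))
    # isolated node forms its own community
    B <- rbind(cbind(A, 0), 0)
    netB <- structure(list(n = n + 1, adjacency = Matrix::Matrix(B, sparse = TRUE)),
                      class = "hotspot_network")
    pB <- leiden_communities(netB, 1, 0)
    expect_false(pB[n + 1] %in% pB[1:n])
})

test_that("communities become coexpression hotspots under the membership rule", {
    cfg <- coexpression_config(min_genes = 3, membership_cutoff = 0.3)
    # community of 2 hotspots: below min_genes
    hs2 <- hs_of(1:5, 2:6)
    expect_length(form_coexpression_hotspots(c(1, 1), hs2, cfg, 6), 0L)
    # community of 4: cell 1 in exactly 1 of 4 (0.25) out, cell 2 in 2 (0.5) in
    hs4 <- hs_of(c(1, 2, 3), c(2, 3), c(3, 4), c(3, 4, 5))
    ch <- form_coexpression_hotspots(rep(1, 4), hs4, cfg, 5)[[1]]
    expect_false(1 %in% ch$members)
    expect_true(2 %in% ch$members)
    # community of 3: any member cell has fraction 1/3 > 0.3 -> union
    hs3 <- hs_of(1:2, 3:4, 5:6)
    ch3 <- form_coexpression_hotspots(rep(1, 3), hs3, cfg, 6)[[1]]
    expect_setequal(ch3$members, 1:6)
})

test_that("coexpression hotspot ids decrease with size and genes deduplicate", {
    cfg <- coexpression_config(min_genes = 3, membership_cutoff = 0.3)
    hs <- c(hs_of(1:2, 1:2, 1:2), hs_of(1:10, 1:10, 1:10))
    hs[[1]]$gene <- "dup"; hs[[2]]$gene <- "dup"
    chs <- form_coexpression_hotspots(c(1, 1, 1, 2, 2, 2), hs, cfg, 10)
    expect_equal(vapply(chs, `[[`, 1L, "id"), c(0L, 1L))
    expect_gt(length(chs[[1]]$members), length(chs[[2]]$members))
    expect_equal(sort(chs[[2]]$genes), c("dup", "g3"))
    expect_length(chs[[2]]$gene_hotspots, 3L)
})

test_that("the pipeline recovers planted regions and nothing from noise", {
    d <- make_two_region_fixture(genes_per_region = 10, side = 20, seed = 1)
    chs <- run_coexpression(d, small_det_cfg(), coexpression_config(seed = 0))
    expect_length(chs, 2L)
    got <- lapply(chs, `[[`, "members")
    want <- list(region_cells(20, c(1, 8), c(1, 8)),
                 region_cells(20, c(12, 20), c(12, 20)))
    ms <- match_score(chs, want)
    expect_gt(min(ms$pairs$jaccard), 0.8)
    # all-noise dataset: nothing
    set.seed(30)
    noise <- spatial_dataset(matrix(rpois(400 * 20, 0.3), 400, 20),
                             grid_coords(20))
    noise <- suppressWarnings(preprocess(noise, preprocessing_config()))
    expect_length(run_coexpression(noise, small_det_cfg(),
                                   coexpression_config(seed = 0)), 0L)
})

test_that("nested planted regions give overlapping nested hotspots", {
    d <- make_planted_dataset(20, list(
        A = list(x = c(1, 16), y = c(1, 16), genes = 8),
        B = list(x = c(4, 10), y = c(4, 10), genes = 8)), n_noise = 4, seed = 2)
    chs <- run_coexpression(d, small_det_cfg(), coexpression_config(seed = 0))
    expect_length(chs, 2L)
    big <- chs[[1]]$members; small <- chs[[2]]$members
    expect_gt(length(intersect(small, big)) / length(small), 0.95)
    tree <- build_tree(chs)
    expect_equal(unname(tree$parent), c(NA_integer_, 0L))
})

test_that("genes without hotspots do not change the result", {
    d <- make_two_region_fixture(genes_per_region = 5, side = 16, seed = 3)
    base <- run_coexpression(d, small_det_cfg(), coexpression_config(seed = 0))
    d2 <- d
    set.seed(31)
    d2$expression <- cbind(d$expression,
                           flat1 = log1p(rbinom(256, 1, 0.1)),
                           flat2 = 0)
    chs2 <- suppressWarnings(run_coexpression(d2, small_det_cfg(),
                                              coexpression_config(seed = 0)))
    expect_equal(lapply(chs2, `[[`, "members"), lapply(base, `[[`, "members"))
})
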