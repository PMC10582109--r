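test_that("otsu threshold separates the obvious two-group cases", {
    r <- otsu_threshold(c(0, 0, 0, 10, 10))
    expect_equal(which(r$mask), c(4L, 5L))
    r2 <- otsu_threshold(c(0, 1))
    expect_equal(which(r2$mask), 2L)
    expect_error(otsu_threshold(rep(3.5, 10)), "constant")
})

test_that("otsu threshold matches the exhaustive variance minimizer", {
    set.seed(3)
    for (i in 1:40) {
        v <- switch(1 + i %% 4,
                    rpois(50, 2),
                    c(rnorm(30, 0), rnorm(20, 4)),
                    round(runif(25, 0, 5)),       # heavy ties
                    rexp(40))
        if (length(unique(v)) < 2) next
        expect_equal(otsu_threshold(v)$threshold, naive_otsu(v), info = paste("case", i))
    }
})

test_that("dbscan clustering matches a naive density-connectivity oracle", {
    set.seed(5)
    # two discs of 10 points separated by 10 * epsilon
    disc <- function(cx, cy) cbind(x = cx + runif(10, -1, 1),
                                   y = cy + runif(10, -1, 1))
    pts <- rbind(disc(0, 0), disc(20, 0))
    cfg <- hotspot_config(epsilon = 2, local_density = 0.5, hotspot_min_size = 5)
    hs <- dbscan_hotspots(pts, cfg, gene = "g")
    expect_length(hs, 2L)
    # oracle with the same derived min_samples
    pr <- as.matrix(dist(pts))
    mean_nb <- mean(rowSums(pr <= 2) - 1)
    ms <- max(2L, round(0.5 * mean_nb))
    oracle <- naive_dbscan(pts, 2, ms, 5)
    got <- lapply(hs, `[[`, "members")
    expect_setequal(lapply(got, sort), lapply(oracle, sort))
})

test_that("dbscan handles empty input and the size filter", {
    cfg <- hotspot_config(epsilon = 1, hotspot_min_size = 5)
    expect_length(dbscan_hotspots(matrix(numeric(0), 0, 2), cfg), 0L)
    tri <- cbind(x = c(0, 0.5, 1), y = c(0, 0.5, 0))
    expect_length(dbscan_hotspots(tri, cfg), 0L)
})

test_that("dbscan is invariant to point order and rigid motion", {
    set.seed(11)
    pts <- rbind(cbind(runif(30, 0, 3), runif(30, 0, 3)),
                 cbind(runif(25, 10, 12), runif(25, 10, 12)))
    cfg <- hotspot_config(epsilon = 1.5, local_density = 0.3, hotspot_min_size = 5)
    base <- lapply(dbscan_hotspots(pts, cfg), `[[`, "members")
    perm <- sample(nrow(pts))
    shuf <- lapply(dbscan_hotspots(pts[perm, ], cfg, point_index = perm),
                   `[[`, "members")
    expect_setequal(lapply(base, sort), lapply(shuf, sort))
    th <- 0.7
    rot <- pts %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) + 100
    rotr <- lapply(dbscan_hotspots(rot, cfg), `[[`, "members")
    expect_setequal(lapply(base, sort), lapply(rotr, sort))
})

test_that("per-gene hotspots find planted discs and skip uninformative genes", {
    side <- 16
    d <- make_planted_dataset(side, list(A = list(x = c(3, 9), y = c(3, 9),
                                                  genes = 1)),
                              n_noise = 0, seed = 2)
    # add a uniform random gene and an all-zero gene
    set.seed(9)
    expr <- cbind(d$expression,
                  uniform = log1p(rbinom(side^2, 1, 0.15)),
                  zero = 0)
    d2 <- spatial_dataset(expr, d$coords)
    d2$processing <- d$processing
    cfg <- small_det_cfg()
    expect_warning(hs <- compute_all_gene_hotspots(d2, cfg), "constant")
    genes <- vapply(hs, `[[`, "", "gene")
    expect_equal(sum(genes == "A_g1"), 1L)
    expect_equal(sum(genes == "zero"), 0L)
    expect_equal(sum(genes == "uniform"), 0L)
    # planted hotspot covers the region, with high precision
    target <- region_cells(side, c(3, 9), c(3, 9))
    got <- hs[[which(genes == "A_g1")]]$members
    expect_gt(length(intersect(got, target)) / length(union(got, target)), 0.8)
})

test_that("uniform random genes yield no hotspots across seeds", {
    side <- 16
    for (seed in 1:4) {
        set.seed(seed)
        d <- spatial_dataset(matrix(rbinom(side^2 * 3, 1, 0.15), side^2, 3),
                             grid_coords(side))
        hs <- compute_all_gene_hotspots(d, small_det_cfg())
        expect_length(hs, 0L)
    }
})

test_that("hotspot members exceed the Otsu threshold and are disjoint per gene", {
    d <- make_two_region_fixture(genes_per_region = 2, side = 16, seed = 4)
    hs <- compute_all_gene_hotspots(d, small_det_cfg())
    expect_gt(length(hs), 0)
    for (g in unique(vapply(hs, `[[`, "", "gene"))) {
        mine <- hs[vapply(hs, `[[`, "", "gene") == g]
        thr <- mine[[1]]$threshold
        members <- unlist(lapply(mine, `[[`, "members"))
        expect_equal(anyDuplicated(members), 0L)
        expect_true(all(d$expression[members, g] > thr))
    }
})

test_that("layered data produces per-layer hotspots with source_layer set", {
    side <- 10
    coords <- rbind(grid_coords(side), grid_coords(side))
    layer <- rep(1:2, each = side^2)
    inside <- c(region_cells(side, c(2, 6), c(2, 6)),
                side^2 + region_cells(side, c(2, 6), c(2, 6)))
    set.seed(6)
    v <- rpois(2 * side^2, 0.05); v[inside] <- 5 + rpois(length(inside), 2)
    d <- spatial_dataset(cbind(g = v), coords, layer_index = layer,
                         z = layer * 10)
    hs <- compute_all_gene_hotspots(d, small_det_cfg())
    expect_equal(sort(vapply(hs, `[[`, 1L, "source_layer")), c(1L, 2L))
})
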