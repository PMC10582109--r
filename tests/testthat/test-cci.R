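lr_file <- function(rows) {
    f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(c("ligand,receptor,pathway,annotation", rows), f)
    f
}

test_that("the interaction database is filtered by annotation and gene presence", {
    fx <- make_cci_fixture()
    f <- lr_file(c("LigA,RecA,PathA,Secreted Signaling",
                   "LigA,Missing,PathA,Secreted Signaling",
                   "LigA,RecA,PathB,ECM-Receptor",
                   "other,RecA,PathC,Cell-Cell Contact"))
    db <- load_lr_database(f, dataset = fx$d)
    expect_equal(nrow(db), 2L)
    expect_equal(attr(db, "n_class_dropped"), 1L)
    expect_equal(attr(db, "n_missing_genes"), 1L)
    f2 <- lr_file(character(0))
    expect_warning(db2 <- load_lr_database(f2), "no analyzable")
    expect_equal(nrow(db2), 0L)
    f3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("ligand,receptor", "a,b"), f3)
    expect_error(load_lr_database(f3), "lacks column")
})

test_that("diffusion transport is a truncated Gaussian with unit row sums", {
    # isolated cell: all ligand stays
    A1 <- diffusion_transport(cbind(0, 0), cutoff = 10)
    expect_equal(as.numeric(A1$A), 1)
    # two cells at distance sigma
    A2 <- diffusion_transport(rbind(c(0, 0), c(5, 0)), cutoff = 10)
    w <- exp(-0.5)
    expect_equal(A2$A[1, 1], 1 / (1 + w))
    expect_equal(A2$A[1, 2], w / (1 + w))
    # row sums exactly 1 in 2D and 3D
    set.seed(22)
    xy <- cbind(runif(80, 0, 50), runif(80, 0, 50))
    xyz <- cbind(xy, sample(c(0, 10, 20), 80, TRUE))
    for (coords in list(xy, xyz)) {
        A <- diffusion_transport(coords, cutoff = 15)
        expect_lt(max(abs(Matrix::rowSums(A$A) - 1)), 1e-12)
    }
})

test_that("contact transport keeps short Delaunay edges only", {
    sq <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
    A <- contact_transport(sq, max_edge = 12)   # diagonals ~14.1 removed
    M <- as.matrix(A$A)
    expect_equal(sum(M[1, ] > 0), 3L)            # self + 2 side neighbors
    expect_equal(M[1, 4], 0)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    # all edges too long: identity
    far <- rbind(c(0, 0), c(100, 0), c(50, 90))
    expect_equal(as.matrix(contact_transport(far, 20)$A), diag(3),
                 ignore_attr = TRUE)
    # degenerate geometry errors
    expect_error(contact_transport(rbind(c(0, 0), c(1, 1)), 5), "degenerate")
})

test_that("activity follows the Hill function of transported ligand x receptor", {
    coords <- rbind(c(0, 0), c(1000, 1000))
    d <- spatial_dataset(cbind(L = c(exp(1) - 1, 0), R = c(exp(1) - 1, 0)),
                         coords)
    d$processing$logged <- TRUE
    A <- diffusion_transport(coords, cutoff = 10)  # both cells isolated
    pair <- list(ligand = "L", receptor = "R")
    f <- cci_activity(d, pair, A, K_h = 0.5)
    expect_equal(f$activity[1], 1 / 1.5)           # L' = R = 1
    expect_equal(f$activity[2], 0)                  # zero ligand -> zero
    expect_true(all(f$activity >= 0 & f$activity < 1))
    # monotone in the product: doubling K_h lowers activity
    f2 <- cci_activity(d, pair, A, K_h = 2)
    expect_lt(f2$activity[1], f$activity[1])
    expect_error(cci_activity(d, list(ligand = "nope", receptor = "R"), A),
                 "absent")
    expect_warning(cci_activity(d, list(ligand = "L", receptor = "R"),
                                A, K_h = 0.5) -> ok, NA)
})

test_that("permutation cutoff matches the enumerated pool on a 4-cell toy", {
    coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(8, 8))
    d <- spatial_dataset(cbind(L = c(5, 0, 1, 2), R = c(0, 4, 1, 3)), coords)
    A <- diffusion_transport(coords, cutoff = 2)
    pair <- list(ligand = "L", receptor = "R")
    perms <- lapply(seq_len(factorial(4)), function(i) NULL)
    pm <- as.matrix(expand.grid(rep(list(1:4), 4)))
    pm <- pm[apply(pm, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
    perms <- lapply(seq_len(nrow(pm)), function(i) pm[i, ])
    f <- permutation_cutoff(d, pair, A, alpha = 0.1, permutations = perms)
    # independent oracle: enumerate all 24 permutations explicitly
    L <- d$expression[, "L"] / max(d$expression[, "L"])
    R <- d$expression[, "R"] / max(d$expression[, "R"])
    pool <- unlist(lapply(perms, function(p) {
        Lt <- as.numeric(Matrix::crossprod(A$A, L[p]))
        x <- Lt * R[p]
        x / (0.5 + x)
    }))
    expect_equal(f$cutoff_value, quantile(pool, 0.9, names = FALSE))
    expect_equal(f$active, f$activity > f$cutoff_value)
})

test_that("constant expression yields no active cells under the exchangeable null", {
    coords <- grid_coords(6)
    d <- spatial_dataset(cbind(L = rep(2, 36), R = rep(3, 36)), coords)
    A <- diffusion_transport(coords, cutoff = 2)
    f <- permutation_cutoff(d, list(ligand = "L", receptor = "R"), A,
                            n_perm = 20, seed = 1)
    expect_equal(sum(f$active), 0L)
})

test_that("the active set is invariant to the Hill constant and to reruns", {
    fx <- make_cci_fixture()
    A <- diffusion_transport(fx$d$coords, cutoff = 3)
    pair <- list(ligand = "LigA", receptor = "RecA")
    sets <- lapply(c(0.25, 0.5, 2.0), function(k)
        permutation_cutoff(fx$d, pair, A, K_h = k, n_perm = 50, seed = 3)$active)
    expect_identical(sets[[1]], sets[[2]])
    expect_identical(sets[[2]], sets[[3]])
    again <- permutation_cutoff(fx$d, pair, A, K_h = 0.5, n_perm = 50, seed = 3)
    expect_identical(sets[[2]], again$active)
    # alpha = 1: the cutoff is the pool minimum-quantile, nothing exceeds it
    none <- permutation_cutoff(fx$d, pair, A, n_perm = 20, seed = 3, alpha = 1)
    expect_equal(sum(none$active), 0L)
})

test_that("interaction hotspots appear where ligand meets receptor and nowhere else", {
    fx <- make_cci_fixture()
    A <- diffusion_transport(fx$d$coords, cutoff = 3)
    pair <- list(ligand = "LigA", receptor = "RecA")
    f <- permutation_cutoff(fx$d, pair, A, n_perm = 100, seed = 4)
    hs <- cci_hotspots(fx$d, f, small_det_cfg())
    expect_gte(length(hs), 1L)
    cells <- unlist(lapply(hs, `[[`, "members"))
    # hotspot sits in the exposed receptor zone
    expect_gt(mean(cells %in% fx$receptor_zone), 0.9)
    # no hotspot at the far sender (no receptor there)
    expect_equal(length(intersect(cells, fx$far_sender)), 0L)
    # no active cells at all -> no hotspots
    f0 <- f; f0$active <- rep(FALSE, length(f0$active))
    expect_length(cci_hotspots(fx$d, f0, small_det_cfg()), 0L)
})
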