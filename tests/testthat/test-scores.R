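mk_hs <- function(gene, members) hierspot:::new_gene_hotspot(gene, members)
mk_ch2 <- function(id, members, gh, genes) {
    structure(list(id = id, members = members, gene_hotspots = gh,
                   genes = genes, membership_cutoff = 0.3),
              class = "coexpression_hotspot")
}

test_that("coherence counts constituent hotspots and max-normalizes", {
    hs <- list(mk_hs("a", c(2, 3)), mk_hs("b", c(3, 2)), mk_hs("c", c(3, 3)),
               mk_hs("d", c(3, 2)), mk_hs("orphan", c(1, 2)))
    # cell1: 0 hotspots, cell2: 2, cell3: 4 (orphan hotspot not in any CH)
    hs <- list(mk_hs("a", c(2, 3)), mk_hs("b", c(2, 3)), mk_hs("c", 3),
               mk_hs("d", 3), mk_hs("orphan", c(1, 2, 3)))
    chs <- list(mk_ch2(0L, c(2, 3), 1:4, c("a", "b", "c", "d")))
    f <- coherence_score(chs, hs, 3)
    expect_equal(f$score, c(0, 0.5, 1))
    expect_warning(z <- coherence_score(list(), hs, 3), "no coexpression")
    expect_equal(z$score, rep(0, 3))
})

test_that("uniqueness excludes genes spanning several coexpression hotspots", {
    hs <- list(mk_hs("shared", 1:2), mk_hs("shared", 5:6),
               mk_hs("own", 1:3), mk_hs("other", 5:6))
    chs <- list(mk_ch2(0L, 1:3, c(1L, 3L), c("shared", "own")),
                mk_ch2(1L, 5:6, c(2L, 4L), c("shared", "other")))
    u <- uniqueness_score(chs, hs, 6)
    co <- coherence_score(chs, hs, 6)
    # "shared" contributes nothing anywhere; cells 1-3 get "own" only
    expect_equal(u$score[1:3], c(1, 1, 1))
    expect_equal(u$score[4], 0)
    # uniqueness <= coherence before normalization: raw counts comparison
    raw_u <- u$score * max(c(tabulate(unlist(lapply(hs[c(3, 4)], `[[`, "members")), 6)))
    raw_c <- co$score * max(tabulate(unlist(lapply(hs, `[[`, "members")), 6))
    expect_true(all(raw_u <= raw_c + 1e-12))
})

test_that("similarity maps report the fraction of locally hot genes", {
    side <- 12
    d <- make_planted_dataset(side, list(
        A = list(x = c(2, 6), y = c(2, 6), genes = 4),
        B = list(x = c(8, 12), y = c(8, 12), genes = 4)), n_noise = 2, seed = 5)
    cfg <- small_det_cfg(5)
    hs <- compute_all_gene_hotspots(d, cfg)
    chs <- run_coexpression(d, cfg, coexpression_config(min_genes = 3, seed = 0))
    expect_gte(length(chs), 2L)
    chA <- chs[[which.max(vapply(chs, function(c) sum(grepl("^A", c$genes)), 1))]]
    f <- similarity_map(chA, d, target_hotspots = hs)
    expect_true(all(f$score >= 0 & f$score <= 1))
    inA <- region_cells(side, c(3, 5), c(3, 5))
    outB <- region_cells(side, c(9, 11), c(9, 11))
    expect_gt(mean(f$score[inA]), 0.9)       # its own region is fully hot
    expect_lt(mean(f$score[outB]), 0.3)      # the other program is not
    # a CH whose genes are absent errors; partially absent drops with warning
    ghost <- mk_ch2(9L, 1:3, integer(0), c("nope1", "nope2"))
    expect_error(similarity_map(ghost, d, target_hotspots = hs), "no genes")
    half <- mk_ch2(9L, 1:3, integer(0), c(chA$genes[1], "nope"))
    expect_warning(similarity_map(half, d, target_hotspots = hs), "absent")
})

test_that("similarity map works cross-sample by recomputing target hotspots", {
    dref <- make_planted_dataset(12, list(A = list(x = c(2, 7), y = c(2, 7),
                                                   genes = 4)), 2, seed = 6)
    dtar <- make_planted_dataset(12, list(A = list(x = c(6, 11), y = c(6, 11),
                                                   genes = 4)), 2, seed = 7)
    cfg <- small_det_cfg(5)
    chs <- run_coexpression(dref, cfg, coexpression_config(min_genes = 3, seed = 0))
    f <- similarity_map(chs[[1]], dtar, det_cfg = cfg)
    shifted <- region_cells(12, c(7, 10), c(7, 10))
    expect_gt(mean(f$score[shifted]), 0.8)
    # mean similarity over the reference structure's own cells transfers
    expect_gt(mean(f$score), 0)
})

test_that("self similarity map covers members at least at the membership cutoff", {
    d <- make_two_region_fixture(6, side = 16, seed = 8)
    cfg <- small_det_cfg()
    chs <- run_coexpression(d, cfg, coexpression_config(seed = 0))
    hs <- attr(chs, "hotspots")
    for (ch in chs) {
        f <- similarity_map(ch, d, target_hotspots = hs)
        expect_gte(mean(f$score[ch$members]), ch$membership_cutoff)
    }
})

test_that("greedy decomposition follows the match-score recursion", {
    n <- 40
    H1 <- mk_hs("g", 1:10)
    # CH covering H plus 2 extra spots: MS = 10 - 2 = 8
    chs <- list(mk_ch2(0L, c(1:10, 11, 12), integer(0), "x"))
    dec <- decompose_gene("g", list(H1), chs, n)
    expect_equal(dec$match_scores[1], 8)
    expect_equal(dec$selected, 0L)
    expect_equal(dec$residual, 0L)
    # disjoint CH: negative score, never selected
    far <- list(mk_ch2(0L, 21:30, integer(0), "x"))
    dec2 <- decompose_gene("g", list(H1), far, n)
    expect_length(dec2$selected, 0L)
    expect_equal(dec2$residual, 10L)
    # H == CH1 exactly: single-step termination
    dec3 <- decompose_gene("g", list(H1), list(mk_ch2(0L, 1:10, integer(0), "x")), n)
    expect_equal(dec3$selected, 0L)
    expect_equal(dec3$residual, 0L)
})

test_that("greedy decomposition reproduces an independent step-by-step trace", {
    n <- 30
    H <- list(mk_hs("g", 1:12))
    chs <- list(mk_ch2(0L, 1:6, integer(0), "a"),
                mk_ch2(1L, 7:12, integer(0), "b"),
                mk_ch2(2L, c(1:9, 13:14), integer(0), "c"))
    dec <- decompose_gene("g", H, chs, n)
    # independent oracle: recompute the greedy recursion with plain set
    # arithmetic (match score = |H int CH| - |CH \ H|)
    Hc <- 1:12
    avail <- chs
    sel <- integer(0); sc <- numeric(0)
    repeat {
        ms <- vapply(avail, function(c)
            length(intersect(Hc, c$members)) - length(setdiff(c$members, Hc)), 1)
        if (!length(ms) || max(ms) <= 0) break
        k <- which.max(ms)
        sel <- c(sel, avail[[k]]$id); sc <- c(sc, ms[k])
        Hc <- setdiff(Hc, avail[[k]]$members)
        avail <- avail[-k]
    }
    expect_equal(dec$selected, sel)          # here: CH2 first (MS 7 beats 6)
    expect_equal(dec$match_scores, sc)
    expect_equal(dec$residual, length(Hc))
    expect_true(all(dec$match_scores > 0))
    expect_lte(length(dec$selected), 3L)
})

test_that("pairwise CH similarity is high for twins and low for strangers", {
    side <- 14
    d <- make_planted_dataset(side, list(
        A = list(x = c(1, 6), y = c(1, 6), genes = 4),
        B = list(x = c(9, 14), y = c(9, 14), genes = 4)), 2, seed = 9)
    cfg <- small_det_cfg(5)
    chs <- run_coexpression(d, cfg, coexpression_config(min_genes = 3, seed = 0))
    hs <- attr(chs, "hotspots")
    res <- ch_similarity_matrix(chs, d, hs)
    S <- res$similarity
    expect_true(isSymmetric(S))
    expect_gt(min(diag(S)), 0.8)          # self similarity maximal-ish
    off <- S[upper.tri(S)]
    expect_lt(max(off), 0.2)              # disjoint programs barely related
    expect_setequal(res$order, seq_along(chs))
    # twins: duplicate one CH -> similarity ~ 1
    twin <- chs[[1]]; twin$id <- 99L
    S2 <- ch_similarity_matrix(list(chs[[1]], twin), d, hs)$similarity
    expect_gt(S2[1, 2], 0.9)
})
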