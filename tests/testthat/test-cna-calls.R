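test_that("replicate averaging, blacklisting and median-centering", {
    m1 <- matrix(c(0.9, 0.3, 1.4, 0.1, 0.2, 0.3), 3, 2,
                 dimnames = list(c("c1", "c2", "bad"), c("s1", "s2")))
    m2 <- matrix(c(1.1, 0.3, 1.4, NA, 0.2, 0.3), 3, 2,
                 dimnames = list(c("c1", "c2", "bad"), c("s1", "s2")))
    out <- preprocess_acgh(list(m1, m2), clone_blacklist = "bad")
    expect_false("bad" %in% rownames(out))
    # replicates {0.9, 1.1} average to 1.0 before centering
    raw <- (m1 + ifelse(is.na(m2), m1, m2)) / 2
    expect_equal(out["c1", "s1"] - out["c2", "s1"],
                 raw["c1", "s1"] - raw["c2", "s1"])
    expect_equal(unname(apply(out, 2, median, na.rm = TRUE)), c(0, 0))
    # a constant per-sample offset is removed entirely
    shifted <- preprocess_acgh(m1 + 0.3)
    expect_equal(shifted, preprocess_acgh(m1))
    # all-replicates-missing stays missing, no error
    m3 <- m1; m3["c2", "s2"] <- NA
    m4 <- m2; m4["c2", "s2"] <- NA
    expect_true(is.na(preprocess_acgh(list(m3, m4))["c2", "s2"]))
})

test_that("arc statistic handles degenerate and symmetric cases", {
    expect_equal(arc_statistic(rep(0.5, 10), 2, 7), 0)
    expect_equal(arc_statistic(c(0, 0, 0, 1, 1, 1), 3, 6), Inf)
    set.seed(42)
    p <- rnorm(10)
    # absolute value: exchanging the groups leaves the statistic unchanged
    expect_equal(arc_statistic(p, 0, 4), arc_statistic(p, 4, 10))
    expect_error(arc_statistic(p, 5, 5), "non-empty")
    expect_error(arc_statistic(p, 0, 10), "non-empty")
})

test_that("maximal arc search agrees with exhaustive enumeration", {
    set.seed(7)
    for (rep in 1:25) {
        n <- sample(8:14, 1)
        p <- rnorm(n) + rep(c(0, sample(c(0, 1.5), 1)),
                            c(n %/% 2, n - n %/% 2))
        got <- gctsig:::cbs_max_arc_cpp(p, 2L)
        want <- oracle_max_arc(p, 2)
        expect_equal(got$stat, unname(want["stat"]), tolerance = 1e-10)
        expect_equal(arc_boundaries(got$i, got$j, n),
                     arc_boundaries(want["i"], want["j"], n))
    }
})

test_that("constant profiles stay unsegmented and steps are found", {
    seg <- cbs_segment(rep(0.3, 25), seed = 1)
    expect_equal(nrow(seg), 1)
    expect_equal(seg$seg_mean, 0.3)
    expect_equal(seg$n_clones, 25)
    set.seed(5)
    p <- c(rnorm(15, 0, 0.1), rnorm(15, 1, 0.1))
    seg <- cbs_segment(p, alpha = 0.01, seed = 2)
    expect_gte(nrow(seg), 2)
    expect_true(any(abs(seg$end_index - 15) <= 1))
    # alpha -> 0 limit: a single segment regardless of structure
    seg0 <- cbs_segment(p, alpha = 1e-9, seed = 3)
    expect_equal(nrow(seg0), 1)
    expect_error(cbs_segment(p, n_perm = 50), "n_perm")
})

test_that("segment means conserve the profile mean", {
    set.seed(11)
    for (rep in 1:5) {
        p <- rnorm(40) + rep(rnorm(4, 0, 1), each = 10)
        seg <- cbs_segment(p, alpha = 0.05, n_perm = 200, seed = rep)
        expect_equal(sum(seg$seg_mean * seg$n_clones) / 40, mean(p))
        expect_equal(sum(seg$n_clones), 40)
        # segments partition the profile without overlap
        expect_equal(seg$start_index[1], 1)
        if (nrow(seg) > 1)
            expect_true(all(seg$start_index[-1] ==
                            head(seg$end_index, -1) + 1))
    }
})

test_that("lowering alpha never increases the segment count", {
    set.seed(13)
    p <- c(rnorm(20, 0, 0.3), rnorm(20, 0.8, 0.3), rnorm(20, -0.2, 0.3))
    alphas <- c(0.2, 0.05, 0.01, 0.001)
    counts <- vapply(alphas, function(a)
        nrow(cbs_segment(p, alpha = a, n_perm = 500, seed = 17)),
        numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("split probability on pure noise is close to alpha", {
    set.seed(19)
    alpha <- 0.05
    splits <- vapply(1:500, function(i)
        nrow(cbs_segment(rnorm(30), alpha = alpha, n_perm = 200,
                         seed = i)) > 1, logical(1))
    rate <- mean(splits)
    mc <- 3 * sqrt(alpha * (1 - alpha) / 500)
    expect_lte(rate, alpha + mc)
    expect_gte(rate, alpha / 4)  # permutation p-values are conservative
})

test_that("missing clones are carried through segmentation as missing calls", {
    tr <- tiny_truth(seed = 21, missing_rate = 0.1)
    cn <- simulate_copy_number(tr, 6, seed = 22)
    segs <- segment_cohort(cn$log_ratio, tr$clone_map, alpha = 0.01,
                           n_perm = 200, seed = 23)
    calls <- call_alterations(segs)
    expect_identical(is.na(calls), is.na(cn$log_ratio))
    # per-sample weighted segment means reproduce the non-missing mean
    df <- segs$segments
    for (s in colnames(cn$log_ratio)) {
        sub <- df[df$sample == s, ]
        expect_equal(sum(sub$seg_mean * sub$n_clones) / sum(sub$n_clones),
                     mean(cn$log_ratio[, s], na.rm = TRUE))
    }
})

test_that("alteration calls respect inclusive thresholds", {
    tr <- tiny_truth(seed = 25, cn_noise_sd = 0, missing_rate = 0)
    cn <- simulate_copy_number(tr, 4, seed = 26)
    segs <- segment_cohort(cn$log_ratio, tr$clone_map, alpha = 0.01,
                           n_perm = 200, seed = 27)
    m <- segs$seg_mean_matrix
    calls <- call_alterations(segs, gain_threshold = 0.2,
                              loss_threshold = -0.2)
    expect_true(all(calls[m >= 0.2] == "gain"))
    expect_true(all(calls[m > -0.2 & m < 0.2] == "normal"))
    # boundary inclusive: a segment mean exactly at threshold is a gain
    fake <- segs
    fake$seg_mean_matrix[] <- 0.2
    expect_true(all(call_alterations(fake) == "gain"))
    expect_error(call_alterations(segs, gain_threshold = -0.1,
                                  loss_threshold = -0.2), "threshold")
})

test_that("concordance counts identical non-missing calls", {
    a <- c("gain", "normal", "loss", NA, "normal")
    b <- c("gain", "loss", "loss", "gain", NA)
    expect_equal(concordance(a, a), 100.0)
    expect_equal(concordance(a, b), round(100 * 2 / 3, 1))
    expect_error(concordance(c(NA, "gain"), c("gain", NA)), "comparable")
})

test_that("concordance reproduces one-decimal reporting", {
    a <- rep("gain", 1000)
    b <- c(rep("gain", 927), rep("loss", 73))
    expect_equal(concordance(a, b), 92.7)
    expect_equal(concordance(c("g", "g"), c("g", "l")), 50.0)
})
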