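test_that("clone map layout is deterministic with strictly increasing positions", {
    cm <- build_clone_map(c(100, 100, 100), spacing_mb = 1)
    expect_equal(nrow(cm), 300)
    expect_equal(max(cm$position_mb), 100)
    expect_false(any(duplicated(cm$clone_id)))
    for (ch in unique(cm$chromosome))
        expect_true(all(diff(cm$position_mb[cm$chromosome == ch]) > 0))
    expect_identical(cm, build_clone_map(c(100, 100, 100), spacing_mb = 1))
    expect_error(build_clone_map(c(10), spacing_mb = 0), "positive")
    expect_error(build_clone_map(integer(0)), "chromosome")
})

test_that("region specs are validated and must lie on the clone map", {
    expect_error(region_specs(1, 10, 5, "gain", 0.5, 1), "start_mb")
    expect_error(region_specs(1, 5, 10, "gain", 0, 1), "prevalence")
    expect_error(
        synthetic_truth(clone_map = build_clone_map(c(20)),
                        regions = region_specs(1, 5, 50, "gain", 0.5, 1)),
        "outside")
})

test_that("same seed reproduces the cohort byte for byte", {
    a <- simulate_gct_cohort(n_train = 10, n_val = 8, n_normals = 3,
                             seed = 7)
    b <- simulate_gct_cohort(n_train = 10, n_val = 8, n_normals = 3,
                             seed = 7)
    expect_identical(a$train$log_ratio, b$train$log_ratio)
    expect_identical(a$train$records, b$train$records)
    expect_identical(a$val$expr, b$val$expr)
    expect_identical(a$val$batch_factors, b$val$batch_factors)
})

test_that("zero-noise copy number is recovered exactly by thresholding", {
    tr <- tiny_truth(seed = 3, cn_noise_sd = 0, missing_rate = 0)
    cn <- simulate_copy_number(tr, 20, seed = 11)
    in_reg <- tr$clone_map$chromosome == 1 &
        tr$clone_map$position_mb >= 5 & tr$clone_map$position_mb <= 15
    called_gain <- cn$log_ratio >= 0.2
    for (s in seq_len(20)) {
        expect_equal(unname(colSums(called_gain)[s] > 0),
                     unname(cn$carriers[1, s]))
        if (cn$carriers[1, s])
            expect_true(all(called_gain[in_reg, s]))
    }
})

test_that("carrier counts stay within the binomial 99% interval", {
    tr <- synthetic_truth(clone_map = build_clone_map(c(30)),
                          regions = region_specs(1, 5, 15, "gain", 0.3, 2),
                          seed = 5)
    cn <- simulate_copy_number(tr, 53, seed = 23)
    k <- sum(cn$carriers[1, ])
    bounds <- qbinom(c(0.005, 0.995), 53, 0.3)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
})

test_that("carrier marginal prevalence is preserved under correlation", {
    tr <- synthetic_truth(seed = 2)  # three default regions, overlap 0.85
    set.seed(99)
    counts <- rowSums(simulate_copy_number(tr, 4000)$carriers)
    prev <- counts / 4000
    expect_equal(unname(prev), tr$regions$prevalence, tolerance = 0.05)
})

test_that("noise-free dosage probes show the exact planted fold change", {
    tr <- tiny_truth(seed = 4, expr_noise_sd = 0, dosage_fold = 2)
    cn <- simulate_copy_number(tr, 30, seed = 8)
    ex <- simulate_expression(tr, cn$carriers, n_normals = 0, seed = 9)
    dp <- tr$dosage_probes[["R01"]]
    carr <- cn$carriers[1, ]
    skip_if(sum(carr) < 1 || sum(!carr) < 1)
    for (p in dp) {
        fold <- 2^(mean(ex$expr[p, carr]) - mean(ex$expr[p, !carr]))
        expect_equal(fold, 2, tolerance = 1e-12)
    }
    # a probe outside the region has identical group means by construction
    outside <- setdiff(rownames(ex$expr), unlist(tr$dosage_probes))[1]
    expect_equal(mean(ex$expr[outside, carr]),
                 mean(ex$expr[outside, !carr]), tolerance = 1e-12)
    expect_error(synthetic_truth(dosage_fold = 0.5), "dosage_fold")
})

test_that("infinite effect regions force every carrier to poor outcome", {
    tr <- synthetic_truth(clone_map = build_clone_map(c(30)),
                          regions = region_specs(1, 5, 15, "gain", 0.3, Inf),
                          seed = 6)
    cn <- simulate_copy_number(tr, 40, seed = 10)
    rec <- simulate_outcomes(cn$carriers, tr, baseline_poor_rate = 0.1,
                             seed = 12)
    lab <- derive_endpoint_labels(rec, "2yDFS")
    carr_ids <- colnames(cn$carriers)[cn$carriers[1, ]]
    expect_true(all(lab[carr_ids] == "poor"))
})

test_that("null effects give a poor rate near baseline for all patients", {
    tr <- synthetic_truth(clone_map = build_clone_map(c(30)),
                          regions = region_specs(1, 5, 15, "gain", 0.3, 0),
                          seed = 7)
    cn <- simulate_copy_number(tr, 600, seed = 13)
    rec <- simulate_outcomes(cn$carriers, tr, baseline_poor_rate = 0.2,
                             seed = 14)
    carr <- cn$carriers[1, rec$patient_id]
    expect_lt(abs(mean(rec$disease_event_flag[carr]) - 0.2), 0.07)
    expect_lt(abs(mean(rec$disease_event_flag[!carr]) - 0.2), 0.07)
    expect_identical(rec, simulate_outcomes(cn$carriers, tr,
                                            baseline_poor_rate = 0.2,
                                            seed = 14))
})

test_that("batch effect is multiplicative per gene and invertible", {
    m <- matrix(log2(c(100, 200, 400, 50, 80, 120)), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
    expect_equal(apply_batch_effect(m, c(1, 1)), m)
    shifted <- apply_batch_effect(m, c(2, 1))
    expect_equal(median(2^shifted["g1", ]), 2 * median(2^m["g1", ]))
    expect_equal(shifted["g2", ], m["g2", ])
    expect_error(apply_batch_effect(m, c(2, -1)), "positive")
    # median-match normalization restores the pre-batch medians exactly
    factors <- c(1.7, 0.4)
    pert <- apply_batch_effect(m, factors)
    back <- median_match_normalize(pert, m)
    expect_equal(apply(2^back, 1, median), apply(2^m, 1, median),
                 tolerance = 1e-12)
})
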