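make_records <- function(...) {
    defaults <- list(followup_months = 72, disease_event_flag = FALSE,
                     death_from_disease_flag = FALSE,
                     never_disease_free_flag = FALSE,
                     recurrence_months = NA_real_,
                     igcccg_risk = "good", batch = "train")
    rows <- list(...)
    do.call(rbind, lapply(seq_along(rows), function(i) {
        r <- utils::modifyList(defaults, rows[[i]])
        r$patient_id <- sprintf("p%02d", i)
        as.data.frame(r, stringsAsFactors = FALSE)
    }))
}

test_that("endpoint labels follow the clinical definitions", {
    rec <- make_records(
        list(followup_months = 36, disease_event_flag = TRUE,
             death_from_disease_flag = TRUE, recurrence_months = 10),
        list(followup_months = 72, disease_event_flag = TRUE,
             never_disease_free_flag = TRUE),
        list(followup_months = 40),
        list(followup_months = 20),
        list(followup_months = 90))
    l2 <- derive_endpoint_labels(rec, "2yDFS")
    l5 <- derive_endpoint_labels(rec, "5yDSS")
    # death of disease at 36 months: 5yDSS poor (and 2yDFS poor via recurrence)
    expect_equal(as.character(l5[["p01"]]), "poor")
    expect_equal(as.character(l2[["p01"]]), "poor")
    # never disease free but alive at 72 months: 2yDFS poor, 5yDSS good
    expect_equal(as.character(l2[["p02"]]), "poor")
    expect_equal(as.character(l5[["p02"]]), "good")
    # censored alive at 40 months: 5yDSS ineligible but 2yDFS good
    expect_equal(as.character(l5[["p03"]]), "ineligible")
    expect_equal(as.character(l2[["p03"]]), "good")
    # censored alive at 20 months: ineligible for both
    expect_equal(as.character(l2[["p04"]]), "ineligible")
    expect_equal(as.character(l5[["p05"]]), "good")
})

test_that("contradictory records are rejected", {
    rec <- make_records(list(death_from_disease_flag = TRUE,
                             disease_event_flag = FALSE))
    expect_error(derive_endpoint_labels(rec, "2yDFS"), "contradictory")
    rec2 <- make_records(list(followup_months = 10,
                              disease_event_flag = TRUE,
                              recurrence_months = 30))
    expect_error(derive_endpoint_labels(rec2, "5yDSS"), "recurrence")
})

test_that("fisher exact p matches full enumeration including worked value", {
    expect_equal(fisher_exact(c(3, 1, 1, 3)), 34 / 70, tolerance = 1e-12)
    expect_equal(fisher_exact(rbind(c(5, 5), c(20, 20))), 1.0)
    set.seed(31)
    for (rep in 1:100) {
        n <- sample(4:40, 1)
        cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
        if (any(cells[1] + cells[2] == 0, cells[3] + cells[4] == 0,
                cells[1] + cells[3] == 0, cells[2] + cells[4] == 0)) next
        expect_equal(fisher_exact(cells),
                     oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                     tolerance = 1e-9)
    }
    expect_warning(p <- fisher_exact(c(0, 0, 3, 4)), "zero margin")
    expect_equal(p, 1)
})

test_that("all-altered-poor tables give one-sided hypergeometric tails", {
    # 7 altered all poor: p equals the enumeration oracle for those margins
    expect_equal(fisher_exact(c(7, 0, 8, 38)), oracle_fisher_p(7, 0, 8, 38),
                 tolerance = 1e-12)
})

test_that("odds ratio arithmetic, infinity convention and intervals", {
    expect_equal(odds_ratio(c(1, 1, 1, 1))$or, 1.0)
    expect_equal(round(odds_ratio(c(20, 8, 6, 19))$or, 2), 7.92)
    inf <- odds_ratio(c(7, 0, 10, 20))
    expect_equal(inf$or, Inf)
    expect_true(is.na(inf$ci_low) && is.na(inf$ci_high))
    fin <- odds_ratio(c(0, 5, 8, 20))
    expect_equal(fin$or, 0)
    expect_false(is.na(fin$ci_low))  # Haldane correction keeps the CI finite
    w <- odds_ratio(c(20, 8, 6, 19))
    expect_lt(w$ci_low, w$or)
    expect_gt(w$ci_high, w$or)
    ex <- odds_ratio(c(20, 8, 6, 19), method = "exact")
    expect_lt(ex$ci_low, ex$ci_high)
})

test_that("clone association builds margins from eligible non-missing calls", {
    calls <- matrix("normal", 2, 10,
                    dimnames = list(c("c1", "c2"), sprintf("p%02d", 1:10)))
    calls["c1", 1:4] <- "gain"
    calls["c1", 9:10] <- NA
    labels <- factor(rep(c("poor", "good"), each = 5),
                     levels = c("good", "poor", "ineligible"))
    names(labels) <- sprintf("p%02d", 1:10)
    res <- clone_association(calls, labels, "c1", "gain")
    expect_equal(res$a + res$b + res$c + res$d, 8)  # 2 missing excluded
    expect_equal(res$a, 4)
    expect_message(
        out <- clone_association(calls, labels, "c2", "loss"), "skipped")
    expect_null(out)
})

test_that("region building follows the proximity rule", {
    cm <- data.frame(clone_id = c("a", "b", "c", "d"),
                     chromosome = c(4, 4, 9, 9),
                     position_mb = c(10, 20.4, 5, 16.4))
    assoc <- data.frame(
        clone_id = c("a", "b", "c", "d"), type = "loss",
        a = 5, b = 1, c = 3, d = 20, n_altered = 6,
        p_value = c(0.01, 0.02, 0.03, 0.04),
        odds_ratio = 5, ci_low = 1, ci_high = 20,
        chromosome = c(4, 4, 9, 9), position_mb = c(10, 20.4, 5, 16.4),
        stringsAsFactors = FALSE)
    reg <- build_regions(assoc, cm, max_gap_mb = 11.5)
    # 10.4 and 11.4 Mb gaps merge under the 11.5 Mb cutoff
    expect_equal(nrow(reg), 2)
    expect_equal(reg$n_clones, c(2, 2))
    # 12.0 Mb apart: two regions
    assoc2 <- assoc
    assoc2$position_mb[2] <- 22.0
    cm2 <- cm; cm2$position_mb[2] <- 22.0
    reg2 <- build_regions(assoc2, cm2, max_gap_mb = 11.5)
    expect_equal(sum(reg2$chromosome == 4), 2)
    expect_true(all(reg2$single_clone[reg2$chromosome == 4]))
    # gain and loss clones never merge
    assoc3 <- assoc
    assoc3$type <- c("gain", "loss", "loss", "loss")
    reg3 <- build_regions(assoc3[order(assoc3$chromosome,
                                       assoc3$position_mb, assoc3$type), ],
                          cm)
    expect_equal(nrow(reg3[reg3$chromosome == 4, ]), 2)
    expect_setequal(reg3$type[reg3$chromosome == 4], c("gain", "loss"))
})

test_that("region merging is monotone in the gap cutoff", {
    set.seed(37)
    pos <- sort(runif(30, 0, 150))
    cm <- data.frame(clone_id = sprintf("c%02d", 1:30), chromosome = 1,
                     position_mb = pos)
    assoc <- data.frame(clone_id = cm$clone_id, type = "gain",
                        a = 4, b = 2, c = 5, d = 30, n_altered = 6,
                        p_value = runif(30, 0, 0.2), odds_ratio = 3,
                        ci_low = 1, ci_high = 9, chromosome = 1,
                        position_mb = pos, stringsAsFactors = FALSE)
    counts <- vapply(c(2, 5, 10, 20, 50), function(g)
        nrow(build_regions(assoc, cm, max_gap_mb = g)), numeric(1))
    expect_true(all(diff(counts) <= 0))
    # same-type regions never overlap
    reg <- build_regions(assoc, cm, max_gap_mb = 10)
    if (nrow(reg) > 1)
        expect_true(all(reg$start_mb[-1] > head(reg$end_mb, -1)))
    # unsorted input is rejected
    expect_error(build_regions(assoc[c(2, 1, 3:30), ], cm), "sorted")
})

test_that("representative clone carries minimum p-value into the region", {
    cm <- data.frame(clone_id = c("a", "b"), chromosome = 1,
                     position_mb = c(1, 2))
    assoc <- data.frame(clone_id = c("a", "b"), type = "gain",
                        a = c(5, 7), b = c(3, 1), c = 4, d = 30,
                        n_altered = c(8, 8),
                        p_value = c(0.04, 0.001), odds_ratio = c(2, 10),
                        ci_low = 1, ci_high = 30, chromosome = 1,
                        position_mb = c(1, 2), stringsAsFactors = FALSE)
    reg <- build_regions(assoc, cm)
    expect_equal(reg$p_value, 0.001)
    expect_equal(reg$odds_ratio, 10)
})

test_that("gap statistics pool within-region clone gaps", {
    cm <- data.frame(clone_id = c("a", "b", "c", "d"), chromosome = 1,
                     position_mb = c(1, 1.5, 2.4, 4.6))
    reg <- data.frame(clone_ids = "a,b,c,d", stringsAsFactors = FALSE)
    gs <- region_gap_stats(reg, cm)
    expect_equal(gs$median_gap_mb, 0.9)
    expect_equal(gs$mean_gap_mb, 1.2)
    reg1 <- data.frame(clone_ids = "a,b", stringsAsFactors = FALSE)
    gs1 <- region_gap_stats(reg1, cm)
    expect_equal(gs1$median_gap_mb, gs1$mean_gap_mb)
    expect_error(region_gap_stats(
        data.frame(clone_ids = "a", stringsAsFactors = FALSE), cm),
        "two clones")
})

test_that("region table prints INF/N-A cells and keeps protective regions", {
    reg <- structure(data.frame(
        chromosome = c(9, 12), start_mb = c(72.7, 82.3),
        end_mb = c(120.8, 83.6), type = c("gain", "gain"),
        n_clones = c(5, 2), clone_ids = c("x,y", "u,v"),
        n_altered = c(7, 14), p_value = c(0.017, 0.041),
        odds_ratio = c(Inf, 0.18), ci_low = c(NA, 0.04),
        ci_high = c(NA, 0.80), single_clone = FALSE,
        stringsAsFactors = FALSE), class = c("genomic_regions", "data.frame"))
    tab <- region_table(reg)
    expect_equal(tab$OR, c("INF", "0.18"))
    expect_equal(tab$CI_95[1], "N/A")
    expect_equal(tab$CI_95[2], "0.04-0.80")
    path <- tempfile(fileext = ".tsv")
    region_table(reg[0, ], path)
    expect_equal(length(readLines(path)), 1)  # header-only
})
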