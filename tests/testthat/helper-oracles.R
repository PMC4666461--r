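# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (enumeration, closed forms)
# and never call the package code paths they check.

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(x) dhyper(x, c1, r1 + r2 - c1, r1),
                    numeric(1))
    pobs <- dhyper(a, c1, r1 + r2 - c1, r1)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Exhaustive search for the max arc statistic, via the exported
# arc_statistic(), with both group sizes >= min_width.
oracle_max_arc <- function(profile, min_width = 2) {
    n <- length(profile)
    best <- c(i = -1, j = -1, stat = -1)
    for (i in 0:(n - min_width)) {
        for (j in (i + min_width):min(n, i + n - min_width)) {
            s <- arc_statistic(profile, i, j)
            if (s > best["stat"]) best <- c(i = i, j = j, stat = s)
        }
    }
    best
}

# The segmentation boundaries an arc (i, j] induces on a profile of length
# n. An edge arc and its complement describe the same split, so comparisons
# go through this normalization.
arc_boundaries <- function(i, j, n) sort(setdiff(c(i, j), c(0, n)))

# SAM oracle for tiny two-group designs: recomputes scatters, the
# median-scatter fudge factor, d-statistics, and FDR estimates over the
# full enumeration of label assignments.
oracle_sam <- function(x, altered) {
    two_group <- function(lab) {
        n1 <- sum(lab); n2 <- sum(!lab)
        m1 <- apply(x[, lab, drop = FALSE], 1, mean)
        m2 <- apply(x[, !lab, drop = FALSE], 1, mean)
        ss <- apply((x[, lab, drop = FALSE] - m1)^2, 1, sum) +
            apply((x[, !lab, drop = FALSE] - m2)^2, 1, sum)
        list(num = m1 - m2,
             s = sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2)))
    }
    obs <- two_group(altered)
    s0 <- median(obs$s)
    d <- obs$num / (obs$s + s0)
    sets <- combn(ncol(x), sum(altered), simplify = FALSE)
    null_d <- lapply(sets, function(idx) {
        lab <- seq_len(ncol(x)) %in% idx
        p <- two_group(lab)
        abs(p$num / (p$s + s0))
    })
    thr <- sort(unique(abs(d)))
    counts <- function(t) vapply(null_d, function(v)
        sum(v >= t - 1e-12), numeric(1))
    fdr_mean <- vapply(thr, function(t) {
        n_obs <- sum(abs(d) >= t - 1e-12)
        min(1, mean(counts(t)) / max(1, n_obs))
    }, numeric(1))
    fdr_median <- vapply(thr, function(t) {
        n_obs <- sum(abs(d) >= t - 1e-12)
        min(1, median(counts(t)) / max(1, n_obs))
    }, numeric(1))
    list(d = d, s0 = s0, thresholds = thr, fdr = fdr_mean,
         fdr_median = fdr_median)
}

# Log-rank chi-square by direct O-E/V tabulation over event times.
oracle_logrank_chisq <- function(time, event, group) {
    g1 <- group == sort(unique(group))[1]
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        at <- time >= t
        n <- sum(at); n1 <- sum(at & g1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

# Plain nearest-centroid decision with the NSC standardization (the
# delta = 0 limit), recomputed from scratch.
oracle_nearest_centroid <- function(x, labels, newx, priors) {
    labels <- as.factor(labels)
    classes <- levels(labels)
    n <- ncol(x); K <- length(classes)
    cents <- sapply(classes, function(k)
        apply(x[, labels == k, drop = FALSE], 1, mean))
    if (nrow(x) == 1) cents <- matrix(cents, 1, K,
                                      dimnames = list(rownames(x), classes))
    ss <- rep(0, nrow(x))
    for (k in classes)
        ss <- ss + apply((x[, labels == k, drop = FALSE] - cents[, k])^2,
                         1, sum)
    s <- sqrt(ss / (n - K))
    s0 <- median(s)
    apply(newx, 2, function(v) {
        sc <- vapply(classes, function(k)
            sum(((v - cents[, k]) / (s + s0))^2) - 2 * log(priors[k]),
            numeric(1))
        classes[which.min(sc)]
    })
}

# Small cohort settings used where full study-scale runs are unnecessary.
tiny_truth <- function(seed = 1, ...) {
    synthetic_truth(clone_map = build_clone_map(c(30, 30)),
                    regions = region_specs(1, 5, 15, "gain", 0.3, 2),
                    n_probes = 40, n_dosage_per_region = 5,
                    seed = seed, ...)
}
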