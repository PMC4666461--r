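#' Preprocess aCGH ratio data
#'
#' Averages replicate spots per clone, drops blacklisted clones (polymorphic,
#' unmapped or absent on the array) and median-centers every sample on the
#' log2 scale. Clones with no usable measurement in any replicate are kept
#' with an explicit missing flag (`NA`), never imputed.
#'
#' @param replicates A single log2-ratio matrix (clones x samples) or a list
#'   of replicate matrices sharing dimnames.
#' @param clone_blacklist Character vector of clone ids to remove.
#' @return A clones x samples log2-ratio matrix with per-sample median 0.
#' @examples
#' m <- matrix(c(0.9, 1.1), 1, 2, dimnames = list("c1", c("s1", "s2")))
#' @export
preprocess_acgh <- function(replicates, clone_blacklist = character()) {
    if (is.matrix(replicates)) replicates <- list(replicates)
    if (!length(replicates)) stop("no replicate matrices", call. = FALSE)
    first <- replicates[[1]]
    stop_if_not_matrix(first, "replicate matrix")
    for (m in replicates[-1]) {
        stop_if_not_matrix(m, "replicate matrix")
        if (!identical(dimnames(m), dimnames(first)))
            stop("replicates must share clone and sample ids", call. = FALSE)
    }
    arr <- array(unlist(replicates),
                 dim = c(dim(first), length(replicates)))
    avg <- apply(arr, c(1, 2), function(v) {
        v <- v[!is.na(v)]
        if (length(v)) mean(v) else NA_real_
    })
    dimnames(avg) <- dimnames(first)
    avg <- avg[!rownames(avg) %in% clone_blacklist, , drop = FALSE]
    med <- apply(avg, 2, median, na.rm = TRUE)
    sweep(avg, 2, med, "-")
}

#' Arc statistic for circular binary segmentation
#'
#' The two-sample pooled-variance t-like statistic comparing the mean of the
#' arc `(i, j]` (positions `i+1` to `j`) against the rest of the profile,
#' returned as an absolute value. When the pooled within-group variance is
#' zero the statistic is defined as `+Inf` if the group means differ and `0`
#' if they are equal.
#'
#' @param profile Numeric log2-ratio profile (no missing values).
#' @param i,j Arc bounds, `0 <= i < j <= length(profile)`, with both the arc
#'   and its complement non-empty.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
arc_statistic <- function(profile, i, j) {
    n <- length(profile)
    if (anyNA(profile)) stop("profile must not contain NA", call. = FALSE)
    if (i < 0 || j > n || i >= j || (j - i) >= n)
        stop("need 0 <= i < j <= n with both groups non-empty", call. = FALSE)
    arc <- profile[(i + 1):j]
    rest <- profile[-((i + 1):j)]
    m1 <- mean(arc); m2 <- mean(rest)
    ss <- sum((arc - m1)^2) + sum((rest - m2)^2)
    tol <- 1e-12 * (1 + sum(profile^2))
    if (ss <= tol)
        return(if (abs(m1 - m2) <= sqrt(tol)) 0 else Inf)
    sp2 <- ss / (n - 2)
    abs(m1 - m2) / sqrt(sp2 * (1 / length(arc) + 1 / length(rest)))
}

#' Segment one profile by circular binary segmentation
#'
#' Recursively finds the arc maximizing the arc statistic, assesses it by a
#' permutation test (add-one estimator `(r + 1) / (B + 1)`), splits when the
#' p-value is below `alpha` and recurses on the pieces. Adjacent segments
#' whose means agree to within 1e-9 are merged. Each recursion node draws its
#' permutations from a seed derived deterministically from the node's bounds,
#' so segmentations are reproducible and nested decisions do not interact.
#'
#' @param profile Numeric log2-ratio profile without missing values.
#' @param alpha Split significance level.
#' @param n_perm Permutations per test (>= 100).
#' @param min_width Minimum number of clones on each side of a tested split.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `start_index`, `end_index`,
#'   `n_clones`, `seg_mean`; indices refer to positions in `profile`.
#' @export
cbs_segment <- function(profile, alpha = 0.01, n_perm = 1000L,
                        min_width = 2L, seed = NULL) {
    if (anyNA(profile)) stop("remove missing values first", call. = FALSE)
    n <- length(profile)
    if (n < 1) stop("empty profile", call. = FALSE)
    if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
    seed_base <- with_seed(seed, sample.int(2147483629L, 1))
    stop_count <- ceiling(alpha * (n_perm + 1))
    segs <- list()
    stack <- list(c(1L, n))
    while (length(stack)) {
        node <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        lo <- node[1]; hi <- node[2]
        m <- hi - lo + 1L
        split <- NULL
        if (m >= 2L * min_width && alpha > 0) {
            piece <- profile[lo:hi]
            best <- cbs_max_arc_cpp(piece, min_width)
            if (best$stat >= 0) {
                p <- with_seed(node_seed(seed_base, lo, hi), {
                    res <- cbs_perm_count_cpp(piece, best$stat, n_perm,
                                              min_width, stop_count)
                    (res$count + 1) / (res$n_done + 1)
                })
                if (p < alpha) split <- c(best$i, best$j)
            }
        }
        if (is.null(split)) {
            segs[[length(segs) + 1L]] <- c(lo, hi)
        } else {
            i <- split[1]; j <- split[2]
            # change-points after positions lo+i-1 and lo+j-1 (0-based arc)
            pieces <- list()
            if (i > 0) pieces[[length(pieces) + 1L]] <- c(lo, lo + i - 1L)
            pieces[[length(pieces) + 1L]] <- c(lo + i, lo + j - 1L)
            if (j < m) pieces[[length(pieces) + 1L]] <- c(lo + j, hi)
            for (pc in rev(pieces)) stack[[length(stack) + 1L]] <- pc
        }
    }
    segs <- segs[order(vapply(segs, `[`, integer(1), 1))]
    out <- data.frame(
        start_index = vapply(segs, `[`, integer(1), 1),
        end_index = vapply(segs, `[`, integer(1), 2)
    )
    out$n_clones <- out$end_index - out$start_index + 1L
    out$seg_mean <- vapply(seq_len(nrow(out)), function(k)
        mean(profile[out$start_index[k]:out$end_index[k]]), numeric(1))
    # merge adjacent segments with numerically identical means
    k <- 1L
    while (k < nrow(out)) {
        if (abs(out$seg_mean[k] - out$seg_mean[k + 1]) < 1e-9) {
            out$end_index[k] <- out$end_index[k + 1]
            out <- out[-(k + 1), , drop = FALSE]
            out$n_clones[k] <- out$end_index[k] - out$start_index[k] + 1L
            out$seg_mean[k] <- mean(profile[out$start_index[k]:out$end_index[k]])
        } else k <- k + 1L
    }
    rownames(out) <- NULL
    out
}

#' Segment every sample of a copy-number matrix
#'
#' Applies [cbs_segment()] per sample and chromosome. Missing clones are
#' removed before segmentation and re-inserted as missing calls afterwards.
#'
#' @param log_ratio Clones x samples log2-ratio matrix (`NA` = missing),
#'   rows ordered as in `clone_map`.
#' @param clone_map Clone map `data.frame` (`clone_id`, `chromosome`,
#'   `position_mb`).
#' @param alpha,n_perm,min_width,seed Passed to [cbs_segment()].
#' @return An object of class `segment_set`: list with `segments` (a
#'   SEG-style `data.frame`: sample, chromosome, start_mb, end_mb, n_clones,
#'   seg_mean) and `seg_mean_matrix` (clones x samples segment means, `NA`
#'   where the input was missing).
#' @export
segment_cohort <- function(log_ratio, clone_map, alpha = 0.01,
                           n_perm = 1000L, min_width = 2L, seed = NULL) {
    stop_if_not_matrix(log_ratio, "log_ratio")
    if (!identical(rownames(log_ratio), clone_map$clone_id))
        stop("log_ratio rows must match clone_map order", call. = FALSE)
    seed_base <- with_seed(seed, sample.int(2147483629L, 1))
    seg_mat <- log_ratio * NA_real_
    rows <- list()
    chroms <- unique(clone_map$chromosome)
    for (s in seq_len(ncol(log_ratio))) {
        for (ch in chroms) {
            idx <- which(clone_map$chromosome == ch)
            prof <- log_ratio[idx, s]
            keep <- which(!is.na(prof))
            if (!length(keep)) next
            segs <- cbs_segment(prof[keep], alpha, n_perm, min_width,
                                seed = node_seed(seed_base, s, ch))
            for (k in seq_len(nrow(segs))) {
                clones <- idx[keep[segs$start_index[k]:segs$end_index[k]]]
                seg_mat[clones, s] <- segs$seg_mean[k]
                rows[[length(rows) + 1L]] <- data.frame(
                    sample = colnames(log_ratio)[s],
                    chromosome = ch,
                    start_mb = clone_map$position_mb[clones[1]],
                    end_mb = clone_map$position_mb[clones[length(clones)]],
                    n_clones = length(clones),
                    seg_mean = segs$seg_mean[k],
                    stringsAsFactors = FALSE
                )
            }
        }
    }
    structure(list(segments = do.call(rbind, rows),
                   seg_mean_matrix = seg_mat,
                   clone_map = clone_map),
              class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
    cat("CBS segmentation:", nrow(x$segments), "segments over",
        ncol(x$seg_mean_matrix), "samples\n")
    invisible(x)
}

#' Call per-clone gains and losses from segment means
#'
#' Thresholds are inclusive: a segment mean equal to `gain_threshold` is
#' called a gain, equal to `loss_threshold` a loss.
#'
#' @param segments A `segment_set` from [segment_cohort()].
#' @param gain_threshold,loss_threshold Log2 thresholds,
#'   `gain_threshold > 0 > loss_threshold`.
#' @return A clones x samples character matrix with entries `"gain"`,
#'   `"normal"`, `"loss"` or `NA` (missing input).
#' @export
call_alterations <- function(segments, gain_threshold = 0.2,
                             loss_threshold = -0.2) {
    stopifnot(inherits(segments, "segment_set"))
    if (!(gain_threshold > 0 && loss_threshold < 0))
        stop("need gain_threshold > 0 > loss_threshold", call. = FALSE)
    m <- segments$seg_mean_matrix
    calls <- ifelse(m >= gain_threshold, "gain",
             ifelse(m <= loss_threshold, "loss", "normal"))
    calls
}

#' Concordance between two call vectors
#'
#' Percent of positions with identical call among positions where both
#' inputs are non-missing, reported to one decimal (the convention used for
#' cross-platform call comparisons).
#'
#' @param calls_a,calls_b Character vectors or matrices over a common
#'   clone/bin index.
#' @return Percent agreement, one decimal.
#' @export
concordance <- function(calls_a, calls_b) {
    a <- as.vector(calls_a); b <- as.vector(calls_b)
    if (length(a) != length(b))
        stop("call vectors must have equal length", call. = FALSE)
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) stop("no comparable positions", call. = FALSE)
    round(100 * sum(a[ok] == b[ok]) / sum(ok), 1)
}

#' Write segments in SEG format
#'
#' Standard tab-delimited segment table: sample, chromosome, start, end
#' (bp), number of markers, segment mean.
#'
#' @param segments A `segment_set`.
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
    stopifnot(inherits(segments, "segment_set"))
    df <- segments$segments
    out <- data.frame(
        ID = df$sample,
        chrom = df$chromosome,
        loc.start = as.integer(round(df$start_mb * 1e6)),
        loc.end = as.integer(round(df$end_mb * 1e6)),
        num.mark = df$n_clones,
        seg.mean = round(df$seg_mean, 4)
    )
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
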