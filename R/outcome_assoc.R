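#' Derive endpoint labels from outcome records
#'
#' Two endpoints are supported. Two-year disease-free survival (`"2yDFS"`):
#' poor if the patient was never disease free, recurred within 24 months, or
#' died of disease within 24 months; good if disease free at 24 months;
#' ineligible if censored earlier. Five-year disease-specific survival
#' (`"5yDSS"`): poor if the patient died of disease within 60 months; good if
#' alive at 60 months (or died of disease later); ineligible if censored
#' alive before 60 months.
#'
#' @param records Outcome-record `data.frame` (see [simulate_outcomes()] for
#'   the column contract).
#' @param endpoint `"2yDFS"` or `"5yDSS"`.
#' @return A named factor with levels good/poor/ineligible and attributes
#'   `endpoint`; class `endpoint_labels`.
#' @export
derive_endpoint_labels <- function(records, endpoint = c("2yDFS", "5yDSS")) {
    endpoint <- match.arg(endpoint)
    req <- c("patient_id", "followup_months", "death_from_disease_flag",
             "never_disease_free_flag", "disease_event_flag")
    if (!all(req %in% names(records)))
        stop("records lack required fields: ",
             paste(setdiff(req, names(records)), collapse = ", "),
             call. = FALSE)
    if (any(records$followup_months < 0, na.rm = TRUE))
        stop("negative follow-up months", call. = FALSE)
    bad <- records$death_from_disease_flag & !records$disease_event_flag
    if (any(bad))
        stop("contradictory flags: disease death without any disease event (",
             paste(records$patient_id[bad], collapse = ", "), ")",
             call. = FALSE)
    rec_m <- if ("recurrence_months" %in% names(records))
        records$recurrence_months else rep(NA_real_, nrow(records))
    late <- !is.na(rec_m) & rec_m > records$followup_months
    if (any(late))
        stop("recurrence after end of follow-up for ",
             paste(records$patient_id[late], collapse = ", "), call. = FALSE)
    if (endpoint == "2yDFS") {
        poor <- records$never_disease_free_flag |
            (!is.na(rec_m) & rec_m <= 24) |
            (records$death_from_disease_flag & records$followup_months <= 24)
        lab <- ifelse(poor, "poor",
               ifelse(records$followup_months >= 24, "good", "ineligible"))
    } else {
        poor <- records$death_from_disease_flag &
            records$followup_months <= 60
        lab <- ifelse(poor, "poor",
               ifelse(records$followup_months >= 60, "good", "ineligible"))
    }
    out <- factor(lab, levels = c("good", "poor", "ineligible"))
    names(out) <- records$patient_id
    structure(out, endpoint = endpoint, class = c("endpoint_labels", "factor"))
}

as_table_2x2 <- function(table) {
    if (is.matrix(table)) {
        stopifnot(all(dim(table) == 2))
        c(a = table[1, 1], b = table[1, 2], c = table[2, 1], d = table[2, 2])
    } else {
        stopifnot(length(table) == 4)
        setNames(as.numeric(table), c("a", "b", "c", "d"))
    }
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Cells follow the altered-by-outcome layout: `a` altered & poor, `b`
#' altered & good, `c` not-altered & poor, `d` not-altered & good. The
#' p-value sums hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed one. A zero margin
#' gives p = 1 with a warning (no information about association).
#'
#' @param table 2x2 matrix `rbind(c(a, b), c(c, d))` or a length-4 vector
#'   `(a, b, c, d)`.
#' @return The two-sided exact p-value.
#' @examples
#' fisher_exact(c(3, 1, 1, 3))  # 34/70
#' @export
fisher_exact <- function(table) {
    x <- as_table_2x2(table)
    if (any(x < 0)) stop("negative cell counts", call. = FALSE)
    m <- matrix(x, 2, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        warning("zero margin: p-value set to 1", call. = FALSE)
        return(1)
    }
    fisher.test(m)$p.value
}

#' Sample odds ratio with confidence interval
#'
#' The sample odds ratio `ad / (bc)`. When `b = 0` or `c = 0` the odds ratio
#' is infinite and the confidence interval is reported absent (`NA`), the
#' convention used for regions whose carriers all had poor outcome. For
#' finite odds ratios the default interval is the Woolf log interval, with
#' the Haldane-Anscombe 0.5 continuity correction applied when any cell is
#' zero; `method = "exact"` returns the exact conditional interval instead.
#'
#' @param table 2x2 matrix or `(a, b, c, d)` vector (see [fisher_exact()]).
#' @param method `"woolf"` (default) or `"exact"`.
#' @param conf_level Confidence level.
#' @return List with elements `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(table, method = c("woolf", "exact"),
                       conf_level = 0.95) {
    method <- match.arg(method)
    x <- as_table_2x2(table)
    a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
    if (b == 0 || c == 0)
        return(list(or = Inf, ci_low = NA_real_, ci_high = NA_real_))
    or <- (a * d) / (b * c)
    if (method == "exact") {
        ft <- fisher.test(matrix(x, 2, 2, byrow = TRUE),
                          conf.level = conf_level)
        return(list(or = unname(or), ci_low = ft$conf.int[1],
                    ci_high = ft$conf.int[2]))
    }
    y <- x
    if (any(x == 0)) y <- x + 0.5
    se <- sqrt(sum(1 / y))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lor <- log((y["a"] * y["d"]) / (y["b"] * y["c"]))
    list(or = unname(or),
         ci_low = unname(exp(lor - z * se)),
         ci_high = unname(exp(lor + z * se)))
}

#' Test one clone's alteration status against outcome
#'
#' Builds the 2x2 table over eligible patients with a non-missing call at
#' the clone (missing calls shrink the margins) and applies the exact test.
#' Clones with no altered patient are skipped with a message.
#'
#' @param calls Clones x samples call matrix from [call_alterations()].
#' @param labels [derive_endpoint_labels()] output (names matching sample
#'   ids).
#' @param clone_id Clone to test.
#' @param alteration_type `"gain"` or `"loss"`.
#' @return A one-row `data.frame` (clone, type, a, b, c, d, p_value,
#'   odds_ratio, ci_low, ci_high) or `NULL` when skipped.
#' @export
clone_association <- function(calls, labels, clone_id,
                              alteration_type = c("gain", "loss")) {
    alteration_type <- match.arg(alteration_type)
    if (!clone_id %in% rownames(calls))
        stop("unknown clone: ", clone_id, call. = FALSE)
    common <- intersect(colnames(calls), names(labels))
    lab <- labels[common]
    cl <- calls[clone_id, common]
    use <- !is.na(cl) & lab %in% c("good", "poor")
    cl <- cl[use]; lab <- factor(lab[use], c("good", "poor"))
    altered <- cl == alteration_type
    if (!any(altered)) {
        message("clone ", clone_id, ": no patients with ", alteration_type,
                "; skipped")
        return(NULL)
    }
    a <- sum(altered & lab == "poor")
    b <- sum(altered & lab == "good")
    cc <- sum(!altered & lab == "poor")
    d <- sum(!altered & lab == "good")
    p <- suppressWarnings(fisher_exact(c(a, b, cc, d)))
    or <- odds_ratio(c(a, b, cc, d))
    data.frame(clone_id = clone_id, type = alteration_type,
               a = a, b = b, c = cc, d = d,
               n_altered = a + b, p_value = p,
               odds_ratio = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               stringsAsFactors = FALSE)
}

#' Scan every clone for outcome association
#'
#' Runs [clone_association()] for each clone and each alteration type that
#' occurs at it (gain and loss tested independently when both occur).
#'
#' @param calls Call matrix.
#' @param labels Endpoint labels.
#' @param clone_map Clone map (gives genomic order).
#' @return A `data.frame` of clone associations sorted by genomic position,
#'   with `chromosome` and `position_mb` attached.
#' @export
associate_clones <- function(calls, labels, clone_map) {
    rows <- list()
    for (k in seq_len(nrow(clone_map))) {
        cid <- clone_map$clone_id[k]
        if (!cid %in% rownames(calls)) next
        present <- unique(calls[cid, !is.na(calls[cid, ])])
        for (ty in intersect(c("gain", "loss"), present)) {
            res <- suppressMessages(
                clone_association(calls, labels, cid, ty))
            if (!is.null(res)) {
                res$chromosome <- clone_map$chromosome[k]
                res$position_mb <- clone_map$position_mb[k]
                rows[[length(rows) + 1L]] <- res
            }
        }
    }
    if (!length(rows))
        return(data.frame(clone_id = character(), type = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), n_altered = integer(),
                          p_value = numeric(), odds_ratio = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          chromosome = integer(), position_mb = numeric()))
    out <- do.call(rbind, rows)
    out[order(out$chromosome, out$position_mb, out$type), , drop = FALSE]
}

#' Aggregate significant clones into genomic regions
#'
#' Chains significant clones (p < `alpha`) of the same alteration type on
#' the same chromosome while consecutive gaps stay within `max_gap_mb`
#' (default 11.5 Mb, a conservative cutoff absorbing missing clones and
#' centromeric gaps). Region bounds are the first and last clone positions;
#' the region-level p-value, odds ratio and altered-patient count are taken
#' from the minimum-p clone (ties broken by genomic position).
#'
#' @param assoc Clone associations from [associate_clones()] (must be
#'   position-sorted).
#' @param clone_map Clone map.
#' @param alpha Clone significance threshold.
#' @param max_gap_mb Maximum gap between consecutive significant clones.
#' @param min_clones Regions with fewer clones are dropped.
#' @return A `data.frame` of regions (class `genomic_regions`): chromosome,
#'   start_mb, end_mb, type, n_clones, clone_ids (comma separated),
#'   n_altered, p_value, odds_ratio, ci_low, ci_high, single_clone.
#' @export
build_regions <- function(assoc, clone_map, alpha = 0.05,
                          max_gap_mb = 11.5, min_clones = 1L) {
    if (nrow(assoc) > 1) {
        o <- order(assoc$chromosome, assoc$position_mb, assoc$type)
        if (!identical(o, seq_len(nrow(assoc))))
            stop("assoc must be sorted by genomic position", call. = FALSE)
    }
    sig <- assoc[assoc$p_value < alpha, , drop = FALSE]
    regions <- list()
    for (ty in unique(sig$type)) {
        for (ch in unique(sig$chromosome[sig$type == ty])) {
            sub <- sig[sig$type == ty & sig$chromosome == ch, , drop = FALSE]
            sub <- sub[order(sub$position_mb), , drop = FALSE]
            grp <- cumsum(c(1, diff(sub$position_mb) > max_gap_mb))
            for (g in unique(grp)) {
                blk <- sub[grp == g, , drop = FALSE]
                if (nrow(blk) < min_clones) next
                rep_row <- blk[order(blk$p_value, blk$position_mb), ][1, ]
                regions[[length(regions) + 1L]] <- data.frame(
                    chromosome = ch,
                    start_mb = min(blk$position_mb),
                    end_mb = max(blk$position_mb),
                    type = ty,
                    n_clones = nrow(blk),
                    clone_ids = paste(blk$clone_id, collapse = ","),
                    n_altered = rep_row$n_altered,
                    p_value = rep_row$p_value,
                    odds_ratio = rep_row$odds_ratio,
                    ci_low = rep_row$ci_low,
                    ci_high = rep_row$ci_high,
                    single_clone = nrow(blk) == 1L,
                    stringsAsFactors = FALSE
                )
            }
        }
    }
    if (!length(regions)) {
        out <- data.frame(chromosome = integer(), start_mb = numeric(),
                          end_mb = numeric(), type = character(),
                          n_clones = integer(), clone_ids = character(),
                          n_altered = integer(), p_value = numeric(),
                          odds_ratio = numeric(), ci_low = numeric(),
                          ci_high = numeric(), single_clone = logical())
    } else {
        out <- do.call(rbind, regions)
        out <- out[order(out$chromosome, out$start_mb, out$type), ,
                   drop = FALSE]
        rownames(out) <- NULL
        out$region_id <- sprintf("reg%02d", seq_len(nrow(out)))
    }
    class(out) <- c("genomic_regions", "data.frame")
    out
}

#' Gap statistics for clones inside regions
#'
#' Pools the gaps between consecutive clones within every multi-clone region
#' and returns their median and mean (Mb).
#'
#' @param regions [build_regions()] output.
#' @param clone_map Clone map.
#' @return List with `median_gap_mb` and `mean_gap_mb`.
#' @export
region_gap_stats <- function(regions, clone_map) {
    gaps <- numeric()
    for (k in seq_len(nrow(regions))) {
        ids <- strsplit(regions$clone_ids[k], ",")[[1]]
        if (length(ids) < 2) next
        pos <- sort(clone_map$position_mb[match(ids, clone_map$clone_id)])
        gaps <- c(gaps, diff(pos))
    }
    if (!length(gaps))
        stop("no regions with at least two clones", call. = FALSE)
    list(median_gap_mb = median(gaps), mean_gap_mb = mean(gaps))
}

#' Format regions as a publication-style table
#'
#' Mirrors the layout of region report tables: chromosome, region in Mb,
#' number of altered tumors, alteration type, p-value, odds ratio (printed
#' `INF` when infinite) and 95% CI (printed `N/A` when absent).
#'
#' @param regions [build_regions()] output.
#' @param path Optional path; when given the table is written as TSV.
#' @return The formatted `data.frame`, invisibly when written to `path`.
#' @export
region_table <- function(regions, path = NULL) {
    fmt <- data.frame(
        Chr = regions$chromosome,
        Region_Mb = ifelse(regions$start_mb == regions$end_mb,
                           sprintf("%.1f", regions$start_mb),
                           sprintf("%.1f-%.1f", regions$start_mb,
                                   regions$end_mb)),
        No. = regions$n_altered,
        Alt. = regions$type,
        P_Value = signif(regions$p_value, 2),
        OR = ifelse(is.infinite(regions$odds_ratio), "INF",
                    sprintf("%.2f", regions$odds_ratio)),
        CI_95 = ifelse(is.na(regions$ci_low), "N/A",
                       sprintf("%.2f-%.2f", regions$ci_low,
                               regions$ci_high)),
        stringsAsFactors = FALSE
    )
    if (nrow(regions) == 0)
        fmt <- fmt[0, , drop = FALSE]
    if (!is.null(path)) {
        write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(fmt))
    }
    fmt
}
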