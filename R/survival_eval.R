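#' Prediction rate
#'
#' Percent of samples whose predicted class matches the observed class,
#' reported to one decimal. Named vectors are aligned by name.
#'
#' @param predicted,actual Class vectors (character or factor). When both
#'   are named, they are matched on names; disjoint names are an error.
#' @return Percent correct, one decimal.
#' @export
prediction_rate <- function(predicted, actual) {
    p <- as.character(predicted); a <- as.character(actual)
    if (!is.null(names(predicted)) && !is.null(names(actual))) {
        common <- intersect(names(predicted), names(actual))
        if (!length(common)) stop("no shared sample ids", call. = FALSE)
        p <- as.character(predicted[common])
        a <- as.character(actual[common])
    } else if (length(p) != length(a)) {
        stop("predicted and actual differ in length", call. = FALSE)
    }
    if (!length(p)) stop("empty prediction vector", call. = FALSE)
    round(100 * mean(p == a), 1)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator; censored subjects leave the risk set without an
#' event step.
#'
#' @param time Follow-up times (months, non-negative).
#' @param event Event indicator (1/TRUE = disease death).
#' @param group Group label per subject (e.g. predicted good/poor).
#' @return `data.frame` (class `km_curves`) with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, one row per observed time
#'   per group.
#' @export
km_estimate <- function(time, event, group = rep("all", length(time))) {
    if (any(time < 0)) stop("negative times", call. = FALSE)
    group <- as.factor(group)
    fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ group)
    strata <- if (is.null(fit$strata)) {
        rep(levels(group)[1], length(fit$time))
    } else {
        rep(sub("^group=", "", names(fit$strata)), fit$strata)
    }
    out <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv, stringsAsFactors = FALSE)
    class(out) <- c("km_curves", "data.frame")
    out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with a one-degree-of-freedom chi-square
#' reference (two-sided).
#'
#' @inheritParams km_estimate
#' @return List with `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) < 2)
        stop("need at least two groups", call. = FALSE)
    sd_ <- survival::survdiff(
        survival::Surv(time, as.integer(event)) ~ group)
    df <- length(sd_$n) - 1
    list(chi_square = unname(sd_$chisq), df = df,
         p_value = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Multivariate model of outcome on gene prediction and IGCCCG risk
#'
#' Fits the binary poor-outcome indicator on the gene-model prediction and
#' the IGCCCG risk class, both as a linear-probability model (plain linear
#' regression on the 0/1 outcome) and as a logistic regression. IGCCCG risk
#' enters either as a continuous score (good = 0, intermediate = 1,
#' poor = 2) or as a binary indicator merging intermediate and poor.
#' Complete separation in the logistic fit is detected and flagged (an
#' exact conditional method is suggested in that case).
#'
#' @param outcome Observed outcome, factor/character with values good/poor.
#' @param predicted Gene-model prediction, good/poor.
#' @param igcccg IGCCCG risk class: good/intermediate/poor.
#' @param coding `"continuous"` or `"binary"` risk coding.
#' @return List with `linear` and `logistic` coefficient tables
#'   (term, estimate, p_value) and a `separation` flag.
#' @export
multivariate_model <- function(outcome, predicted, igcccg,
                               coding = c("continuous", "binary")) {
    coding <- match.arg(coding)
    if (anyNA(outcome) || anyNA(predicted) || anyNA(igcccg))
        stop("missing covariates", call. = FALSE)
    y <- as.integer(as.character(outcome) == "poor")
    pr <- as.integer(as.character(predicted) == "poor")
    risk <- if (coding == "continuous") {
        c(good = 0, intermediate = 1, poor = 2)[as.character(igcccg)]
    } else {
        as.integer(as.character(igcccg) %in% c("intermediate", "poor"))
    }
    df <- data.frame(y = y, gene_model = pr, igcccg = unname(risk))
    lin <- lm(y ~ gene_model + igcccg, data = df)
    ls <- summary(lin)$coefficients
    linear <- data.frame(term = rownames(ls), estimate = ls[, 1],
                         p_value = ls[, 4], row.names = NULL)
    sep <- FALSE
    logi <- withCallingHandlers(
        glm(y ~ gene_model + igcccg, data = df, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    gs <- summary(logi)$coefficients
    logistic <- data.frame(term = rownames(gs), estimate = gs[, 1],
                           p_value = gs[, 4], row.names = NULL)
    if (any(abs(gs[-1, 1]) > 10 & gs[-1, 2] > 10)) sep <- TRUE
    out <- list(linear = linear, logistic = logistic, separation = sep)
    if (sep)
        out$note <- paste("complete or quasi-complete separation detected;",
                          "consider an exact conditional logistic model")
    out
}

interval_jaccard <- function(s1, e1, s2, e2) {
    inter <- max(0, min(e1, e2) - max(s1, s2))
    un <- max(e1, e2) - min(s1, s2)
    if (un <= 0) return(as.numeric(s1 == s2 && e1 == e2))
    inter / un
}

#' Benchmark a pipeline run against synthetic truth
#'
#' A planted region counts as recovered when a called region of the same
#' alteration type on the same chromosome overlaps it with a Jaccard index
#' of at least 0.5. Dosage-gene recall is computed over the dosage probes of
#' recovered regions.
#'
#' @param truth A [synthetic_truth()] object.
#' @param regions Called regions ([build_regions()] output; typically the
#'   union over endpoints).
#' @param gene_set Character vector (or `data.frame` with `probe_id`) of
#'   selected target probes.
#' @param predicted,actual Validation predictions and observed labels
#'   (named by sample), or `NULL` to skip.
#' @param jaccard_min Recovery threshold.
#' @return List (class `evaluation_report`): per-region recovery table,
#'   `sensitivity_pct`, `n_false_regions`, `dosage_recall_pct`,
#'   `prediction_rate_pct`.
#' @export
evaluate_pipeline <- function(truth, regions, gene_set = NULL,
                              predicted = NULL, actual = NULL,
                              jaccard_min = 0.5) {
    stopifnot(inherits(truth, "synthetic_truth"))
    tr <- truth$regions
    best_j <- numeric(nrow(tr))
    for (r in seq_len(nrow(tr))) {
        cand <- regions[regions$type == tr$type[r] &
                        regions$chromosome == tr$chromosome[r], ,
                        drop = FALSE]
        best_j[r] <- if (nrow(cand)) max(vapply(seq_len(nrow(cand)),
            function(k) interval_jaccard(cand$start_mb[k], cand$end_mb[k],
                                         tr$start_mb[r], tr$end_mb[r]),
            numeric(1))) else 0
    }
    recovered <- best_j >= jaccard_min
    false_regions <- 0L
    for (k in seq_len(nrow(regions))) {
        js <- vapply(seq_len(nrow(tr)), function(r)
            if (regions$type[k] == tr$type[r] &&
                regions$chromosome[k] == tr$chromosome[r])
                interval_jaccard(regions$start_mb[k], regions$end_mb[k],
                                 tr$start_mb[r], tr$end_mb[r]) else 0,
            numeric(1))
        if (all(js < jaccard_min)) false_regions <- false_regions + 1L
    }
    recall <- NA_real_
    if (!is.null(gene_set) && any(recovered)) {
        ids <- if (is.data.frame(gene_set)) gene_set$probe_id else gene_set
        planted <- unique(unlist(truth$dosage_probes[tr$region_id[recovered]]))
        if (length(planted))
            recall <- round(100 * mean(planted %in% ids), 1)
    }
    rate <- if (!is.null(predicted) && !is.null(actual))
        prediction_rate(predicted, actual) else NA_real_
    structure(list(
        region_recovery = data.frame(region_id = tr$region_id,
                                     jaccard = round(best_j, 3),
                                     recovered = recovered),
        sensitivity_pct = round(100 * mean(recovered), 1),
        n_false_regions = false_regions,
        dosage_recall_pct = recall,
        prediction_rate_pct = rate
    ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
    cat("Pipeline evaluation vs planted truth\n")
    cat("  region sensitivity:", x$sensitivity_pct, "%\n")
    cat("  false regions:", x$n_false_regions, "\n")
    cat("  dosage-gene recall:", x$dosage_recall_pct, "%\n")
    cat("  validation prediction rate:", x$prediction_rate_pct, "%\n")
    invisible(x)
}
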