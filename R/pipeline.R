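#' Run the combined copy-number / expression outcome pipeline
#'
#' End-to-end analysis of a cohort: CBS segmentation of the training aCGH
#' profiles, gain/loss calling, per-clone Fisher association scans for both
#' endpoints, region aggregation by the proximity rule, per-region SAM
#' screens with directional fold-change filters, gene-set construction (per
#' endpoint and combined), median-match normalization of the second
#' validation batch, nearest-shrunken-centroid model building and validation
#' prediction, and survival separation of the predicted groups.
#'
#' @param cohort A `gct_cohort` from [simulate_gct_cohort()], or any list
#'   with the same structure (`train$log_ratio`, `train$expr`,
#'   `train$records`, `val$expr`, `val$records`, `val$batch2`,
#'   `normal_expr`, and `truth` carrying `clone_map` and
#'   `probe_annotation`).
#' @param cbs_alpha,cbs_nperm CBS split level and permutation count.
#' @param gain_threshold,loss_threshold Log2 call thresholds.
#' @param assoc_alpha Clone significance level for the association scan.
#' @param max_gap_mb,min_clones Region aggregation parameters.
#' @param sam_nperm,fdr_target SAM screen parameters.
#' @param two_x,three_x Fold-change filters.
#' @param cv_folds Upper bound on NSC cross-validation folds (reduced to the
#'   smallest class when needed).
#' @param seed Integer seed for all stochastic steps.
#' @return List of class `gct_pipeline_result`: calls, per-endpoint
#'   associations/regions/gene sets, the combined gene set, fitted models,
#'   validation predictions and rates, log-rank results, and (when truth is
#'   available) an [evaluate_pipeline()] report.
#' @export
run_gct_pipeline <- function(cohort,
                             cbs_alpha = 0.01, cbs_nperm = 200L,
                             gain_threshold = 0.2, loss_threshold = -0.2,
                             assoc_alpha = 0.05, max_gap_mb = 11.5,
                             min_clones = 1L,
                             sam_nperm = 200L, fdr_target = 0.10,
                             two_x = 2.0, three_x = 3.0,
                             cv_folds = 10L, seed = 1L) {
    truth <- cohort$truth
    clone_map <- truth$clone_map
    annotation <- truth$probe_annotation
    endpoints <- c("2yDFS", "5yDSS")

    segs <- segment_cohort(cohort$train$log_ratio, clone_map,
                           alpha = cbs_alpha, n_perm = cbs_nperm,
                           seed = node_seed(seed, 1, 1))
    calls <- call_alterations(segs, gain_threshold, loss_threshold)

    expr_all <- cbind(cohort$train$expr, cohort$normal_expr)
    normal_ids <- colnames(cohort$normal_expr)

    per_ep <- list()
    for (ei in seq_along(endpoints)) {
        ep <- endpoints[ei]
        labels <- derive_endpoint_labels(cohort$train$records, ep)
        assoc <- associate_clones(calls, labels, clone_map)
        regions <- build_regions(assoc, clone_map, alpha = assoc_alpha,
                                 max_gap_mb = max_gap_mb,
                                 min_clones = min_clones)
        targets <- list()
        for (k in seq_len(nrow(regions))) {
            reg <- regions[k, ]
            probes <- suppressMessages(
                map_probes_to_region(annotation, reg))
            if (length(probes) < 1) next
            rep_clone <- region_representative_clone(reg, assoc)
            cl <- calls[rep_clone, ]
            eligible <- names(labels)[labels %in% c("good", "poor")]
            usable <- intersect(eligible, colnames(calls))
            usable <- usable[!is.na(cl[usable]) &
                             cl[usable] %in% c(reg$type, "normal")]
            altered_ids <- usable[cl[usable] == reg$type]
            unaltered_ids <- usable[cl[usable] == "normal"]
            if (length(altered_ids) < 2 || length(unaltered_ids) < 2) next
            sub <- cohort$train$expr[probes, c(altered_ids, unaltered_ids),
                                     drop = FALSE]
            sam <- sam_screen(sub, colnames(sub) %in% altered_ids,
                              n_perm = sam_nperm, fdr_target = fdr_target,
                              seed = node_seed(seed, 2 + ei, k))
            if (!length(sam$selected)) next
            folds <- fold_changes(expr_all[probes, , drop = FALSE],
                                  altered_ids, unaltered_ids, normal_ids,
                                  reg$type)
            tg <- select_targets(sam, folds, two_x, three_x)
            if (nrow(tg)) {
                tg$region_id <- reg$region_id
                targets[[length(targets) + 1L]] <- tg
            }
        }
        gene_set <- if (length(targets))
            unique(do.call(rbind, targets)$probe_id) else character()
        per_ep[[ep]] <- list(labels = labels, assoc = assoc,
                             regions = regions,
                             targets = if (length(targets))
                                 do.call(rbind, targets) else NULL,
                             gene_set = gene_set)
    }

    combined <- combine_gene_sets(per_ep[["2yDFS"]]$gene_set,
                                  per_ep[["5yDSS"]]$gene_set)

    # cross-batch normalization of the second validation batch
    val_expr <- cohort$val$expr
    batch2 <- cohort$val$batch2
    if (length(batch2)) {
        ref_ids <- setdiff(colnames(val_expr), batch2)
        val_expr[, batch2] <- median_match_normalize(
            val_expr[, batch2, drop = FALSE],
            val_expr[, ref_ids, drop = FALSE])
    }

    fit_and_predict <- function(gene_set, train_labels, val_labels, sub_seed) {
        if (length(gene_set) < 1) return(NULL)
        eligible <- names(train_labels)[train_labels %in% c("good", "poor")]
        eligible <- intersect(eligible, colnames(cohort$train$expr))
        y <- droplevels(factor(as.character(train_labels[eligible]),
                               levels = c("good", "poor")))
        if (nlevels(y) < 2 || min(table(y)) < 2) return(NULL)
        folds <- max(2L, min(cv_folds, min(table(y))))
        model <- nsc_train(cohort$train$expr[gene_set, eligible,
                                             drop = FALSE],
                           y, cv_folds = folds,
                           seed = node_seed(seed, 7, sub_seed))
        pred <- nsc_predict(model, val_expr[gene_set, , drop = FALSE])
        pv <- setNames(pred$predicted, pred$sample_id)
        lv <- setNames(as.character(val_labels), names(val_labels))
        ok <- names(lv)[lv %in% c("good", "poor")]
        ok <- intersect(ok, names(pv))
        rate <- prediction_rate(pv[ok], lv[ok])
        list(model = model, predictions = pred, rate = rate,
             eligible_val = ok)
    }
    lab2_val <- derive_endpoint_labels(cohort$val$records, "2yDFS")
    lab5_val <- derive_endpoint_labels(cohort$val$records, "5yDSS")
    fit_2y <- fit_and_predict(per_ep[["2yDFS"]]$gene_set,
                              per_ep[["2yDFS"]]$labels, lab2_val, 1)
    fit_5y <- fit_and_predict(per_ep[["5yDSS"]]$gene_set,
                              per_ep[["5yDSS"]]$labels, lab5_val, 2)
    fit_comb <- fit_and_predict(combined$probe_id,
                                per_ep[["5yDSS"]]$labels, lab5_val, 3)

    # survival separation of predicted groups in the validation cohort
    logrank <- NULL
    km <- NULL
    if (!is.null(fit_comb)) {
        rec <- cohort$val$records
        pv <- setNames(fit_comb$predictions$predicted,
                       fit_comb$predictions$sample_id)
        grp <- pv[rec$patient_id]
        if (length(unique(grp)) > 1) {
            logrank <- logrank_test(rec$followup_months,
                                    rec$death_from_disease_flag, grp)
            km <- km_estimate(rec$followup_months,
                              rec$death_from_disease_flag, grp)
        }
    }

    evaluation <- NULL
    if (!is.null(truth$regions)) {
        all_regions <- rbind(per_ep[["2yDFS"]]$regions,
                             per_ep[["5yDSS"]]$regions)
        pv <- if (!is.null(fit_comb))
            setNames(fit_comb$predictions$predicted,
                     fit_comb$predictions$sample_id)[fit_comb$eligible_val]
        else NULL
        av <- if (!is.null(fit_comb))
            setNames(as.character(lab5_val),
                     names(lab5_val))[fit_comb$eligible_val] else NULL
        evaluation <- evaluate_pipeline(truth, all_regions,
                                        combined$probe_id, pv, av)
    }

    structure(list(
        segments = segs, calls = calls, endpoints = per_ep,
        combined_gene_set = combined,
        models = list(`2yDFS` = fit_2y, `5yDSS` = fit_5y,
                      combined = fit_comb),
        prediction_rates = c(
            `2yDFS` = if (is.null(fit_2y)) NA_real_ else fit_2y$rate,
            `5yDSS` = if (is.null(fit_5y)) NA_real_ else fit_5y$rate,
            combined = if (is.null(fit_comb)) NA_real_ else fit_comb$rate),
        logrank = logrank, km = km, evaluation = evaluation,
        seed = seed
    ), class = "gct_pipeline_result")
}

# Representative clone of a region: the minimum-p clone among its members.
region_representative_clone <- function(region, assoc) {
    ids <- strsplit(region$clone_ids, ",")[[1]]
    sub <- assoc[assoc$clone_id %in% ids & assoc$type == region$type, ,
                 drop = FALSE]
    sub$clone_id[order(sub$p_value, sub$position_mb)][1]
}

#' @export
print.gct_pipeline_result <- function(x, ...) {
    cat("Combined copy-number / expression outcome pipeline\n")
    for (ep in names(x$endpoints)) {
        e <- x$endpoints[[ep]]
        cat(sprintf("  %s: %d regions, %d target probes\n", ep,
                    nrow(e$regions), length(e$gene_set)))
    }
    cat("  combined gene set:", nrow(x$combined_gene_set), "probes\n")
    r <- x$prediction_rates
    cat(sprintf("  validation prediction rates: 2yDFS %.1f%%, 5yDSS %.1f%%, combined %.1f%%\n",
                r[1], r[2], r[3]))
    if (!is.null(x$logrank))
        cat(sprintf("  log-rank (combined model): chi2 = %.2f, p = %.4g\n",
                    x$logrank$chi_square, x$logrank$p_value))
    invisible(x)
}
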