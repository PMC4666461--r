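#' Build an evenly spaced clone map
#'
#' Constructs the genomic scaffold for a simulated BAC array: clones laid out
#' at a fixed spacing along each chromosome, mimicking a ~1 Mb resolution
#' array.
#'
#' @param n_clones_per_chrom Integer vector; number of clones on each
#'   chromosome (chromosomes are numbered 1, 2, ... in order).
#' @param spacing_mb Spacing between adjacent clones in megabases (> 0).
#' @return A `data.frame` with columns `clone_id`, `chromosome`, `position_mb`;
#'   positions are strictly increasing within a chromosome and clone ids are
#'   unique.
#' @examples
#' cm <- build_clone_map(c(10, 10), spacing_mb = 1)
#' head(cm)
#' @export
build_clone_map <- function(n_clones_per_chrom, spacing_mb = 1) {
    if (length(n_clones_per_chrom) == 0L)
        stop("need at least one chromosome", call. = FALSE)
    if (!is.numeric(spacing_mb) || length(spacing_mb) != 1L || spacing_mb <= 0)
        stop("spacing_mb must be a single positive number", call. = FALSE)
    n_clones_per_chrom <- as.integer(n_clones_per_chrom)
    if (any(n_clones_per_chrom < 1L))
        stop("each chromosome needs at least one clone", call. = FALSE)
    rows <- lapply(seq_along(n_clones_per_chrom), function(ch) {
        k <- n_clones_per_chrom[ch]
        data.frame(
            clone_id = sprintf("C%02d-%04d", ch, seq_len(k)),
            chromosome = ch,
            position_mb = spacing_mb * seq_len(k),
            stringsAsFactors = FALSE
        )
    })
    do.call(rbind, rows)
}

#' Specify planted copy-number regions
#'
#' @param chromosome,start_mb,end_mb Region coordinates (Mb, closed interval).
#' @param type Alteration type, `"gain"` or `"loss"` (recycled).
#' @param prevalence Fraction of patients carrying the alteration, in (0, 1].
#' @param effect_log_odds Increment to the poor-outcome log-odds for carriers;
#'   `Inf` makes every carrier a poor-outcome patient (the infinite-odds-ratio
#'   situation).
#' @return A `data.frame` of region specifications with a `region_id` column.
#' @export
region_specs <- function(chromosome, start_mb, end_mb, type, prevalence,
                         effect_log_odds) {
    spec <- data.frame(
        region_id = sprintf("R%02d", seq_along(chromosome)),
        chromosome = as.integer(chromosome),
        start_mb = as.numeric(start_mb),
        end_mb = as.numeric(end_mb),
        type = as.character(type),
        prevalence = as.numeric(prevalence),
        effect_log_odds = as.numeric(effect_log_odds),
        stringsAsFactors = FALSE
    )
    if (any(spec$start_mb >= spec$end_mb))
        stop("start_mb must be < end_mb", call. = FALSE)
    if (any(spec$prevalence <= 0 | spec$prevalence > 1))
        stop("prevalence must lie in (0, 1]", call. = FALSE)
    if (!all(spec$type %in% c("gain", "loss")))
        stop("type must be 'gain' or 'loss'", call. = FALSE)
    spec
}

#' Default planted-region specification
#'
#' Three outcome-associated regions: two with strong but noisy effects and one
#' whose carriers all have poor outcome, emulating the infinite-odds-ratio
#' regions seen in real cohorts.
#' @return A region-specification `data.frame` (see [region_specs()]).
#' @export
default_region_specs <- function() {
    region_specs(
        chromosome = c(1, 2, 3),
        start_mb = c(20, 10, 30),
        end_mb = c(32, 22, 40),
        type = c("gain", "loss", "gain"),
        prevalence = c(0.25, 0.25, 0.15),
        effect_log_odds = c(3.0, 3.0, Inf)
    )
}

#' Assemble the ground truth for a synthetic cohort
#'
#' Fixes everything the simulators need: the clone map, the planted regions,
#' the probe annotation (with dosage probes placed inside each region), and
#' the noise model. Carrier indicators and measurements are drawn later by
#' the `simulate_*` functions.
#'
#' @param clone_map Clone map from [build_clone_map()].
#' @param regions Region specification from [region_specs()].
#' @param n_probes Total number of expression probes.
#' @param n_dosage_per_region Dosage-responsive probes planted inside each
#'   region.
#' @param dosage_fold Linear fold change of dosage probes in carriers (>= 1);
#'   direction follows the alteration type (up for gains, down for losses).
#' @param expr_noise_sd Probe-level Gaussian noise, log2 scale.
#' @param cn_noise_sd Clone-level Gaussian noise on log2 ratios.
#' @param gain_shift,loss_shift Segment-mean shifts (log2) for carriers.
#' @param missing_rate Independent clone-by-sample missingness rate.
#' @param unstable_fraction Fraction of tumors with a genomically unstable
#'   phenotype in which the planted alterations co-occur.
#' @param carrier_overlap How strongly carriers concentrate in unstable
#'   tumors, in \code{[0, 1]}: 0 makes regions independent across patients,
#'   1 concentrates carriers in unstable tumors as much as the marginal
#'   prevalence allows. Marginal prevalence per region is preserved exactly
#'   either way.
#' @param batch_log_sd SD of per-gene log-normal batch factors for the second
#'   validation batch.
#' @param seed Integer seed fixing the probe layout and baselines.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(clone_map = build_clone_map(rep(55L, 4)),
                            regions = default_region_specs(),
                            n_probes = 260L, n_dosage_per_region = 8L,
                            dosage_fold = 2.5, expr_noise_sd = 0.5,
                            cn_noise_sd = 0.15, gain_shift = 0.4,
                            loss_shift = -0.6, missing_rate = 0.02,
                            unstable_fraction = 0.25, carrier_overlap = 0.85,
                            batch_log_sd = 0.2, seed = NULL) {
    if (dosage_fold < 1) stop("dosage_fold must be >= 1", call. = FALSE)
    chrom_max <- tapply(clone_map$position_mb, clone_map$chromosome, max)
    for (r in seq_len(nrow(regions))) {
        ch <- as.character(regions$chromosome[r])
        if (!ch %in% names(chrom_max) || regions$end_mb[r] > chrom_max[[ch]])
            stop("region ", regions$region_id[r],
                 " lies outside the clone map", call. = FALSE)
    }
    with_seed(seed, {
        chroms <- unique(clone_map$chromosome)
        probe_chrom <- sample(chroms, n_probes, replace = TRUE)
        probe_pos <- vapply(probe_chrom, function(ch)
            runif(1, 0.5, chrom_max[[as.character(ch)]]), numeric(1))
        # plant dosage probes inside each region (replacing background probes)
        dosage <- vector("list", nrow(regions))
        names(dosage) <- regions$region_id
        idx <- 1L
        for (r in seq_len(nrow(regions))) {
            take <- idx:(idx + n_dosage_per_region - 1L)
            probe_chrom[take] <- regions$chromosome[r]
            probe_pos[take] <- runif(n_dosage_per_region,
                                     regions$start_mb[r], regions$end_mb[r])
            idx <- idx + n_dosage_per_region
        }
        ord <- order(probe_chrom, probe_pos)
        probe_chrom <- probe_chrom[ord]
        probe_pos <- probe_pos[ord]
        annotation <- data.frame(
            probe_id = sprintf("P%04d", seq_len(n_probes)),
            chromosome = probe_chrom,
            position_mb = round(probe_pos, 3),
            gene_symbol = sprintf("GENE%04d", seq_len(n_probes)),
            stringsAsFactors = FALSE
        )
        for (r in seq_len(nrow(regions))) {
            inside <- annotation$chromosome == regions$chromosome[r] &
                annotation$position_mb >= regions$start_mb[r] &
                annotation$position_mb <= regions$end_mb[r]
            dosage[[regions$region_id[r]]] <- annotation$probe_id[inside]
        }
        baseline <- setNames(runif(n_probes, 6, 10), annotation$probe_id)
        structure(list(
            clone_map = clone_map, regions = regions,
            probe_annotation = annotation, dosage_probes = dosage,
            probe_baseline = baseline, dosage_fold = dosage_fold,
            expr_noise_sd = expr_noise_sd, cn_noise_sd = cn_noise_sd,
            gain_shift = gain_shift, loss_shift = loss_shift,
            missing_rate = missing_rate,
            unstable_fraction = unstable_fraction,
            carrier_overlap = carrier_overlap,
            batch_log_sd = batch_log_sd,
            seed = seed
        ), class = "synthetic_truth")
    })
}

#' @export
print.synthetic_truth <- function(x, ...) {
    cat("Synthetic cohort truth:", nrow(x$clone_map), "clones,",
        nrow(x$regions), "planted regions,",
        nrow(x$probe_annotation), "probes\n")
    invisible(x)
}

#' Simulate aCGH copy-number log-ratio profiles
#'
#' Draws carrier indicators for every planted region, then builds per-sample
#' log2-ratio profiles: carriers get a constant segment shift over the clones
#' inside the region, everything else is centered at zero, and clone-level
#' Gaussian noise plus independent missingness are added on top.
#'
#' Carrier indicators are correlated across regions within a patient: a
#' latent genomically unstable phenotype (fraction `unstable_fraction` of
#' tumors) concentrates the alterations in the same tumors, the way large
#' chromosomal gains and losses co-occur in aggressive disease. Each
#' region's marginal prevalence is preserved exactly, so the per-region
#' carrier count remains binomial.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_samples Number of tumors.
#' @param sample_prefix Prefix for generated sample ids.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A list with `log_ratio` (clones x samples, `NA` = missing) and
#'   `carriers` (regions x samples logical matrix).
#' @export
simulate_copy_number <- function(truth, n_samples, sample_prefix = "S",
                                 seed = NULL) {
    stopifnot(inherits(truth, "synthetic_truth"), n_samples >= 1)
    with_seed(seed, {
        cm <- truth$clone_map
        ids <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
        carriers <- matrix(FALSE, nrow(truth$regions), n_samples,
                           dimnames = list(truth$regions$region_id, ids))
        q <- truth$unstable_fraction
        w <- truth$carrier_overlap
        unstable <- if (q > 0 && w > 0) runif(n_samples) < q else
            rep(FALSE, n_samples)
        for (r in seq_len(nrow(truth$regions))) {
            prev <- truth$regions$prevalence[r]
            if (q > 0 && w > 0 && q < 1) {
                p_hi <- w * min(1, prev / q) + (1 - w) * prev
                p_lo <- max(0, (prev - q * p_hi) / (1 - q))
                p <- ifelse(unstable, p_hi, p_lo)
            } else p <- rep(prev, n_samples)
            carriers[r, ] <- runif(n_samples) < p
        }
        lr <- matrix(rnorm(nrow(cm) * n_samples, 0, truth$cn_noise_sd),
                     nrow(cm), n_samples,
                     dimnames = list(cm$clone_id, ids))
        for (r in seq_len(nrow(truth$regions))) {
            reg <- truth$regions[r, ]
            in_reg <- cm$chromosome == reg$chromosome &
                cm$position_mb >= reg$start_mb & cm$position_mb <= reg$end_mb
            shift <- if (reg$type == "gain") truth$gain_shift else truth$loss_shift
            lr[in_reg, carriers[r, ]] <- lr[in_reg, carriers[r, ]] + shift
        }
        if (truth$missing_rate > 0) {
            miss <- runif(length(lr)) < truth$missing_rate
            lr[miss] <- NA_real_
        }
        list(log_ratio = lr, carriers = carriers)
    })
}

#' Simulate expression for tumors and normal testes
#'
#' Dosage probes shift by `log2(dosage_fold)` in carriers, upward for gains
#' and downward for losses; all other probes are exchangeable between carrier
#' groups. Normal testes are drawn around the same per-probe baselines.
#'
#' @param truth A [synthetic_truth()] object.
#' @param carriers Carrier matrix from [simulate_copy_number()].
#' @param n_normals Number of normal-testis reference samples (0 allowed).
#' @param seed Optional seed.
#' @return A list with `expr` (probes x tumors, log2), `normal_expr`
#'   (probes x normals, log2) and `annotation`.
#' @export
simulate_expression <- function(truth, carriers, n_normals = 10L,
                                seed = NULL) {
    stopifnot(inherits(truth, "synthetic_truth"), is.matrix(carriers))
    with_seed(seed, {
        ids <- colnames(carriers)
        probes <- truth$probe_annotation$probe_id
        expr <- matrix(rnorm(length(probes) * length(ids), 0,
                             truth$expr_noise_sd),
                       length(probes), length(ids),
                       dimnames = list(probes, ids)) +
            truth$probe_baseline[probes]
        shift <- log2(truth$dosage_fold)
        for (r in seq_len(nrow(truth$regions))) {
            reg <- truth$regions[r, ]
            dp <- truth$dosage_probes[[reg$region_id]]
            if (length(dp) == 0L) next
            s <- if (reg$type == "gain") shift else -shift
            expr[dp, carriers[reg$region_id, ]] <-
                expr[dp, carriers[reg$region_id, ]] + s
        }
        normal_expr <- NULL
        if (n_normals > 0L) {
            nids <- sprintf("N%03d", seq_len(n_normals))
            normal_expr <- matrix(rnorm(length(probes) * n_normals, 0,
                                        truth$expr_noise_sd),
                                  length(probes), n_normals,
                                  dimnames = list(probes, nids)) +
                truth$probe_baseline[probes]
        }
        list(expr = expr, normal_expr = normal_expr,
             annotation = truth$probe_annotation)
    })
}

#' Simulate clinical outcome records
#'
#' Poor outcome is logistic in the carrier indicators: the log-odds are
#' `qlogis(baseline_poor_rate)` plus the sum of the carried regions'
#' `effect_log_odds`; an infinite effect makes every carrier poor. Follow-up
#' times are drawn to be consistent with the labels: poor-outcome patients
#' are never disease free or recur within two years, and die of disease
#' within five years with probability `death_given_poor`; good-outcome
#' patients are followed past five years except for a `censor_rate` fraction
#' censored alive earlier (ineligible for the five-year endpoint).
#'
#' @param carriers Carrier matrix (regions x samples).
#' @param truth A [synthetic_truth()] object.
#' @param baseline_poor_rate Poor-outcome probability for non-carriers, (0,1).
#' @param censor_rate Fraction of good-outcome patients censored before 60
#'   months.
#' @param death_given_poor Probability a poor-outcome patient dies of disease
#'   within five years.
#' @param batch Batch label stored on every record.
#' @param seed Optional seed.
#' @return A `data.frame` of outcome records, one row per patient.
#' @export
simulate_outcomes <- function(carriers, truth, baseline_poor_rate = 0.10,
                              censor_rate = 0.10, death_given_poor = 0.8,
                              batch = "train", seed = NULL) {
    stopifnot(is.matrix(carriers),
              baseline_poor_rate > 0, baseline_poor_rate < 1)
    with_seed(seed, {
        ids <- colnames(carriers)
        n <- length(ids)
        eff <- truth$regions$effect_log_odds
        finite_eff <- ifelse(is.finite(eff), eff, 0)
        lp <- qlogis(baseline_poor_rate) +
            as.vector(finite_eff %*% carriers)
        p_poor <- plogis(lp)
        forced <- as.vector((!is.finite(eff)) %*% carriers) > 0
        poor <- runif(n) < p_poor | forced
        never_free <- poor & runif(n) < 0.3
        recur <- ifelse(poor & !never_free, runif(n, 3, 22), NA_real_)
        dies <- poor & runif(n) < death_given_poor
        death_m <- ifelse(dies, runif(n, 30, 58), NA_real_)
        followup <- ifelse(dies, death_m,
                    ifelse(poor, runif(n, 61, 96),
                    ifelse(runif(n) < censor_rate, runif(n, 30, 59),
                           runif(n, 61, 120))))
        risk_levels <- c("good", "intermediate", "poor")
        risk <- ifelse(poor,
                       sample(risk_levels, n, TRUE, prob = c(.3, .3, .4)),
                       sample(risk_levels, n, TRUE, prob = c(.7, .2, .1)))
        data.frame(
            patient_id = ids,
            followup_months = round(followup, 1),
            disease_event_flag = poor,
            death_from_disease_flag = dies,
            never_disease_free_flag = never_free,
            recurrence_months = round(recur, 1),
            igcccg_risk = risk,
            batch = batch,
            stringsAsFactors = FALSE
        )
    })
}

#' Draw per-gene batch factors
#'
#' @param n_genes Number of genes.
#' @param log_sd SD of the log-normal factor distribution.
#' @param seed Optional seed.
#' @return Positive numeric vector of length `n_genes`.
#' @export
draw_batch_factors <- function(n_genes, log_sd = 0.2, seed = NULL) {
    with_seed(seed, rlnorm(n_genes, 0, log_sd))
}

#' Apply a multiplicative per-gene batch effect
#'
#' Scales each gene's linear-scale intensities by its batch factor; on the
#' log2 matrices used throughout the package this is an additive per-gene
#' offset of `log2(factor)`.
#'
#' @param expr Expression matrix (probes x samples, log2 scale).
#' @param batch_factors Positive factor per gene (length `nrow(expr)`).
#' @return The perturbed matrix.
#' @export
apply_batch_effect <- function(expr, batch_factors) {
    stop_if_not_matrix(expr, "expr")
    if (length(batch_factors) != nrow(expr))
        stop("need one factor per gene", call. = FALSE)
    if (any(!is.finite(batch_factors)) || any(batch_factors <= 0))
        stop("batch factors must be positive and finite", call. = FALSE)
    expr + log2(batch_factors)
}

#' Simulate a full training + validation cohort
#'
#' Generates everything the pipeline consumes: a training cohort with aCGH
#' profiles, expression, normal testes references, and outcomes; and a
#' validation cohort (expression and outcomes only, mirroring the study
#' design where the validation tumors lacked copy-number data) split into
#' two batches, the second perturbed by a per-gene multiplicative batch
#' effect.
#'
#' @param n_train,n_val Cohort sizes (defaults 53 and 54).
#' @param n_normals Number of normal-testis references.
#' @param truth Optional pre-built [synthetic_truth()]; built from `...` if
#'   missing.
#' @param baseline_poor_rate,censor_rate,death_given_poor Passed to
#'   [simulate_outcomes()].
#' @param val2_fraction Fraction of validation tumors in the second batch.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param ... Passed to [synthetic_truth()] when `truth` is missing.
#' @return An object of class `gct_cohort`: a list with elements `truth`,
#'   `train` (log_ratio, carriers, expr, records), `val` (expr, carriers,
#'   records, batch2, batch_factors) and `normal_expr`.
#' @export
simulate_gct_cohort <- function(n_train = 53L, n_val = 54L, n_normals = 10L,
                                truth = NULL, baseline_poor_rate = 0.10,
                                censor_rate = 0.10, death_given_poor = 0.8,
                                val2_fraction = 0.5, seed = 1L, ...) {
    with_seed(seed, {
        if (is.null(truth)) truth <- synthetic_truth(..., seed = NULL)
        tr_cn <- simulate_copy_number(truth, n_train, sample_prefix = "T")
        tr_ex <- simulate_expression(truth, tr_cn$carriers, n_normals)
        tr_rec <- simulate_outcomes(tr_cn$carriers, truth,
                                    baseline_poor_rate, censor_rate,
                                    death_given_poor, batch = "train")
        va_cn <- simulate_copy_number(truth, n_val, sample_prefix = "V")
        va_ex <- simulate_expression(truth, va_cn$carriers, 0L)
        va_rec <- simulate_outcomes(va_cn$carriers, truth,
                                    baseline_poor_rate, censor_rate,
                                    death_given_poor, batch = "val1")
        n2 <- round(n_val * val2_fraction)
        batch2 <- colnames(va_ex$expr)[seq_len(n_val) > (n_val - n2)]
        va_rec$batch[va_rec$patient_id %in% batch2] <- "val2"
        factors <- draw_batch_factors(nrow(va_ex$expr), truth$batch_log_sd)
        names(factors) <- rownames(va_ex$expr)
        va_expr <- va_ex$expr
        if (length(batch2) > 0)
            va_expr[, batch2] <- apply_batch_effect(
                va_expr[, batch2, drop = FALSE], factors)
        structure(list(
            truth = truth,
            train = list(log_ratio = tr_cn$log_ratio,
                         carriers = tr_cn$carriers,
                         expr = tr_ex$expr, records = tr_rec),
            val = list(expr = va_expr, carriers = va_cn$carriers,
                       records = va_rec, batch2 = batch2,
                       batch_factors = factors),
            normal_expr = tr_ex$normal_expr,
            seed = seed
        ), class = "gct_cohort")
    })
}

#' @export
print.gct_cohort <- function(x, ...) {
    cat("Synthetic GCT cohort:", ncol(x$train$log_ratio), "training tumors,",
        ncol(x$val$expr), "validation tumors,",
        ncol(x$normal_expr), "normal testes\n")
    invisible(x)
}

#' Write a clone map as a BED-like TSV
#'
#' Columns: chrom, start, end (bp, derived from the Mb positions), clone_id,
#' position_mb.
#' @param clone_map Clone map `data.frame`.
#' @param path Output path.
#' @export
write_clone_map <- function(clone_map, path) {
    bed <- data.frame(
        chrom = paste0("chr", clone_map$chromosome),
        start = as.integer(round(clone_map$position_mb * 1e6)) - 1L,
        end = as.integer(round(clone_map$position_mb * 1e6)),
        clone_id = clone_map$clone_id,
        position_mb = clone_map$position_mb
    )
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
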