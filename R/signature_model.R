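#' Median-matching cross-batch normalization
#'
#' Rescales every gene of a batch so that its median matches the same gene's
#' median in a reference batch. The default works multiplicatively on the
#' linear scale (factor = reference linear median / batch linear median);
#' `method = "additive_log"` shifts log2 values by the difference of log2
#' medians. The two coincide whenever the median is attained at a single
#' sample and differ only in how ties across the two middle samples are
#' averaged. The operation is idempotent.
#'
#' @param batch,reference Probes x samples log2 expression matrices over a
#'   shared probe namespace (`reference` probes must cover `batch`).
#' @param method `"multiplicative"` (linear scale) or `"additive_log"`.
#' @return The normalized batch matrix (log2 scale).
#' @export
median_match_normalize <- function(batch, reference,
                                   method = c("multiplicative",
                                              "additive_log")) {
    method <- match.arg(method)
    stop_if_not_matrix(batch, "batch")
    stop_if_not_matrix(reference, "reference")
    if (!all(rownames(batch) %in% rownames(reference)))
        stop("reference lacks some batch probes", call. = FALSE)
    ref <- reference[rownames(batch), , drop = FALSE]
    if (method == "multiplicative") {
        bm <- apply(2^batch, 1, median)
        rm_ <- apply(2^ref, 1, median)
        if (any(bm == 0)) stop("zero batch median", call. = FALSE)
        batch + log2(rm_ / bm)
    } else {
        batch + (apply(ref, 1, median) - apply(batch, 1, median))
    }
}

nsc_standardize <- function(x, labels) {
    classes <- levels(labels)
    n <- ncol(x)
    nk <- table(labels)
    overall <- rowMeans(x)
    cents <- vapply(classes, function(k)
        rowMeans(x[, labels == k, drop = FALSE]), numeric(nrow(x)))
    if (nrow(x) == 1L)
        cents <- matrix(cents, 1, length(classes),
                        dimnames = list(rownames(x), classes))
    ss <- 0
    for (k in classes)
        ss <- ss + rowSums((x[, labels == k, drop = FALSE] - cents[, k])^2)
    s <- sqrt(ss / (n - length(classes)))
    s0 <- median(s)
    mk <- sqrt(1 / nk - 1 / n)
    dik <- sweep(cents - overall, 1, s + s0, "/")
    dik <- sweep(dik, 2, mk[classes], "/")
    list(classes = classes, nk = nk, overall = overall, centroids = cents,
         s = s, s0 = s0, mk = mk, dik = dik)
}

nsc_shrink <- function(std, delta) {
    dshr <- sign(std$dik) * pmax(abs(std$dik) - delta, 0)
    cents <- std$overall +
        sweep(sweep(dshr, 2, std$mk[std$classes], "*"), 1,
              std$s + std$s0, "*")
    list(shrunken_offsets = dshr, shrunken_centroids = cents)
}

nsc_score <- function(shrunken_centroids, s, s0, priors, newx) {
    classes <- colnames(shrunken_centroids)
    scores <- vapply(classes, function(k) {
        colSums(((newx - shrunken_centroids[, k]) / (s + s0))^2) -
            2 * log(priors[k])
    }, numeric(ncol(newx)))
    if (ncol(newx) == 1L) scores <- matrix(scores, nrow = 1,
                                           dimnames = list(colnames(newx),
                                                           classes))
    scores
}

#' Train a nearest-shrunken-centroid outcome classifier
#'
#' Standardized class-versus-overall centroid offsets
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` with pooled within-class
#' scatter `s_i`, fudge factor `s0 = median(s_i)` and
#' `m_k = sqrt(1/n_k - 1/n)` are soft-thresholded by the shrinkage `delta`.
#' `delta` is chosen by stratified cross-validated misclassification error;
#' ties go to the largest `delta` (the most parsimonious model).
#'
#' @param x Probes x samples log2 expression matrix.
#' @param labels Factor of class labels (one per sample).
#' @param delta_grid Shrinkage grid; default 30 values from 0 to the largest
#'   absolute offset.
#' @param cv_folds Number of stratified folds; every class must have at
#'   least `cv_folds` members.
#' @param prior `"class"` (training frequencies) or `"uniform"`.
#' @param seed Optional seed controlling fold assignment.
#' @return An object of class `centroid_model`.
#' @export
nsc_train <- function(x, labels, delta_grid = NULL, cv_folds = 10L,
                      prior = c("class", "uniform"), seed = NULL) {
    prior <- match.arg(prior)
    stop_if_not_matrix(x, "x")
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
    if (length(labels) != ncol(x))
        stop("one label per sample required", call. = FALSE)
    nk <- table(labels)
    if (any(nk < cv_folds))
        stop("every class needs at least cv_folds members; reduce cv_folds",
             call. = FALSE)
    std <- nsc_standardize(x, labels)
    if (is.null(delta_grid))
        delta_grid <- seq(0, max(abs(std$dik)), length.out = 30)
    priors <- if (prior == "uniform")
        setNames(rep(1 / nlevels(labels), nlevels(labels)), levels(labels))
    else nk / sum(nk)

    folds <- with_seed(seed, {
        f <- integer(length(labels))
        for (k in levels(labels)) {
            idx <- sample(which(labels == k))
            f[idx] <- rep_len(seq_len(cv_folds), length(idx))
        }
        f
    })
    cv_pred <- matrix(NA_character_, length(labels), length(delta_grid))
    for (fold in seq_len(cv_folds)) {
        tr <- folds != fold
        std_f <- nsc_standardize(x[, tr, drop = FALSE],
                                 droplevels(labels[tr]))
        pri_f <- if (prior == "uniform") priors else {
            nkf <- table(droplevels(labels[tr]))
            nkf / sum(nkf)
        }
        for (di in seq_along(delta_grid)) {
            sh <- nsc_shrink(std_f, delta_grid[di])
            sc <- nsc_score(sh$shrunken_centroids, std_f$s, std_f$s0,
                            pri_f, x[, !tr, drop = FALSE])
            cv_pred[!tr, di] <- std_f$classes[apply(sc, 1, which.min)]
        }
    }
    cv_err <- colMeans(cv_pred != as.character(labels))
    best <- max(which(cv_err == min(cv_err)))  # ties -> more shrinkage
    delta <- delta_grid[best]
    sh <- nsc_shrink(std, delta)
    structure(list(
        probe_ids = rownames(x), classes = std$classes,
        overall_centroid = std$overall, class_centroids = std$centroids,
        shrunken_offsets = sh$shrunken_offsets,
        shrunken_centroids = sh$shrunken_centroids,
        offsets = std$dik, s = std$s, s0 = std$s0, mk = std$mk,
        delta = delta, priors = priors, n_per_class = nk,
        cv = data.frame(delta = delta_grid, cv_error = cv_err),
        cv_pred = cv_pred, cv_folds = folds, labels = labels,
        seed = seed
    ), class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
    active <- sum(rowSums(abs(x$shrunken_offsets)) > 0)
    cat("Nearest-shrunken-centroid model:", length(x$probe_ids), "probes (",
        active, "active ), classes",
        paste(x$classes, collapse = "/"),
        sprintf("; delta = %.3f, CV error = %.3f\n", x$delta,
                x$cv$cv_error[which.min(abs(x$cv$delta - x$delta))]))
    invisible(x)
}

#' Predict outcomes with a shrunken-centroid model
#'
#' Discriminant score for class k is the squared standardized distance to
#' the shrunken centroid minus twice the log prior; the smallest score wins,
#' with ties broken deterministically by class order.
#'
#' @param model A [nsc_train()] model.
#' @param x Probes x samples matrix containing all model probes.
#' @return `data.frame` (class `prediction_result`) with `sample_id` and
#'   `predicted`; discriminant scores and posterior-like weights are
#'   attached as attributes `scores` and `posterior`.
#' @export
nsc_predict <- function(model, x) {
    stopifnot(inherits(model, "centroid_model"))
    stop_if_not_matrix(x, "x")
    missing <- setdiff(model$probe_ids, rownames(x))
    if (length(missing))
        stop("matrix lacks model probes: ",
             paste(head(missing, 5), collapse = ", "), call. = FALSE)
    newx <- x[model$probe_ids, , drop = FALSE]
    if (any(!is.finite(newx)))
        stop("non-finite expression values", call. = FALSE)
    sc <- nsc_score(model$shrunken_centroids, model$s, model$s0,
                    model$priors, newx)
    pred <- model$classes[apply(sc, 1, which.min)]
    w <- exp(-(sc - apply(sc, 1, min)) / 2)
    post <- w / rowSums(w)
    out <- data.frame(sample_id = colnames(x), predicted = pred,
                      stringsAsFactors = FALSE)
    attr(out, "scores") <- sc
    attr(out, "posterior") <- post
    class(out) <- c("prediction_result", "data.frame")
    out
}

#' Serialize a centroid model to JSON
#'
#' @param model A [nsc_train()] model.
#' @param path Output path.
#' @export
write_centroid_model <- function(model, path) {
    obj <- list(probe_ids = model$probe_ids, classes = model$classes,
                overall_centroid = model$overall_centroid,
                shrunken_centroids = as.data.frame(model$shrunken_centroids),
                s = model$s, s0 = model$s0, delta = model$delta,
                priors = as.list(model$priors), seed = model$seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
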