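#' Train an elastic-net similarity model on a labeled reference
#'
#' One-vs-rest binomial logistic regression per reference cell type with
#' elastic-net penalty `lambda * (alpha * ||b||_1 + (1 - alpha)/2 *
#' ||b||_2^2)` (default mixing `alpha = 0.6`). Features are standardized
#' internally with the reference means and standard deviations (stored in
#' the model and later applied to query cells — similarity is always
#' measured in reference feature space). With `lambda = "auto"`, the
#' penalty strength is chosen per type by `nfolds`-fold cross-validated
#' binomial deviance on a seeded fold split.
#'
#' @param refMatrix cells x genes normalized expression matrix of the
#'   reference.
#' @param labels cell-type label per reference cell; at least 2 types with
#'   at least 10 cells each.
#' @param alpha elastic-net mixing (default 0.6).
#' @param lambda `"auto"` (cross-validated) or a fixed numeric penalty.
#' @param nfolds folds for the cross-validation (default 5).
#' @param seed RNG seed for the fold split.
#' @return a [SimilarityModel-class].
#' @export
trainSimilarityModel <- function(refMatrix, labels, alpha = 0.6,
                                 lambda = "auto", nfolds = 5, seed = 0) {
    labels <- as.character(labels)
    if (nrow(refMatrix) != length(labels))
        stop("labels must align to reference rows")
    types <- sort(unique(labels))
    if (length(types) < 2) stop("reference needs at least 2 cell types")
    if (any(table(labels) < 10))
        stop("every reference type needs at least 10 cells")
    mu <- colMeans(refMatrix)
    sdev <- apply(refMatrix, 2L, sd)
    sdev[sdev == 0] <- 1  # constant genes carry no signal; coef stays 0
    xs <- sweep(sweep(refMatrix, 2L, mu, `-`), 2L, sdev, `/`)
    coefs <- matrix(0, ncol(refMatrix), length(types),
                    dimnames = list(colnames(refMatrix), types))
    intercepts <- setNames(numeric(length(types)), types)
    lambdas <- setNames(numeric(length(types)), types)
    set.seed(as.integer(seed))
    foldid <- sample(rep_len(seq_len(nfolds), nrow(xs)))
    for (ty in types) {
        y <- as.integer(labels == ty)
        perFold <- table(y, foldid)
        if (any(perFold < 2))
            stop("type '", ty, "' has < 2 cells in a CV fold; ",
                 "use fewer folds")
        if (identical(lambda, "auto")) {
            cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial",
                                       alpha = alpha, foldid = foldid,
                                       standardize = FALSE,
                                       thresh = 1e-6)
            lam <- cvfit$lambda.min
            fit <- cvfit$glmnet.fit
        } else {
            lam <- lambda
            fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = alpha,
                                  standardize = FALSE, thresh = 1e-6)
        }
        beta <- as.matrix(predict(fit, type = "coefficients", s = lam))
        intercepts[ty] <- beta[1L, 1L]
        coefs[, ty] <- beta[-1L, 1L]
        lambdas[ty] <- lam
    }
    methods::new("SimilarityModel", coefficients = coefs,
                 intercepts = intercepts, alpha = alpha, lambda = lambdas,
                 genes = colnames(refMatrix), geneMeans = mu,
                 geneSds = sdev, types = types)
}

#' Similarity of query groups to reference cell types
#'
#' Per query cell and reference type, the logit `intercept + b . x` on the
#' reference-standardized shared features; model genes missing from the
#' query are imputed as 0 on the standardized scale (warned when more than
#' half are missing). Logits are then averaged within each query group
#' (cluster or sample), matching the convention of reporting mean logits
#' per group; set `scale = "probability"` to average sigmoid-transformed
#' values instead.
#'
#' @param model a [SimilarityModel-class].
#' @param queryMatrix cells x genes normalized expression matrix.
#' @param groupLabels group per query cell (cluster id or sample id).
#' @param scale `"logit"` (default) or `"probability"`.
#' @return list with `groupMeans` (groups x types matrix) and `cellValues`
#'   (cells x types matrix).
#' @export
predictSimilarity <- function(model, queryMatrix, groupLabels,
                              scale = c("logit", "probability")) {
    scale <- match.arg(scale)
    if (nrow(queryMatrix) != length(groupLabels))
        stop("groupLabels must align to query rows")
    shared <- intersect(model@genes, colnames(queryMatrix))
    if (!length(shared)) stop("query and model share no genes")
    if (length(shared) < length(model@genes) / 2)
        warning("more than 50% of model genes missing from query; ",
                "missing genes imputed as 0")
    idx <- match(shared, model@genes)
    xs <- sweep(sweep(queryMatrix[, shared, drop = FALSE], 2L,
                      model@geneMeans[idx], `-`),
                2L, model@geneSds[idx], `/`)
    logits <- xs %*% model@coefficients[idx, , drop = FALSE]
    logits <- sweep(logits, 2L, model@intercepts, `+`)
    vals <- if (scale == "probability") 1 / (1 + exp(-logits)) else logits
    rownames(vals) <- rownames(queryMatrix)
    grp <- sort(unique(as.character(groupLabels)))
    gm <- t(vapply(grp, function(g)
        colMeans(vals[groupLabels == g, , drop = FALSE]),
        numeric(ncol(vals))))
    list(groupMeans = gm, cellValues = vals)
}
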