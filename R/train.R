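# User-facing training, clustering and evaluation.

#' Loss weights
#'
#' Weights on the four loss components: omics-label cross-entropy (`a`),
#' commonality (`b`), spatial regulariser (`c`), reconstruction (`d`).
#' Default 1 each.
#'
#' @param a,b,c,d non-negative reals, not all zero.
#' @return A list with class `"LossWeights"`.
#' @export
lossWeights <- function(a = 1, b = 1, c = 1, d = 1) {
    if (any(c(a, b, c, d) < 0) || a + b + c + d == 0)
        stop("loss weights must be non-negative and not all zero")
    structure(list(a = a, b = b, c = c, d = d), class = "LossWeights")
}

#' Training configuration
#'
#' @param epochs number of full-batch epochs (default 300).
#' @param lr Adam learning rate (default 1e-3).
#' @param optimizer only "adam" is available.
#' @param seed integer seed governing weight initialisation, posterior
#'   sampling and any other randomness of the run.
#' @param klWeight weight on the ADT background posterior/prior KL term
#'   (default 1; 0 disables it).
#' @param spatialMode "kernel" (default; pairs weighted by the Gaussian
#'   spatial kernel) or "literal" (pairs weighted by raw spatial
#'   distance).
#' @return A list with class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 300L, lr = 1e-3, optimizer = "adam",
                        seed = 0L, klWeight = 1,
                        spatialMode = c("kernel", "literal")) {
    if (epochs < 1) stop("'epochs' must be >= 1")
    if (lr <= 0) stop("'lr' must be positive")
    match.arg(optimizer, "adam")
    structure(list(epochs = as.integer(epochs), lr = lr,
                   optimizer = "adam", seed = as.integer(seed),
                   klWeight = klWeight,
                   spatialMode = match.arg(spatialMode)),
              class = "TrainConfig")
}

#' Combine loss components into the total loss
#'
#' `a * ce + b * con + c * reg + d * recon`.
#'
#' @param parts named list/vector with elements `ce`, `con`, `reg`,
#'   `recon` from one forward pass.
#' @param weights a [lossWeights()] object.
#' @return Scalar total loss.
#' @export
totalLoss <- function(parts, weights = lossWeights()) {
    parts <- unlist(parts)
    for (nm in c("ce", "con", "reg", "recon")) {
        if (!is.finite(parts[[nm]]))
            stop(sprintf("loss component '%s' is not finite", nm))
    }
    weights$a * parts[["ce"]] + weights$b * parts[["con"]] +
        weights$c * parts[["reg"]] + weights$d * parts[["recon"]]
}

.buildContext <- function(pair, graph, encCfg, fw, lw, config, single) {
    stopifnot(is(pair, "SpatialOmicsPair"))
    if (!pair@aligned)
        stop("pair must be aligned (see loadPair or SpatialOmicsPair)")
    if (is.null(graph))
        graph <- buildSpatialGraph(pair@coords)
    if (nrow(graph@normalized) == 0)
        graph <- normalizeAdjacency(graph)
    o1 <- pair@omics1; o2 <- pair@omics2
    for (o in list(o1, o2))
        if (any(!is.finite(o@encodedInput)))
            stop("non-finite encoder input; preprocess the modalities first")
    ctx <- list(X1 = o1@encodedInput, raw1 = o1@raw, mod1 = o1@modality,
                S = graphNormalized(graph), P = graphWeights(graph),
                encCfg = encCfg, fw = fw, lw = lw,
                klWeight = config$klWeight,
                spatialMode = config$spatialMode)
    if (config$spatialMode == "literal")
        ctx$Ddist <- as.matrix(stats::dist(pair@coords@positions))
    if (!single) {
        ctx$X2 <- o2@encodedInput; ctx$raw2 <- o2@raw
        ctx$mod2 <- o2@modality
    } else {
        ctx$mod2 <- NULL
    }
    ctx
}

#' Train the fusion model on a spatial omics pair
#'
#' Full-batch joint optimisation of the label, commonality, spatial and
#' reconstruction losses with Adam. The returned representation comes
#' from a final evaluation-mode forward pass (posterior sampling
#' disabled), so it is deterministic given the seed.
#'
#' @param pair an aligned [SpatialOmicsPair-class] with preprocessed
#'   modalities.
#' @param graph optional [SpatialGraph-class]; built from the pair's
#'   coordinates with defaults when NULL.
#' @param encoderCfg an [encoderConfig()].
#' @param fusion a [fusionWeights()] object.
#' @param weights a [lossWeights()] object (defaults: all 1).
#' @param config a [trainConfig()].
#' @return A [JointRepresentation-class] with the fused `Z`, the common
#'   feature `EC`, the per-epoch `lossTrace` and the trained parameters
#'   in `model`.
#' @examples
#' \donttest{
#' bundle <- makeSmokeBundle(seed = 1)
#' jr <- trainFusion(bundle$pair, config = trainConfig(epochs = 5, seed = 1))
#' jr
#' }
#' @export
trainFusion <- function(pair, graph = NULL, encoderCfg = encoderConfig(),
                        fusion = fusionWeights(),
                        weights = lossWeights(),
                        config = trainConfig()) {
    ctx <- .buildContext(pair, graph, encoderCfg, fusion, weights,
                         config, single = FALSE)
    set.seed(config$seed)
    par <- .initModelParams(ncol(ctx$X1), ncol(ctx$X2), ctx$mod1, ctx$mod2,
                            encoderCfg)
    par <- .addDecoderParams(par, "dec1", ctx$mod1, encoderCfg$latentDim,
                             ncol(ctx$raw1))
    par <- .addDecoderParams(par, "dec2", ctx$mod2, encoderCfg$latentDim,
                             ncol(ctx$raw2))
    ctx$prior1 <- if (ctx$mod1 == "adt") fitGMMPrior(ctx$raw1) else NULL
    ctx$prior2 <- if (ctx$mod2 == "adt") fitGMMPrior(ctx$raw2) else NULL
    fit <- .optimise(par, ctx, .forwardFusion, config)
    final <- .forwardFusion(fit$par, ctx, sample = FALSE)
    new("JointRepresentation",
        Z = agValue(final$Z), EC = agValue(final$EC),
        lossTrace = fit$trace, spotIds = spotIds(pair),
        model = list(params = fit$par, encoderCfg = encoderCfg,
                     fusion = fusion, weights = weights, config = config,
                     mode = "fusion",
                     prior1 = ctx$prior1, prior2 = ctx$prior2))
}

#' Train on a single modality
#'
#' Trains the same architecture with one encoder and one decoder; the
#' joint representation is the attention-refined embedding of that
#' modality. Cross-omics terms (label loss, commonality) do not exist in
#' this mode and are forced to zero.
#'
#' @param pair an aligned [SpatialOmicsPair-class].
#' @param which `1`, `2`, or a modality name present in the pair.
#' @inheritParams trainFusion
#' @return A [JointRepresentation-class].
#' @export
singleModalityMode <- function(pair, which = 1L, graph = NULL,
                               encoderCfg = encoderConfig(),
                               weights = lossWeights(),
                               config = trainConfig()) {
    if (is.character(which)) {
        mods <- c(pair@omics1@modality, pair@omics2@modality)
        which <- match(which, mods)
        if (is.na(which)) stop("modality not present in pair")
    }
    o <- if (which == 1L) pair@omics1 else pair@omics2
    solo <- SpatialOmicsPair(o, o, pair@coords)
    ctx <- .buildContext(solo, graph, encoderCfg, fusionWeights(),
                         weights, config, single = TRUE)
    set.seed(config$seed)
    par <- .initModelParams(ncol(ctx$X1), NULL, ctx$mod1, NULL, encoderCfg)
    par <- .addDecoderParams(par, "dec1", ctx$mod1, encoderCfg$latentDim,
                             ncol(ctx$raw1))
    ctx$prior1 <- if (ctx$mod1 == "adt") fitGMMPrior(ctx$raw1) else NULL
    fit <- .optimise(par, ctx, .forwardSingle, config)
    final <- .forwardSingle(fit$par, ctx, sample = FALSE)
    new("JointRepresentation",
        Z = agValue(final$Z), EC = matrix(0, 0, 0),
        lossTrace = fit$trace, spotIds = spotIds(pair),
        model = list(params = fit$par, encoderCfg = encoderCfg,
                     weights = weights, config = config,
                     mode = paste0("single:", ctx$mod1),
                     prior1 = ctx$prior1))
}

#' Cluster the joint representation into spatial domains
#'
#' K-means (when the number of domains is known) with multiple restarts,
#' or Louvain community detection on a kNN graph of the embedding.
#'
#' @param x a [JointRepresentation-class] or an N x g matrix.
#' @param method "kmeans" or "louvain".
#' @param k number of clusters (kmeans; must not exceed N).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed for restarts/community detection.
#' @param knn neighbourhood size of the Louvain graph (default 15).
#' @param truth optional ground-truth labels; fills the `ari` slot.
#' @return A [ClusteringResult-class] with labels in spot order.
#' @export
clusterEmbedding <- function(x, method = c("kmeans", "louvain"), k = NULL,
                             resolution = 1, seed = 0L, knn = 15L,
                             truth = NULL) {
    method <- match.arg(method)
    Z <- if (is(x, "JointRepresentation")) jointEmbedding(x) else as.matrix(x)
    if (any(!is.finite(Z))) stop("embedding must be finite")
    n <- nrow(Z)
    set.seed(seed)
    if (method == "kmeans") {
        if (is.null(k)) stop("'k' is required for kmeans")
        if (k > n) stop(sprintf("k = %d exceeds the number of spots (%d)",
                                k, n))
        labels <- if (k == 1L) rep(1L, n)
                  else as.integer(stats::kmeans(Z, centers = k, nstart = 20,
                                                iter.max = 100)$cluster)
        res <- NA_real_
    } else {
        kk <- min(knn, n - 1L)
        D <- as.matrix(stats::dist(Z))
        diag(D) <- Inf
        edges <- do.call(rbind, lapply(seq_len(n), function(i) {
            nb <- order(D[i, ], seq_len(n))[seq_len(kk)]
            cbind(i, nb)
        }))
        edges <- unique(t(apply(edges, 1, sort)))
        gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
        comm <- igraph::cluster_louvain(gr, resolution = resolution)
        labels <- as.integer(igraph::membership(comm))
        k <- NA_real_
        res <- resolution
    }
    ari <- if (is.null(truth)) NA_real_
           else adjustedRandIndex(labels, truth)
    new("ClusteringResult", labels = labels, method = method,
        k = as.numeric(if (is.null(k)) NA else k),
        resolution = as.numeric(res), ari = ari)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions from the
#' pair-counting contingency table; 1 for identical partitions, about 0
#' for independent ones.
#'
#' @param labels,truth equal-length label vectors (any types coercible to
#'   factors).
#' @return A number in \[-1, 1\].
#' @export
adjustedRandIndex <- function(labels, truth) {
    if (length(labels) != length(truth))
        stop(sprintf("length mismatch: %d labels vs %d truth",
                     length(labels), length(truth)))
    mclust::adjustedRandIndex(labels, truth)
}
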