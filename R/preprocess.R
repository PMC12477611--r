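# Per-modality standardisation. Encoders see a variance-stabilised
# transform; decoders always see raw-scale targets (counts, binary
# accessibility, or [0,1]-scaled intensities), which the likelihoods
# require. No size factors enter the ZINB mean: library-size effects are
# handled purely on the encoder side.

.asDenseCounts <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (min(x) < 0) stop("count matrix must be non-negative")
    x
}

.spotFeatureNames <- function(x) {
    list(spots = if (is.null(rownames(x))) paste0("spot", seq_len(nrow(x)))
                 else rownames(x),
         feats = if (is.null(colnames(x))) paste0("f", seq_len(ncol(x)))
                 else colnames(x))
}

#' Preprocess RNA counts
#'
#' Library-size normalisation to a common target, log1p transform, and
#' restriction to the most variable features. The raw counts (subset to
#' the same features) are kept as the ZINB decoder target.
#'
#' @param raw N x d non-negative integer count matrix (spots x genes).
#' @param nTopFeatures number of highly variable genes to keep
#'   (default 3000; all genes kept, order preserved, when `d <= nTopFeatures`).
#' @param targetLibrary library size each spot is scaled to; default the
#'   median library size. Spots with zero counts are kept as zero rows
#'   (a message reports how many).
#' @return An [OmicsMatrix-class] with `modality = "rna"`.
#' @export
preprocessRNA <- function(raw, nTopFeatures = 3000L, targetLibrary = NULL) {
    raw <- .asDenseCounts(raw)
    if (any(raw != round(raw)))
        stop("RNA counts must be integer-valued")
    nm <- .spotFeatureNames(raw)
    lib <- rowSums(raw)
    nzero <- sum(lib == 0)
    if (nzero > 0)
        message(sprintf("preprocessRNA: %d all-zero spot(s) kept as zero rows",
                        nzero))
    if (is.null(targetLibrary)) {
        pos <- lib[lib > 0]
        targetLibrary <- if (length(pos)) stats::median(pos) else 1
    }
    sf <- ifelse(lib > 0, targetLibrary / lib, 0)
    normed <- log1p(raw * sf)
    if (ncol(raw) > nTopFeatures) {
        v <- apply(normed, 2, stats::var)
        keep <- sort(order(v, decreasing = TRUE)[seq_len(nTopFeatures)])
    } else {
        keep <- seq_len(ncol(raw))
    }
    new("OmicsMatrix",
        raw = raw[, keep, drop = FALSE],
        encodedInput = normed[, keep, drop = FALSE],
        modality = "rna",
        featureIds = nm$feats[keep], spotIds = nm$spots)
}

#' Preprocess ATAC accessibility
#'
#' Binarises the counts (the Bernoulli decoder target), drops features
#' that are zero everywhere, and produces the encoder input as a TF-IDF
#' transform with \eqn{idf_j = \log(1 + N/df_j)} followed by per-feature
#' standardisation (zero-variance features map to 0).
#'
#' @param raw N x d non-negative matrix (spots x peaks).
#' @return An [OmicsMatrix-class] with `modality = "atac"`; `raw` holds the
#'   binary matrix.
#' @export
preprocessATAC <- function(raw) {
    raw <- .asDenseCounts(raw)
    nm <- .spotFeatureNames(raw)
    bin <- (raw > 0) * 1
    df <- colSums(bin)
    drop <- df == 0
    if (any(drop)) {
        message(sprintf("preprocessATAC: dropping %d empty feature(s)",
                        sum(drop)))
        bin <- bin[, !drop, drop = FALSE]
        df <- df[!drop]
        nm$feats <- nm$feats[!drop]
    }
    idf <- log(1 + nrow(bin) / df)
    tfidf <- sweep(bin, 2, idf, `*`)
    enc <- scale(tfidf)
    enc[, attr(enc, "scaled:scale") == 0] <- 0
    enc <- enc[, , drop = FALSE]
    attributes(enc)[c("scaled:center", "scaled:scale")] <- NULL
    enc[!is.finite(enc)] <- 0
    new("OmicsMatrix", raw = bin, encodedInput = as.matrix(enc),
        modality = "atac", featureIds = nm$feats, spotIds = nm$spots)
}

#' Preprocess ADT protein counts
#'
#' Centred log-ratio across features within each spot:
#' \eqn{\log1p(x) - \mathrm{mean}(\log1p(x))}. Raw counts are kept
#' untouched as the negative-binomial-mixture decoder target.
#'
#' @param raw N x d non-negative integer count matrix (spots x proteins).
#' @return An [OmicsMatrix-class] with `modality = "adt"`.
#' @export
preprocessADT <- function(raw) {
    raw <- .asDenseCounts(raw)
    if (any(raw != round(raw)))
        stop("ADT counts must be integer-valued")
    nm <- .spotFeatureNames(raw)
    lg <- log1p(raw)
    clr <- lg - rowMeans(lg)
    new("OmicsMatrix", raw = raw, encodedInput = clr,
        modality = "adt", featureIds = nm$feats, spotIds = nm$spots)
}

#' Preprocess an arbitrary non-negative omics matrix
#'
#' Per-feature min-max scaling to \[0,1\]; constant features map to 0 (a
#' message reports how many). The scaled matrix serves as both encoder
#' input and decoder target, as the generic cross-entropy reconstruction
#' requires targets in \[0,1\].
#'
#' @param raw N x d non-negative matrix.
#' @return An [OmicsMatrix-class] with `modality = "other"`.
#' @export
preprocessOther <- function(raw) {
    raw <- .asDenseCounts(raw)
    nm <- .spotFeatureNames(raw)
    mins <- apply(raw, 2, min)
    maxs <- apply(raw, 2, max)
    rng <- maxs - mins
    nconst <- sum(rng == 0)
    if (nconst > 0)
        message(sprintf("preprocessOther: %d constant feature(s) mapped to 0",
                        nconst))
    denom <- ifelse(rng == 0, 1, rng)
    scaled <- sweep(sweep(raw, 2, mins, `-`), 2, denom, `/`)
    scaled[, rng == 0] <- 0
    new("OmicsMatrix", raw = scaled, encodedInput = scaled,
        modality = "other", featureIds = nm$feats, spotIds = nm$spots)
}

#' Dispatch preprocessing by modality tag
#'
#' @param raw matrix; @param modality one of "rna","atac","adt","other".
#' @param ... forwarded to the modality-specific function.
#' @return An [OmicsMatrix-class].
#' @export
preprocessOmics <- function(raw, modality, ...) {
    switch(match.arg(modality, c("rna", "atac", "adt", "other")),
           rna = preprocessRNA(raw, ...),
           atac = preprocessATAC(raw, ...),
           adt = preprocessADT(raw, ...),
           other = preprocessOther(raw, ...))
}
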