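# Per-modality graph convolutional encoder and the parameter-free global
# self-attention refinement. The exported functions operate on plain
# matrices (they are the module surface and the test surface); training
# drives the same math through the gradient tape.

#' Encoder configuration
#'
#' @param hiddenDims widths of the GCN layers; the last entry is the
#'   latent dimension g (default `c(256, 64)`). Hidden layers use the
#'   activation below; the output layer is linear.
#' @param activation activation for hidden layers: "elu" (default),
#'   "relu" or "linear".
#' @param seed integer seed for weight initialisation.
#' @return A list with class `"EncoderConfig"`.
#' @export
encoderConfig <- function(hiddenDims = c(256L, 64L), activation = "elu",
                          seed = 0L) {
    if (any(hiddenDims <= 0)) stop("all layer widths must be positive")
    activation <- match.arg(activation, c("elu", "relu", "linear"))
    structure(list(hiddenDims = as.integer(hiddenDims),
                   latentDim = as.integer(hiddenDims[length(hiddenDims)]),
                   activation = activation, seed = as.integer(seed)),
              class = "EncoderConfig")
}

.activate <- function(x, activation) {
    switch(activation,
           elu = {
               pos <- x > 0
               x * pos + (exp(pmin(x, 0)) - 1) * !pos
           },
           relu = pmax(x, 0),
           linear = x)
}

#' One graph convolution layer
#'
#' Computes `activation(normalized %*% E %*% W)`. There is no bias term.
#'
#' @param E N x p input feature matrix.
#' @param normalized N x N symmetric-normalised graph operator.
#' @param W p x q weight matrix.
#' @param activation "linear" (default), "elu" or "relu".
#' @return N x q matrix.
#' @export
gcnLayer <- function(E, normalized, W, activation = "linear") {
    E <- as.matrix(E); W <- as.matrix(W)
    if (nrow(normalized) != nrow(E))
        stop(sprintf("graph operator is %dx%d but features have %d rows",
                     nrow(normalized), ncol(normalized), nrow(E)))
    if (ncol(E) != nrow(W))
        stop(sprintf("feature width %d does not match weight rows %d",
                     ncol(E), nrow(W)))
    .activate(as.matrix(normalized %*% E %*% W), activation)
}

# Glorot-uniform initialiser; draws from the current RNG stream.
glorotUniform <- function(fanIn, fanOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

# Initialise the stack of GCN weights for one modality.
.initGcnWeights <- function(dIn, hiddenDims) {
    dims <- c(dIn, hiddenDims)
    lapply(seq_len(length(dims) - 1L),
           function(l) glorotUniform(dims[l], dims[l + 1L]))
}

#' Encode one modality with the GCN
#'
#' Stacks [gcnLayer()] over `cfg$hiddenDims` (hidden layers activated,
#' output linear) with Glorot-uniform weights drawn from a seeded RNG, so
#' the same seed always yields the same embedding.
#'
#' @param x an [OmicsMatrix-class] or a plain N x d matrix of encoder input.
#' @param graph a [SpatialGraph-class] with its normalised operator built.
#' @param cfg an [encoderConfig()].
#' @param weights optional list of pre-initialised weight matrices (used
#'   by training); when NULL, fresh Glorot weights are drawn from
#'   `cfg$seed`.
#' @return N x g embedding matrix E.
#' @export
gcnEncode <- function(x, graph, cfg = encoderConfig(), weights = NULL) {
    X <- if (is(x, "OmicsMatrix")) x@encodedInput else as.matrix(x)
    S <- graphNormalized(graph)
    if (is.null(weights)) {
        withr_seed <- cfg$seed
        old <- globalenv()$.Random.seed
        set.seed(withr_seed)
        weights <- .initGcnWeights(ncol(X), cfg$hiddenDims)
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    H <- X
    nL <- length(weights)
    for (l in seq_len(nL)) {
        act <- if (l < nL) cfg$activation else "linear"
        H <- gcnLayer(H, S, weights[[l]], act)
        if (anyNA(H) || any(!is.finite(H)))
            stop(sprintf("non-finite values after GCN layer %d", l))
    }
    H
}

#' Parameter-free global self-attention
#'
#' Returns `softmax(E %*% t(E) / sqrt(g)) %*% E` with a numerically
#' stabilised row-wise softmax; every attention row sums to 1. There are
#' no learned query/key/value projections.
#'
#' @param E N x g embedding matrix.
#' @return N x g refined embedding.
#' @export
selfAttention <- function(E) {
    E <- as.matrix(E)
    if (ncol(E) < 1L) stop("embedding must have at least one column")
    tape <- agTape()
    agValue(agAttention(agLeaf(tape, E)))
}

# attention weight matrix itself (for tests / inspection)
attentionWeights <- function(E) {
    E <- as.matrix(E)
    S <- tcrossprod(E) / sqrt(ncol(E))
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A / rowSums(A)
}
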