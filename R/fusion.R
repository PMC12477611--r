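# Intra-omics specificity (omics label prediction), inter-omics common
# space with a Gram-matrix commonality constraint, the weighted joint
# representation, and the spatial proximity regulariser. All exported
# functions are pure matrix functions; training drives the identical math
# through the gradient tape so values here and in training agree exactly.

#' Fusion weights
#'
#' @param alpha,beta,gamma non-negative weights on the two attention-refined
#'   modality embeddings and the cross-omics common feature (default 1/3
#'   each; their sum must be positive).
#' @return A list with class `"FusionWeights"`.
#' @export
fusionWeights <- function(alpha = 1/3, beta = 1/3, gamma = 1/3) {
    if (alpha < 0 || beta < 0 || gamma < 0 || alpha + beta + gamma <= 0)
        stop("fusion weights must be non-negative with a positive sum")
    structure(list(alpha = alpha, beta = beta, gamma = gamma),
              class = "FusionWeights")
}

#' Omics-label prediction loss
#'
#' Stacks the two attention-refined embeddings into a 2N x g matrix,
#' labels rows by their modality of origin (0 for modality 1, 1 for
#' modality 2), applies a fully connected two-class head and returns the
#' mean cross-entropy against the construction labels. Minimising this
#' jointly with the encoders rewards embeddings that retain
#' modality-specific character.
#'
#' @param EA1,EA2 N x g matrices.
#' @param head list with `W` (g x 2) and `b` (length 2) head parameters.
#' @return Non-negative scalar; equals `log(2)` for an uninformative head.
#' @export
omicsLabelLoss <- function(EA1, EA2, head) {
    EA1 <- as.matrix(EA1); EA2 <- as.matrix(EA2)
    stopifnot(ncol(EA1) == ncol(EA2))
    tape <- agTape()
    eAll <- agRbind(agLeaf(tape, EA1), agLeaf(tape, EA2))
    logits <- agAddBias(agMatmul(eAll, agLeaf(tape, as.matrix(head$W))),
                        agLeaf(tape, as.numeric(head$b)))
    labels <- c(rep(0L, nrow(EA1)), rep(1L, nrow(EA2)))
    agValue(agSoftmaxCE(logits, labels))
}

#' Project an embedding into the shared space
#'
#' `relu(E %*% W + b)`; all outputs are non-negative.
#'
#' @param E N x g matrix; @param W g x g weights; @param b length-g bias.
#' @return N x g non-negative matrix.
#' @export
projectCommon <- function(E, W, b) {
    v <- sweep(as.matrix(E) %*% as.matrix(W), 2, as.numeric(b), `+`)
    pmax(v, 0)
}

#' Fuse the two common-space projections
#'
#' Row-wise affine map of the feature-concatenated projections:
#' `cbind(C1, C2) %*% W + b` (linear, no activation).
#'
#' @param C1,C2 N x g matrices; @param W 2g x g weights; @param b length-g
#'   bias.
#' @return N x g common feature matrix.
#' @export
fuseCommon <- function(C1, C2, W, b) {
    C1 <- as.matrix(C1); C2 <- as.matrix(C2)
    stopifnot(nrow(C1) == nrow(C2))
    sweep(cbind(C1, C2) %*% as.matrix(W), 2, as.numeric(b), `+`)
}

#' Gram-matrix commonality loss
#'
#' Rows of each projection are L2-normalised (zero rows stay zero); the
#' loss is the squared Frobenius norm of the difference of the two
#' row-normalised Gram matrices, divided by N^2 so it is invariant to the
#' number of spots. Zero iff the normalised Gram matrices coincide; in
#' particular invariant to any right-orthogonal rotation of either input.
#'
#' @param C1,C2 N x g matrices.
#' @return Non-negative scalar.
#' @export
commonalityLoss <- function(C1, C2) {
    C1 <- as.matrix(C1); C2 <- as.matrix(C2)
    stopifnot(nrow(C1) == nrow(C2))
    tape <- agTape()
    agValue(agCommonalityLoss(agLeaf(tape, C1), agLeaf(tape, C2)))
}

#' Weighted joint representation
#'
#' `Z = alpha * EA1 + beta * EA2 + gamma * EC`.
#'
#' @param EA1,EA2,EC N x g matrices of identical shape.
#' @param weights a [fusionWeights()] object (or list with alpha, beta,
#'   gamma).
#' @return N x g joint representation matrix.
#' @export
combineRepresentations <- function(EA1, EA2, EC,
                                   weights = fusionWeights()) {
    EA1 <- as.matrix(EA1); EA2 <- as.matrix(EA2); EC <- as.matrix(EC)
    if (!all(dim(EA1) == dim(EA2)) || !all(dim(EA1) == dim(EC)))
        stop(sprintf("shapes differ: EA1 %dx%d, EA2 %dx%d, EC %dx%d",
                     nrow(EA1), ncol(EA1), nrow(EA2), ncol(EA2),
                     nrow(EC), ncol(EC)))
    weights$alpha * EA1 + weights$beta * EA2 + weights$gamma * EC
}

#' Spatial proximity regulariser
#'
#' Embedding similarity is \eqn{Q_{ij} = \exp(-\|Z_i - Z_j\|^2 /
#' (2\sigma_z^2))} with \eqn{\sigma_z} the median pairwise embedding
#' distance; the loss is \eqn{\sum_{ij} P_{ij} (1 - Q_{ij}) / N^2}. In the
#' default mode `proximity` is the Gaussian spatial kernel (sparse, entries
#' in \[0,1\]), so spots that are spatially close but far apart in the
#' embedding are penalised; `mode = "literal"` instead weights pairs by a
#' raw spatial distance matrix.
#'
#' @param proximity N x N symmetric matrix: sparse kernel weights
#'   (default mode) or dense distances (`literal`).
#' @param Z N x g embedding matrix.
#' @param mode "kernel" (default) or "literal".
#' @return Non-negative scalar; zero when all embedding rows coincide or
#'   when `proximity` has no nonzero entries.
#' @export
spatialRegularization <- function(proximity, Z, mode = c("kernel", "literal")) {
    mode <- match.arg(mode)
    Z <- as.matrix(Z)
    tape <- agTape()
    zn <- agLeaf(tape, Z)
    if (mode == "kernel") {
        P <- methods::as(Matrix(proximity, sparse = TRUE), "CsparseMatrix")
        agValue(agSpatialReg(zn, P))
    } else {
        agValue(agSpatialRegLiteral(zn, as.matrix(proximity)))
    }
}
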