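#' @import methods
#' @importFrom Matrix Matrix t rowSums colSums bdiag Diagonal sparseMatrix
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Spot coordinates for one or more tissue slices
#'
#' Holds the physical (x, y) positions of N spots or cells, their unique
#' identifiers, and an optional slice assignment for multi-slice designs.
#'
#' @slot positions N x 2 numeric matrix of physical coordinates.
#' @slot spotIds character vector of N unique spot identifiers.
#' @slot sliceIds optional character vector of N slice labels, or NULL.
#'
#' @seealso [CoordinateTable()], [buildSpatialGraph()]
#' @export
setClass("CoordinateTable",
    slots = c(positions = "matrix",
              spotIds = "character",
              sliceIds = "characterOrNULL"))

setValidity("CoordinateTable", function(object) {
    msg <- NULL
    if (ncol(object@positions) != 2L)
        msg <- c(msg, "'positions' must have exactly 2 columns")
    if (anyNA(object@positions))
        msg <- c(msg, "'positions' must not contain NA/NaN")
    n <- nrow(object@positions)
    if (n < 2L)
        msg <- c(msg, "at least 2 spots are required")
    if (length(object@spotIds) != n)
        msg <- c(msg, "'spotIds' length must equal nrow(positions)")
    if (anyDuplicated(object@spotIds))
        msg <- c(msg, "'spotIds' must be unique")
    if (!is.null(object@sliceIds) && length(object@sliceIds) != n)
        msg <- c(msg, "'sliceIds' length must equal nrow(positions)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CoordinateTable
#'
#' @param positions N x 2 numeric matrix (or data.frame) of coordinates.
#' @param spotIds character vector of unique spot identifiers; defaults to
#'   rownames of `positions` or `spot1..spotN`.
#' @param sliceIds optional slice labels for multi-slice input.
#' @return A [CoordinateTable-class] object.
#' @examples
#' ct <- CoordinateTable(cbind(x = c(0, 1, 0), y = c(0, 0, 1)))
#' ct
#' @export
CoordinateTable <- function(positions, spotIds = NULL, sliceIds = NULL) {
    positions <- as.matrix(positions)
    storage.mode(positions) <- "double"
    if (is.null(spotIds)) {
        spotIds <- rownames(positions)
        if (is.null(spotIds))
            spotIds <- paste0("spot", seq_len(nrow(positions)))
    }
    rownames(positions) <- spotIds
    new("CoordinateTable", positions = positions,
        spotIds = as.character(spotIds),
        sliceIds = if (is.null(sliceIds)) NULL else as.character(sliceIds))
}

setMethod("show", "CoordinateTable", function(object) {
    cat("CoordinateTable with", nrow(object@positions), "spots")
    if (!is.null(object@sliceIds))
        cat(" across", length(unique(object@sliceIds)), "slice(s)")
    cat("\n")
})

#' Gaussian-kernel spatial neighbourhood graph
#'
#' Sparse symmetric adjacency over spots with edge weights
#' \eqn{A_{ij} = \exp(-d(i,j)^2 / (2\lambda^2))} retained on the mutual-max
#' symmetrised k-nearest-neighbour relation, plus the symmetric-normalised
#' operator \eqn{\tilde D^{-1/2}(A + I)\tilde D^{-1/2}} consumed by the
#' graph convolutional encoder.
#'
#' @slot weights N x N symmetric non-negative sparse adjacency (zero diagonal).
#' @slot normalized N x N symmetric-normalised operator with self-loops, or
#'   a 0 x 0 placeholder before [normalizeAdjacency()] is called.
#' @slot lambda positive kernel bandwidth (in coordinate units).
#' @slot kNeighbors sparsification degree used at construction.
#' @slot spotIds spot identifiers in row order.
#' @export
setClass("SpatialGraph",
    slots = c(weights = "Matrix",
              normalized = "Matrix",
              lambda = "numeric",
              kNeighbors = "integer",
              spotIds = "character"))

setValidity("SpatialGraph", function(object) {
    msg <- NULL
    W <- object@weights
    if (nrow(W) != ncol(W))
        msg <- c(msg, "'weights' must be square")
    if (max(abs(W - Matrix::t(W))) > 1e-9)
        msg <- c(msg, "'weights' must be symmetric within 1e-9")
    rng <- if (length(W@x)) range(W@x) else c(0, 0)
    if (rng[1] < 0 || rng[2] > 1 + 1e-12)
        msg <- c(msg, "'weights' entries must lie in [0, 1]")
    if (length(object@lambda) != 1L || object@lambda <= 0)
        msg <- c(msg, "'lambda' must be a single positive number")
    Nn <- nrow(object@normalized)
    if (Nn > 0 && Nn != nrow(W))
        msg <- c(msg, "'normalized' dimension must match 'weights'")
    if (Nn > 0 &&
        max(abs(object@normalized - Matrix::t(object@normalized))) > 1e-9)
        msg <- c(msg, "'normalized' must be symmetric within 1e-9")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SpatialGraph", function(object) {
    n <- nrow(object@weights)
    ne <- length(object@weights@x) / 2
    cat(sprintf("SpatialGraph: %d spots, %.0f undirected edges, lambda=%.4g, k=%d\n",
                n, ne, object@lambda, object@kNeighbors))
    cat(if (nrow(object@normalized) > 0) "  normalized operator: built\n"
        else "  normalized operator: not built (see normalizeAdjacency)\n")
})

#' A single preprocessed omics modality
#'
#' Carries the decoder-facing raw matrix (counts, binarised accessibility,
#' or [0,1]-scaled intensities depending on the modality) alongside the
#' transformed matrix fed to the graph convolutional encoder.
#'
#' @slot raw N x d numeric matrix, decoder reconstruction target.
#' @slot encodedInput N x d' numeric matrix, encoder input.
#' @slot modality one of "rna", "atac", "adt", "other".
#' @slot featureIds feature identifiers (columns of `raw`).
#' @slot spotIds spot identifiers (rows).
#' @export
setClass("OmicsMatrix",
    slots = c(raw = "matrix",
              encodedInput = "matrix",
              modality = "character",
              featureIds = "character",
              spotIds = "character"))

setValidity("OmicsMatrix", function(object) {
    msg <- NULL
    if (!object@modality %in% c("rna", "atac", "adt", "other"))
        msg <- c(msg, "'modality' must be rna, atac, adt or other")
    if (min(object@raw) < 0)
        msg <- c(msg, "'raw' must be non-negative")
    if (anyNA(object@encodedInput) || any(!is.finite(object@encodedInput)))
        msg <- c(msg, "'encodedInput' must be finite with no NA")
    if (nrow(object@raw) != nrow(object@encodedInput))
        msg <- c(msg, "'raw' and 'encodedInput' must share rows (spots)")
    if (length(object@featureIds) != ncol(object@raw))
        msg <- c(msg, "'featureIds' must match ncol(raw)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "OmicsMatrix", function(object) {
    cat(sprintf("OmicsMatrix [%s]: %d spots x %d features (encoder input: %d features)\n",
                object@modality, nrow(object@raw), ncol(object@raw),
                ncol(object@encodedInput)))
})

#' Two aligned spatial omics modalities plus coordinates
#'
#' @slot omics1,omics2 [OmicsMatrix-class] objects over the same spots in
#'   the same order.
#' @slot coords [CoordinateTable-class] for the shared spots.
#' @slot aligned TRUE once spot identifiers have been intersected/reordered.
#' @export
setClass("SpatialOmicsPair",
    slots = c(omics1 = "OmicsMatrix",
              omics2 = "OmicsMatrix",
              coords = "CoordinateTable",
              aligned = "logical"))

setValidity("SpatialOmicsPair", function(object) {
    msg <- NULL
    n <- nrow(object@coords@positions)
    if (nrow(object@omics1@raw) != n || nrow(object@omics2@raw) != n)
        msg <- c(msg, "both omics and coords must share the same N")
    if (!identical(object@omics1@spotIds, object@omics2@spotIds) ||
        !identical(object@omics1@spotIds, object@coords@spotIds))
        msg <- c(msg, "spot identifiers must be identical and in the same order")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SpatialOmicsPair
#'
#' @param omics1,omics2 [OmicsMatrix-class] objects.
#' @param coords a [CoordinateTable-class].
#' @param aligned whether spots are known to be aligned (default TRUE;
#'   [loadPair()] performs the alignment for on-disk input).
#' @return A [SpatialOmicsPair-class].
#' @export
SpatialOmicsPair <- function(omics1, omics2, coords, aligned = TRUE) {
    new("SpatialOmicsPair", omics1 = omics1, omics2 = omics2,
        coords = coords, aligned = aligned)
}

setMethod("show", "SpatialOmicsPair", function(object) {
    cat("SpatialOmicsPair over", nrow(object@coords@positions), "spots\n")
    show(object@omics1); show(object@omics2)
})

#' Fused multi-omics representation
#'
#' The joint N x g representation \eqn{Z = \alpha E_{A1} + \beta E_{A2} +
#' \gamma E_C} produced by training, with the cross-omics common feature
#' and the per-epoch loss trace.
#'
#' @slot Z N x g joint representation used for clustering.
#' @slot EC N x g cross-omics common feature (0 x 0 in single-modality mode).
#' @slot lossTrace data.frame with one row per epoch (total and components).
#' @slot spotIds spot identifiers in row order.
#' @slot model internal list of trained parameters and settings.
#' @export
setClass("JointRepresentation",
    slots = c(Z = "matrix",
              EC = "matrix",
              lossTrace = "data.frame",
              spotIds = "character",
              model = "list"))

setValidity("JointRepresentation", function(object) {
    msg <- NULL
    if (anyNA(object@Z) || any(!is.finite(object@Z)))
        msg <- c(msg, "'Z' must be finite with no NA")
    if (length(object@spotIds) != nrow(object@Z))
        msg <- c(msg, "'spotIds' must match nrow(Z)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "JointRepresentation", function(object) {
    cat(sprintf("JointRepresentation: %d spots x %d dims", nrow(object@Z),
                ncol(object@Z)))
    if (nrow(object@lossTrace) > 0)
        cat(sprintf("; %d epochs, final loss %.4g",
                    nrow(object@lossTrace),
                    object@lossTrace$total[nrow(object@lossTrace)]))
    cat("\n")
})

#' Spatial clustering result
#'
#' @slot labels integer cluster labels, one per spot, in spot order.
#' @slot method "kmeans" or "louvain".
#' @slot k number of clusters requested (kmeans) or NA.
#' @slot resolution Louvain resolution or NA.
#' @slot ari adjusted Rand index versus ground truth if supplied, else NA.
#' @export
setClass("ClusteringResult",
    slots = c(labels = "integer",
              method = "character",
              k = "numeric",
              resolution = "numeric",
              ari = "numeric"))

setMethod("show", "ClusteringResult", function(object) {
    cat(sprintf("ClusteringResult [%s]: %d spots, %d clusters",
                object@method, length(object@labels),
                length(unique(object@labels))))
    if (!is.na(object@ari)) cat(sprintf(", ARI = %.3f", object@ari))
    cat("\n")
})

# ---- accessors ----

#' Accessors for smofuse classes
#'
#' `graphWeights`/`graphNormalized` return the sparse adjacency and the
#' normalised operator; `jointEmbedding` the fused N x g matrix;
#' `lossTrace` the per-epoch loss table; `clusterLabels` the integer
#' labels; `spotIds` the spot identifiers of any spot-indexed object.
#'
#' @param object a smofuse S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("graphWeights", function(object) standardGeneric("graphWeights"))
#' @rdname accessors
#' @export
setMethod("graphWeights", "SpatialGraph", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("graphNormalized",
           function(object) standardGeneric("graphNormalized"))
#' @rdname accessors
#' @export
setMethod("graphNormalized", "SpatialGraph", function(object) {
    if (nrow(object@normalized) == 0)
        stop("normalized operator not built; call normalizeAdjacency() first")
    object@normalized
})

#' @rdname accessors
#' @export
setGeneric("jointEmbedding", function(object) standardGeneric("jointEmbedding"))
#' @rdname accessors
#' @export
setMethod("jointEmbedding", "JointRepresentation", function(object) object@Z)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setMethod("lossTrace", "JointRepresentation", function(object) object@lossTrace)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusteringResult", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("spotIds", function(object) standardGeneric("spotIds"))
#' @rdname accessors
#' @export
setMethod("spotIds", "CoordinateTable", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "SpatialGraph", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "OmicsMatrix", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "SpatialOmicsPair", function(object) object@coords@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "JointRepresentation", function(object) object@spotIds)
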