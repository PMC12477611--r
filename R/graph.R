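# All graph matrices are kept in general (not symmetric-triangle) sparse
# storage so that entry counts and triplet walks see every nonzero.
.asGeneralC <- function(M) {
    methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
}

# Spatial neighbourhood graph: Gaussian kernel over physical distances,
# sparsified to a mutual-max symmetrised kNN relation, plus the
# symmetric-normalised operator with self-loops used by the GCN.

#' Build the Gaussian-kernel spatial graph
#'
#' Each spot is connected to its `kNeighbors` nearest spots (Euclidean
#' distance on the physical coordinates); the directed kNN relation is
#' symmetrised by mutual maximum, and retained edges are weighted
#' \eqn{A_{ij} = \exp(-d(i,j)^2/(2\lambda^2))}. Non-edges are exactly
#' zero and the diagonal of `weights` is zero: self-loops enter only
#' through the normalised operator \eqn{\tilde A = A + I}.
#'
#' When `sliceIds` are present with more than one slice, each slice's graph
#' is built independently and assembled block-diagonally (no cross-slice
#' edges), preserving the original spot order.
#'
#' @param coords a [CoordinateTable-class], or an N x 2 matrix/data.frame.
#' @param lambda positive kernel bandwidth in coordinate units. The default
#'   (`NULL`) sets `lambda` to the median nearest-neighbour distance, which
#'   makes the kernel scale-free: rescaling all coordinates leaves the
#'   weights unchanged.
#' @param kNeighbors number of nearest neighbours per spot (default 6,
#'   matching a hexagonal Visium-like lattice). Use `N - 1` for the dense
#'   all-pairs kernel.
#' @param normalize build the normalised operator immediately (default TRUE).
#' @return A [SpatialGraph-class].
#' @examples
#' ct <- CoordinateTable(expand.grid(x = 0:2, y = 0:2))
#' g <- buildSpatialGraph(ct, lambda = 1, kNeighbors = 8)
#' max(abs(graphWeights(g) - Matrix::t(graphWeights(g))))
#' @export
buildSpatialGraph <- function(coords, lambda = NULL, kNeighbors = 6L,
                              normalize = TRUE) {
    if (!is(coords, "CoordinateTable"))
        coords <- CoordinateTable(coords)
    n <- nrow(coords@positions)
    kNeighbors <- as.integer(kNeighbors)
    if (kNeighbors < 1L)
        stop("'kNeighbors' must be a positive integer")
    if (n < kNeighbors + 1L)
        stop(sprintf(
            "need at least kNeighbors + 1 = %d spots but only %d supplied (%d short)",
            kNeighbors + 1L, n, kNeighbors + 1L - n))

    slices <- coords@sliceIds
    if (!is.null(slices) && length(unique(slices)) > 1L) {
        ord <- seq_len(n)
        graphs <- lapply(unique(slices), function(s) {
            idx <- which(slices == s)
            buildSpatialGraph(CoordinateTable(
                coords@positions[idx, , drop = FALSE],
                coords@spotIds[idx]), lambda = lambda,
                kNeighbors = kNeighbors, normalize = FALSE)
        })
        g <- blockDiagGraph(graphs)
        # restore original spot order
        perm <- match(coords@spotIds, g@spotIds)
        W <- g@weights[perm, perm, drop = FALSE]
        g <- new("SpatialGraph", weights = W,
                 normalized = methods::as(Matrix(0, 0, 0), "CsparseMatrix"),
                 lambda = g@lambda, kNeighbors = kNeighbors,
                 spotIds = coords@spotIds)
        if (normalize) g <- normalizeAdjacency(g)
        return(g)
    }

    D <- as.matrix(stats::dist(coords@positions))
    if (is.null(lambda)) {
        nnDist <- apply(D + diag(Inf, n), 1, min)
        lambda <- stats::median(nnDist)
        if (!is.finite(lambda) || lambda <= 0) lambda <- 1
    }
    if (lambda <= 0) stop("'lambda' must be positive")

    # kNN sets per spot (self excluded); ties broken by index for determinism
    keep <- matrix(FALSE, n, n)
    Dself <- D + diag(Inf, n)
    for (i in seq_len(n)) {
        nb <- order(Dself[i, ], seq_len(n))[seq_len(kNeighbors)]
        keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)             # mutual-max symmetrisation
    K <- exp(-D^2 / (2 * lambda^2))
    K[!keep] <- 0
    diag(K) <- 0
    W <- .asGeneralC(Matrix(K, sparse = TRUE))
    dimnames(W) <- list(coords@spotIds, coords@spotIds)

    g <- new("SpatialGraph", weights = W,
             normalized = methods::as(Matrix(0, 0, 0), "CsparseMatrix"),
             lambda = lambda, kNeighbors = kNeighbors,
             spotIds = coords@spotIds)
    if (normalize) g <- normalizeAdjacency(g)
    g
}

#' Symmetric normalisation of the adjacency with self-loops
#'
#' Computes \eqn{\tilde D^{-1/2} (A + I) \tilde D^{-1/2}} where
#' \eqn{\tilde D} is the diagonal degree of \eqn{A + I}. An edgeless graph
#' normalises to the identity; the self-loop guarantees every degree is at
#' least 1, so the operation is always defined.
#'
#' @param graph a [SpatialGraph-class].
#' @return The graph with its `normalized` slot filled.
#' @export
normalizeAdjacency <- function(graph) {
    stopifnot(is(graph, "SpatialGraph"))
    n <- nrow(graph@weights)
    Atil <- graph@weights + Diagonal(n)
    dinv <- 1 / sqrt(Matrix::rowSums(Atil))
    Dm <- Diagonal(n, dinv)
    Nrm <- Dm %*% Atil %*% Dm
    Nrm <- (Nrm + Matrix::t(Nrm)) / 2   # kill 1e-16 asymmetry from roundoff
    graph@normalized <- .asGeneralC(Nrm)
    graph
}

#' Assemble per-slice graphs into a block-diagonal multi-slice graph
#'
#' Concatenates the adjacency matrices of independent slices along the
#' diagonal, with no cross-slice edges. Normalising the assembly equals
#' assembling the per-slice normalisations, since degrees never cross
#' blocks.
#'
#' @param graphs a non-empty list of [SpatialGraph-class] objects.
#' @return A single [SpatialGraph-class] over the concatenated spots.
#' @export
blockDiagGraph <- function(graphs) {
    if (!is.list(graphs) || length(graphs) == 0)
        stop("'graphs' must be a non-empty list of SpatialGraph objects")
    stopifnot(all(vapply(graphs, is, logical(1), "SpatialGraph")))
    if (length(graphs) == 1L) return(graphs[[1]])
    W <- .asGeneralC(bdiag(lapply(graphs, graphWeights)))
    W <- (W + Matrix::t(W)) / 2
    ids <- unlist(lapply(graphs, spotIds), use.names = FALSE)
    if (anyDuplicated(ids))
        ids <- make.unique(ids)
    dimnames(W) <- list(ids, ids)
    lambdas <- vapply(graphs, function(g) g@lambda, numeric(1))
    g <- new("SpatialGraph", weights = W,
             normalized = methods::as(Matrix(0, 0, 0), "CsparseMatrix"),
             lambda = stats::median(lambdas),
             kNeighbors = graphs[[1]]@kNeighbors,
             spotIds = ids)
    normalizeAdjacency(g)
}

#' Export the graph as an edge list
#'
#' @param graph a [SpatialGraph-class].
#' @param file optional path; when given, a 3-column TSV (i, j, weight) is
#'   written and the path returned invisibly.
#' @return A data.frame with columns `i`, `j`, `weight` (each undirected
#'   edge listed once, i < j).
#' @export
graphEdgeList <- function(graph, file = NULL) {
    W <- methods::as(graphWeights(graph), "TsparseMatrix")
    sel <- W@i < W@j
    df <- data.frame(i = graph@spotIds[W@i[sel] + 1L],
                     j = graph@spotIds[W@j[sel] + 1L],
                     weight = W@x[sel], stringsAsFactors = FALSE)
    df <- df[order(df$i, df$j), , drop = FALSE]
    rownames(df) <- NULL
    if (!is.null(file)) {
        utils::write.table(df, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(file))
    }
    df
}
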