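# Synthetic spatial multi-omics generator. Domains are contiguous regions
# on a lattice; counts are drawn from the same families the decoders
# assume (ZINB for RNA, Bernoulli for accessibility, a log-normal
# background/foreground NB mixture for ADT), so every stage of the model
# can be validated against a known ground truth without any download.

#' Synthetic data specification
#'
#' Defaults encode the study conditions used throughout the package's
#' validation: disjoint marker blocks per domain with RNA fold-change 4
#' over baseline, accessibility 0.8 versus 0.1, and ADT foreground fold 5
#' — strong enough for stable desk-scale benchmarks, weak enough that
#' sampling noise matters.
#'
#' @param gridShape c(rows, cols) of the lattice.
#' @param nDomains number of spatial domains k (>= 2).
#' @param geometry "blocks", "stripes" or "voronoi".
#' @param rna list: nGenes, markersPerDomain, muBase, fold, theta, dropout.
#' @param atac list: nPeaks, markersPerDomain, pOn, pOff.
#' @param adt list: nProteins, markersPerDomain, bgMeanlog, bgSdlog, fold,
#'   phi, bgProb.
#' @param seed integer seed.
#' @return A list with class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(gridShape = c(20L, 20L), nDomains = 4L,
                          geometry = c("blocks", "stripes", "voronoi"),
                          rna = list(), atac = list(), adt = list(),
                          seed = 0L) {
    geometry <- match.arg(geometry)
    if (nDomains < 2) stop("'nDomains' must be >= 2")
    rnaDef <- list(nGenes = 200L, markersPerDomain = 20L, muBase = 1,
                   fold = 4, theta = 2, dropout = 0.1)
    atacDef <- list(nPeaks = 200L, markersPerDomain = 20L, pOn = 0.8,
                    pOff = 0.1)
    adtDef <- list(nProteins = 30L, markersPerDomain = 5L,
                   bgMeanlog = log(5), bgSdlog = 0.4, fold = 5, phi = 3,
                   bgProb = 0.25)
    structure(list(gridShape = as.integer(gridShape),
                   nDomains = as.integer(nDomains), geometry = geometry,
                   rna = utils::modifyList(rnaDef, rna),
                   atac = utils::modifyList(atacDef, atac),
                   adt = utils::modifyList(adtDef, adt),
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

#' Generate lattice coordinates with contiguous domains
#'
#' @param spec a [syntheticSpec()].
#' @return List with `coords` (a [CoordinateTable-class] over the
#'   rows x cols lattice) and integer `labels` in 1..k; deterministic per
#'   `spec$seed`.
#' @export
generateDomains <- function(spec) {
    rows <- spec$gridShape[1]; cols <- spec$gridShape[2]
    k <- spec$nDomains
    n <- rows * cols
    if (k > n) stop("more domains than lattice cells")
    grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
    x <- grid$col; y <- grid$row
    set.seed(spec$seed)
    labels <- switch(spec$geometry,
        stripes = pmin(ceiling(x / (cols / k)), k),
        blocks = {
            kr <- max(1L, floor(sqrt(k)))
            kc <- ceiling(k / kr)
            rg <- pmin(ceiling(y / (rows / kr)), kr)
            cg <- pmin(ceiling(x / (cols / kc)), kc)
            pmin((rg - 1L) * kc + cg, k)
        },
        voronoi = {
            for (try in seq_len(100L)) {
                cx <- stats::runif(k, 1, cols)
                cy <- stats::runif(k, 1, rows)
                d2 <- outer(x, cx, `-`)^2 + outer(y, cy, `-`)^2
                lab <- max.col(-d2, ties.method = "first")
                if (length(unique(lab)) == k) break
            }
            lab
        })
    labels <- as.integer(labels)
    if (length(unique(labels)) < k)
        stop("failed to occupy every domain; enlarge the grid")
    coords <- CoordinateTable(cbind(x = as.numeric(x), y = as.numeric(y)),
                              spotIds = sprintf("spot%04d", seq_len(n)))
    list(coords = coords, labels = labels)
}

.markerIndex <- function(nFeatures, nGroups, markersPerGroup) {
    if (nGroups * markersPerGroup > nFeatures)
        stop("not enough features for disjoint marker blocks")
    lapply(seq_len(nGroups), function(g)
        seq_len(markersPerGroup) + (g - 1L) * markersPerGroup)
}

#' Simulate ZINB RNA counts
#'
#' Each domain's marker genes have mean `muBase * fold`, all other genes
#' `muBase`; entries are NB(mu, theta) draws zeroed with probability
#' `dropout`.
#'
#' @param labels integer domain labels (any grouping; the complementary
#'   benchmark passes a coarser grouping than the true domains).
#' @param spec a [syntheticSpec()] (fields under `$rna` are used).
#' @return N x nGenes integer count matrix.
#' @export
simulateRNA <- function(labels, spec) {
    p <- spec$rna
    groups <- sort(unique(labels))
    mk <- .markerIndex(p$nGenes, length(groups), p$markersPerDomain)
    n <- length(labels)
    mu <- matrix(p$muBase, n, p$nGenes)
    for (gi in seq_along(groups))
        mu[labels == groups[gi], mk[[gi]]] <- p$muBase * p$fold
    counts <- matrix(stats::rnbinom(n * p$nGenes, size = p$theta, mu = mu),
                     n, p$nGenes)
    if (p$dropout > 0)
        counts <- counts *
            (matrix(stats::runif(n * p$nGenes), n, p$nGenes) >= p$dropout)
    dimnames(counts) <- list(sprintf("spot%04d", seq_len(n)),
                             sprintf("gene%03d", seq_len(p$nGenes)))
    counts
}

#' Simulate Bernoulli accessibility
#'
#' Marker peaks of a domain are open with probability `pOn`, all other
#' peaks with `pOff`.
#'
#' @inheritParams simulateRNA
#' @return N x nPeaks binary matrix.
#' @export
simulateATAC <- function(labels, spec) {
    p <- spec$atac
    groups <- sort(unique(labels))
    mk <- .markerIndex(p$nPeaks, length(groups), p$markersPerDomain)
    n <- length(labels)
    pr <- matrix(p$pOff, n, p$nPeaks)
    for (gi in seq_along(groups))
        pr[labels == groups[gi], mk[[gi]]] <- p$pOn
    x <- matrix(stats::rbinom(n * p$nPeaks, 1, pr), n, p$nPeaks)
    dimnames(x) <- list(sprintf("spot%04d", seq_len(n)),
                        sprintf("peak%03d", seq_len(p$nPeaks)))
    x
}

#' Simulate ADT counts from the background/foreground NB mixture
#'
#' Per entry: a background intensity `nu_b` is drawn log-normally, the
#' foreground is `fold * nu_b` for the domain's marker proteins (fold 1
#' elsewhere), the background branch is chosen with probability `bgProb`,
#' and the count is NB(chosen mean, phi).
#'
#' @inheritParams simulateRNA
#' @return N x nProteins integer count matrix.
#' @export
simulateADT <- function(labels, spec) {
    p <- spec$adt
    groups <- sort(unique(labels))
    mk <- .markerIndex(p$nProteins, length(groups), p$markersPerDomain)
    n <- length(labels)
    fold <- matrix(1, n, p$nProteins)
    for (gi in seq_along(groups))
        fold[labels == groups[gi], mk[[gi]]] <- p$fold
    nuB <- matrix(stats::rlnorm(n * p$nProteins, p$bgMeanlog, p$bgSdlog),
                  n, p$nProteins)
    isBg <- matrix(stats::rbinom(n * p$nProteins, 1, p$bgProb),
                   n, p$nProteins)
    mu <- ifelse(isBg == 1, nuB, fold * nuB)
    x <- matrix(stats::rnbinom(n * p$nProteins, size = p$phi, mu = mu),
                n, p$nProteins)
    dimnames(x) <- list(sprintf("spot%04d", seq_len(n)),
                        sprintf("prot%02d", seq_len(p$nProteins)))
    x
}

.bundle <- function(pair, truth, spec) {
    stopifnot(all(tabulate(truth) >= 1))
    structure(list(pair = pair, truth = truth, spec = spec),
              class = "SyntheticBundle")
}

#' Complementary four-domain benchmark
#'
#' Four domains on a 2 x 2 block layout (44 x 46 lattice, 2024 spots,
#' 506 per domain).
#' RNA markers differ only across the top/bottom split (domains {1,2}
#' versus {3,4}); ATAC markers only across the left/right split ({1,3}
#' versus {2,4}). Each single modality can therefore resolve at most a
#' two-way partition, and only the fusion can identify all four domains —
#' the testable core of the multi-omics complementarity claim.
#'
#' @param seed integer seed (drives domain layout and all draws).
#' @param gridShape lattice size (default c(44, 46)).
#' @param nGenes,nPeaks feature counts for the two modalities (default
#'   150 each).
#' @return A `SyntheticBundle` list: `pair` (preprocessed
#'   [SpatialOmicsPair-class] of RNA + ATAC), integer `truth` labels, and
#'   the `spec`.
#' @export
makeComplementaryBenchmark <- function(seed = 0L, gridShape = c(44L, 46L),
                                       nGenes = 150L, nPeaks = 150L) {
    spec <- syntheticSpec(gridShape = gridShape, nDomains = 4L,
                          geometry = "blocks",
                          rna = list(nGenes = nGenes,
                                     markersPerDomain = 30L),
                          atac = list(nPeaks = nPeaks,
                                      markersPerDomain = 30L),
                          seed = seed)
    dom <- generateDomains(spec)
    truth <- dom$labels
    # blocks layout: 1 = top-left, 2 = top-right, 3 = bottom-left,
    # 4 = bottom-right. RNA sees the row split, ATAC the column split.
    rnaGroups <- ifelse(truth %in% c(1L, 2L), 1L, 2L)
    atacGroups <- ifelse(truth %in% c(1L, 3L), 1L, 2L)
    set.seed(spec$seed + 1L)
    rnaCounts <- simulateRNA(rnaGroups, spec)
    atacCounts <- simulateATAC(atacGroups, spec)
    rownames(rnaCounts) <- rownames(atacCounts) <- spotIds(dom$coords)
    o1 <- preprocessRNA(rnaCounts)
    o2 <- suppressMessages(preprocessATAC(atacCounts))
    pair <- SpatialOmicsPair(o1, o2, dom$coords)
    .bundle(pair, truth, spec)
}

#' Small two-domain RNA + ADT smoke bundle
#'
#' 500 spots (20 x 25 lattice), two vertical-stripe domains, 200 RNA
#' genes and 30 ADT proteins whose markers both distinguish the two
#' domains. Used for fast end-to-end checks.
#'
#' @param seed integer seed.
#' @return A `SyntheticBundle` list (`pair`, `truth`, `spec`).
#' @export
makeSmokeBundle <- function(seed = 0L) {
    spec <- syntheticSpec(gridShape = c(20L, 25L), nDomains = 2L,
                          geometry = "stripes",
                          rna = list(nGenes = 200L, markersPerDomain = 30L),
                          adt = list(nProteins = 30L, markersPerDomain = 8L),
                          seed = seed)
    dom <- generateDomains(spec)
    set.seed(spec$seed + 1L)
    rnaCounts <- simulateRNA(dom$labels, spec)
    adtCounts <- simulateADT(dom$labels, spec)
    rownames(rnaCounts) <- rownames(adtCounts) <- spotIds(dom$coords)
    o1 <- preprocessRNA(rnaCounts)
    o2 <- preprocessADT(adtCounts)
    pair <- SpatialOmicsPair(o1, o2, dom$coords)
    .bundle(pair, dom$labels, spec)
}
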