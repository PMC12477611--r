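# Small in-code fixtures shared across test files.

# 200-spot, 2-domain RNA + ADT pair for fast training checks.
makeTinyBundle <- function(seed = 0L) {
    spec <- syntheticSpec(gridShape = c(10L, 20L), nDomains = 2L,
                          geometry = "stripes",
                          rna = list(nGenes = 60L, markersPerDomain = 15L),
                          adt = list(nProteins = 12L, markersPerDomain = 4L),
                          seed = seed)
    dom <- generateDomains(spec)
    set.seed(seed + 1L)
    rna <- simulateRNA(dom$labels, spec)
    adt <- simulateADT(dom$labels, spec)
    rownames(rna) <- rownames(adt) <- spotIds(dom$coords)
    pair <- SpatialOmicsPair(preprocessRNA(rna), preprocessADT(adt),
                             dom$coords)
    list(pair = pair, truth = dom$labels, spec = spec)
}

# random orthogonal g x g matrix
randomOrthogonal <- function(g) {
    qr.Q(qr(matrix(rnorm(g * g), g)))
}

# zero-weight decoder parameter list for a given modality
zeroDecoderParams <- function(modality, g, d, hidden = 64L) {
    p <- smofuse:::initDecoderParams(modality, g, d, hidden)
    lapply(p, function(v) v * 0)
}
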