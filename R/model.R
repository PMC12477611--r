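# Model assembly: parameter initialisation, the tape-based forward pass
# producing the four loss components, and the Adam optimiser. Internal —
# the user-facing entry points live in train.R.

.initModelParams <- function(d1, d2, mod1, mod2, encCfg) {
    hd <- encCfg$hiddenDims
    g <- encCfg$latentDim
    par <- list()
    enc1 <- .initGcnWeights(d1, hd)
    for (l in seq_along(enc1)) par[[sprintf("enc1.W%d", l)]] <- enc1[[l]]
    if (!is.null(d2)) {
        enc2 <- .initGcnWeights(d2, hd)
        for (l in seq_along(enc2)) par[[sprintf("enc2.W%d", l)]] <- enc2[[l]]
        par$proj1.W <- glorotUniform(g, g); par$proj1.b <- numeric(g)
        par$proj2.W <- glorotUniform(g, g); par$proj2.b <- numeric(g)
        par$fuse.W <- glorotUniform(2L * g, g); par$fuse.b <- numeric(g)
        par$head.W <- glorotUniform(g, 2L); par$head.b <- numeric(2L)
    }
    par
}

.addDecoderParams <- function(par, prefix, modality, g, d) {
    dec <- initDecoderParams(modality, g, d)
    for (nm in names(dec)) par[[paste(prefix, nm, sep = ".")]] <- dec[[nm]]
    par
}

# GCN encoder on the tape: X is a constant matrix, S the constant sparse
# normalised operator, weights are leaf nodes P[["encM.Wl"]].
.tapeEncode <- function(P, X, S, prefix, encCfg) {
    nL <- length(encCfg$hiddenDims)
    H <- NULL
    for (l in seq_len(nL)) {
        W <- P[[sprintf("%s.W%d", prefix, l)]]
        lin <- if (is.null(H)) agMatmul(X, W) else agMatmul(H, W)
        H <- agSpMatmul(S, lin)
        if (l < nL) {
            H <- switch(encCfg$activation,
                        elu = agElu(H), relu = agRelu(H), linear = H)
        }
    }
    H
}

# Reconstruction loss node for one modality.
.tapeDecoderLoss <- function(P, prefix, modality, Znode, raw, prior = NULL,
                             sample = FALSE, eps = NULL, klWeight = 1) {
    p <- function(nm) P[[paste(prefix, nm, sep = ".")]]
    H <- agElu(agAddBias(agMatmul(Znode, p("Wd")), p("bd")))
    head <- function(Wnm, bnm) agAddBias(agMatmul(H, p(Wnm)), p(bnm))
    switch(modality,
        rna = {
            pi <- agSigmoid(head("Wpi", "bpi"), clampEps = 1e-7)
            mu <- agExp(head("Wmu", "bmu"))
            theta <- agExp(head("Wth", "bth"))
            agZinbNLL(pi, mu, theta, raw)
        },
        atac = {
            pb <- agSigmoid(head("Wp", "bp"), clampEps = 1e-7)
            agBCESum(pb, raw)
        },
        adt = {
            mB <- head("Wm", "bm")
            sB <- agExp(head("Ws", "bs"), lo = 1e-4, hi = 10)
            piA <- agSigmoid(head("Wpi", "bpi"), clampEps = 1e-7)
            alpha <- agSoftplus(head("Wa", "ba"))
            logNu <- if (sample) agAdd(mB, agMulC(sB, eps))
                     else agAdd(mB, agScale(agMul(sB, sB), 0.5))
            nuB <- agExp(logNu)
            nuF <- agMul(agAddC(alpha, 1), nuB)
            phi <- agExp(p("logphi"), lo = 1e-4, hi = 1e4)
            nll <- agNBMixNLL(nuB, nuF, piA, phi, raw)
            if (klWeight > 0) {
                kl <- agKLLognormal(mB, sB, prior$mPrior, prior$sigmaPrior)
                agSumScalars(list(nll, kl), c(1, klWeight))
            } else nll
        },
        other = {
            xh <- agSigmoid(head("Wo", "bo"), clampEps = 1e-7)
            agBCESum(xh, raw)
        })
}

# Full two-modality forward pass. Returns loss root, component nodes and
# the embedding nodes. ctx carries the constant data and settings.
.forwardFusion <- function(par, ctx, sample = TRUE, epsList = NULL) {
    tape <- agTape()
    P <- lapply(par, function(v) agLeaf(tape, v))
    E1 <- .tapeEncode(P, ctx$X1, ctx$S, "enc1", ctx$encCfg)
    E2 <- .tapeEncode(P, ctx$X2, ctx$S, "enc2", ctx$encCfg)
    EA1 <- agAttention(E1)
    EA2 <- agAttention(E2)
    C1 <- agRelu(agAddBias(agMatmul(E1, P$proj1.W), P$proj1.b))
    C2 <- agRelu(agAddBias(agMatmul(E2, P$proj2.W), P$proj2.b))
    EC <- agAddBias(agMatmul(agCbind(C1, C2), P$fuse.W), P$fuse.b)
    Z <- agLinComb(list(EA1, EA2, EC),
                   c(ctx$fw$alpha, ctx$fw$beta, ctx$fw$gamma))

    eAll <- agRbind(EA1, EA2)
    logits <- agAddBias(agMatmul(eAll, P$head.W), P$head.b)
    n <- nrow(agValue(E1))
    ce <- agSoftmaxCE(logits, c(rep(0L, n), rep(1L, n)))
    con <- agCommonalityLoss(C1, C2)
    reg <- if (ctx$spatialMode == "kernel") agSpatialReg(Z, ctx$P)
           else agSpatialRegLiteral(Z, ctx$Ddist)
    r1 <- .tapeDecoderLoss(P, "dec1", ctx$mod1, Z, ctx$raw1, ctx$prior1,
                           sample, epsList$e1, ctx$klWeight)
    r2 <- .tapeDecoderLoss(P, "dec2", ctx$mod2, Z, ctx$raw2, ctx$prior2,
                           sample, epsList$e2, ctx$klWeight)
    recon <- agSumScalars(list(r1, r2))
    w <- ctx$lw
    root <- agSumScalars(list(ce, con, reg, recon),
                         c(w$a, w$b, w$c, w$d))
    list(tape = tape, leaves = P, root = root, Z = Z, EC = EC,
         parts = c(ce = agValue(ce), con = agValue(con),
                   reg = agValue(reg), recon = agValue(recon),
                   total = agValue(root)))
}

# Single-modality forward: Z is the attention-refined embedding of the
# one active modality; only the spatial regulariser and the modality's
# reconstruction loss apply (no second omics class exists, so the label
# loss is forced to zero).
.forwardSingle <- function(par, ctx, sample = TRUE, epsList = NULL) {
    tape <- agTape()
    P <- lapply(par, function(v) agLeaf(tape, v))
    E1 <- .tapeEncode(P, ctx$X1, ctx$S, "enc1", ctx$encCfg)
    Z <- agAttention(E1)
    reg <- if (ctx$spatialMode == "kernel") agSpatialReg(Z, ctx$P)
           else agSpatialRegLiteral(Z, ctx$Ddist)
    r1 <- .tapeDecoderLoss(P, "dec1", ctx$mod1, Z, ctx$raw1, ctx$prior1,
                           sample, epsList$e1, ctx$klWeight)
    w <- ctx$lw
    root <- agSumScalars(list(reg, r1), c(w$c, w$d))
    list(tape = tape, leaves = P, root = root, Z = Z, EC = NULL,
         parts = c(ce = 0, con = 0, reg = agValue(reg),
                   recon = agValue(r1), total = agValue(root)))
}

.adamInit <- function(par) {
    st <- new.env(parent = emptyenv())
    st$m <- lapply(par, function(v) v * 0)
    st$v <- lapply(par, function(v) v * 0)
    st$t <- 0L
    st
}

.adamStep <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    st$t <- st$t + 1L
    c1 <- 1 - beta1^st$t
    c2 <- 1 - beta2^st$t
    for (nm in names(par)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
        st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
        par[[nm]] <- par[[nm]] -
            lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
    }
    par
}

# One optimisation run over a prebuilt context; returns params and trace.
.optimise <- function(par, ctx, forward, config) {
    st <- .adamInit(par)
    trace <- vector("list", config$epochs)
    needsEps <- ctx$mod1 == "adt" || identical(ctx$mod2, "adt")
    for (epoch in seq_len(config$epochs)) {
        epsList <- NULL
        if (needsEps) {
            mk <- function(raw) matrix(stats::rnorm(length(raw)),
                                       nrow(raw), ncol(raw))
            epsList <- list(
                e1 = if (ctx$mod1 == "adt") mk(ctx$raw1) else NULL,
                e2 = if (identical(ctx$mod2, "adt")) mk(ctx$raw2) else NULL)
        }
        fw <- forward(par, ctx, sample = TRUE, epsList = epsList)
        parts <- fw$parts
        if (anyNA(parts) || any(!is.finite(parts))) {
            bad <- names(parts)[!is.finite(parts)][1]
            stop(sprintf(
                "loss component '%s' became non-finite at epoch %d (last finite epoch: %d)",
                bad, epoch, epoch - 1L))
        }
        grads <- agBackward(fw$root)
        gl <- lapply(names(par),
                     function(nm) grads[[fw$leaves[[nm]]$id]])
        names(gl) <- names(par)
        par <- .adamStep(par, gl, st, config$lr)
        trace[[epoch]] <- parts
    }
    tr <- as.data.frame(do.call(rbind, trace))
    tr$epoch <- seq_len(config$epochs)
    list(par = par, trace = tr[, c("epoch", "total", "ce", "con",
                                   "reg", "recon")])
}
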