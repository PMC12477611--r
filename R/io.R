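# Readers/writers and run configuration. Matrices are accepted as dense
# CSV (spots x features, first column = spot barcode) or as an MTX
# triplet directory (matrix.mtx + features.tsv + barcodes.tsv, features x
# barcodes as exported by common pipelines). Coordinates come from a CSV
# with columns (spot, x, y[, slice]) or (x, y[, slice]) keyed by row
# order of the first modality. Spot alignment is by barcode intersection,
# never positional, since modality files are routinely exported in
# different orders.

.defaultRunConfig <- function() {
    list(seed = 0L,
         output_dir = "smofuse_out",
         modalities = list(),
         coordinates = NULL,
         graph = list(lambda = NULL, k_neighbors = 6L),
         encoder = list(hidden_dims = c(256L, 64L), activation = "elu"),
         fusion = list(alpha = 1/3, beta = 1/3, gamma = 1/3),
         loss = list(a = 1, b = 1, c = 1, d = 1),
         training = list(epochs = 300L, lr = 1e-3, kl_weight = 1,
                         spatial_mode = "kernel"))
}

#' Load a run configuration
#'
#' Reads a YAML run configuration and fills every omitted field with its
#' default. The file must declare one or two modalities (path, format,
#' modality tag) and a coordinates source.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Named list with class `"RunConfig"`.
#' @export
loadRunConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    mods <- cfg$modalities          # unnamed list; merge it manually
    cfg$modalities <- NULL
    cfg <- utils::modifyList(.defaultRunConfig(), cfg)
    cfg$modalities <- if (is.null(mods)) list() else mods
    nmod <- length(cfg$modalities)
    if (nmod < 1 || nmod > 2)
        stop("config must declare exactly 1 or 2 modalities")
    for (m in cfg$modalities) {
        if (is.null(m$path) || is.null(m$modality))
            stop("each modality needs 'path' and 'modality'")
        if (!file.exists(m$path))
            stop(sprintf("modality file not found: %s", m$path))
    }
    structure(cfg, class = "RunConfig")
}

#' Read one omics count matrix from disk
#'
#' @param path CSV file (spots x features, first column spot barcodes) or
#'   a directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   (features x barcodes).
#' @param format "csv" or "mtx"; guessed from `path` when NULL.
#' @return Numeric matrix, spots x features, with barcode rownames.
#' @export
readOmicsCounts <- function(path, format = NULL) {
    if (is.null(format))
        format <- if (dir.exists(path)) "mtx" else "csv"
    format <- match.arg(format, c("csv", "mtx"))
    if (format == "csv") {
        df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
        as.matrix(df)
    } else {
        m <- Matrix::readMM(file.path(path, "matrix.mtx"))
        feats <- utils::read.table(file.path(path, "features.tsv"),
                                   sep = "\t", stringsAsFactors = FALSE)[, 1]
        bcs <- utils::read.table(file.path(path, "barcodes.tsv"),
                                 sep = "\t", stringsAsFactors = FALSE)[, 1]
        m <- as.matrix(Matrix::t(m))       # -> spots x features
        dimnames(m) <- list(bcs, feats)
        m
    }
}

#' Read spot coordinates
#'
#' @param path CSV with columns `(spot, x, y[, slice])`, or `(x, y[,
#'   slice])` in which case `spotIds` must be supplied to key the rows.
#' @param spotIds optional barcodes for id-less coordinate files.
#' @return A [CoordinateTable-class].
#' @export
readCoordinates <- function(path, spotIds = NULL) {
    df <- utils::read.csv(path, check.names = FALSE)
    cn <- tolower(names(df))
    names(df) <- cn
    slice <- if ("slice" %in% cn) as.character(df$slice) else NULL
    if ("spot" %in% cn) {
        ids <- as.character(df$spot)
    } else if (!is.null(spotIds)) {
        if (length(spotIds) != nrow(df))
            stop("coordinate rows do not match the supplied spot ids")
        ids <- spotIds
    } else {
        ids <- paste0("spot", seq_len(nrow(df)))
    }
    if (!all(c("x", "y") %in% cn))
        stop("coordinate file must have 'x' and 'y' columns")
    CoordinateTable(cbind(x = df$x, y = df$y), spotIds = ids,
                    sliceIds = slice)
}

#' Load and align a spatial omics pair from disk
#'
#' Reads both modality matrices and the coordinates, intersects spot
#' barcodes across all sources, reorders everything to the first
#' modality's barcode order, reports dropped spots, and applies the
#' per-modality preprocessing.
#'
#' @param config a `RunConfig` (or path/list accepted by
#'   [loadRunConfig()]).
#' @return An aligned [SpatialOmicsPair-class].
#' @export
loadPair <- function(config) {
    cfg <- if (is(config, "RunConfig")) config else loadRunConfig(config)
    if (length(cfg$modalities) != 2)
        stop("loadPair requires two modalities (see singleModalityMode for one)")
    m1 <- cfg$modalities[[1]]; m2 <- cfg$modalities[[2]]
    x1 <- readOmicsCounts(m1$path, m1$format)
    x2 <- readOmicsCounts(m2$path, m2$format)
    if (is.null(cfg$coordinates))
        stop("config must name a coordinates file")
    coords <- readCoordinates(cfg$coordinates, spotIds = rownames(x1))
    common <- intersect(rownames(x1), rownames(x2))
    common <- rownames(x1)[rownames(x1) %in% common]   # canonical order
    if (length(common) == 0)
        stop("no shared spot barcodes between the two modalities")
    dropped <- (nrow(x1) - length(common)) + (nrow(x2) - length(common))
    if (dropped > 0)
        message(sprintf("loadPair: dropped %d spot(s) without a match in both modalities",
                        dropped))
    missingCoord <- setdiff(common, spotIds(coords))
    if (length(missingCoord) > 0)
        stop(sprintf("missing coordinates for %d retained spot(s), e.g. %s",
                     length(missingCoord), missingCoord[1]))
    x1 <- x1[common, , drop = FALSE]
    x2 <- x2[common, , drop = FALSE]
    ci <- match(common, spotIds(coords))
    coords <- CoordinateTable(coords@positions[ci, , drop = FALSE],
                              spotIds = common,
                              sliceIds = coords@sliceIds[ci])
    pre <- function(x, m) {
        extra <- m
        extra$path <- NULL; extra$format <- NULL; extra$modality <- NULL
        do.call(preprocessOmics, c(list(raw = x, modality = m$modality),
                                   extra))
    }
    SpatialOmicsPair(pre(x1, m1), pre(x2, m2), coords, aligned = TRUE)
}

#' Save training results to a directory
#'
#' Writes the joint representation (`Z.csv`, spot-keyed), cluster labels
#' (`labels.csv`), the loss trace (`loss_trace.csv`), the resolved
#' configuration (`config_resolved.yaml`) and a reproducibility manifest
#' (`manifest.json`: package version, seed, config hash). Reading `Z.csv`
#' back with [readEmbedding()] reproduces Z exactly.
#'
#' @param jr a [JointRepresentation-class].
#' @param labels optional [ClusteringResult-class] or integer labels.
#' @param dir output directory (created if needed).
#' @param config optional resolved run configuration to copy.
#' @return The directory path, invisibly.
#' @export
saveResults <- function(jr, labels = NULL, dir, config = NULL) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory '%s'", dir))
    zdf <- data.frame(spot = spotIds(jr), jr@Z, check.names = FALSE)
    names(zdf)[-1] <- paste0("dim", seq_len(ncol(jr@Z)))
    utils::write.csv(zdf, file.path(dir, "Z.csv"), row.names = FALSE,
                     quote = FALSE)
    if (!is.null(labels)) {
        lv <- if (is(labels, "ClusteringResult")) clusterLabels(labels)
              else as.integer(labels)
        utils::write.csv(data.frame(spot = spotIds(jr), label = lv),
                         file.path(dir, "labels.csv"), row.names = FALSE,
                         quote = FALSE)
    }
    utils::write.csv(lossTrace(jr), file.path(dir, "loss_trace.csv"),
                     row.names = FALSE, quote = FALSE)
    cfgPath <- file.path(dir, "config_resolved.yaml")
    if (!is.null(config))
        yaml::write_yaml(config, cfgPath)
    manifest <- list(
        package = "smofuse",
        version = as.character(utils::packageVersion("smofuse")),
        seed = jr@model$config$seed,
        epochs = jr@model$config$epochs,
        mode = jr@model$mode,
        config_hash = if (file.exists(cfgPath))
            unname(tools::md5sum(cfgPath)) else NA,
        timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' Read a saved embedding back
#'
#' @param path the `Z.csv` written by [saveResults()].
#' @return Numeric matrix with spot rownames.
#' @export
readEmbedding <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Write a synthetic bundle to disk
#'
#' One CSV per modality (spots x features), a coordinates CSV and a
#' truth-labels CSV, in the layout [loadPair()] reads.
#'
#' @param bundle a `SyntheticBundle` from the generators.
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory '%s'", dir))
    pair <- bundle$pair
    wr <- function(o, file) {
        df <- data.frame(spot = o@spotIds, o@raw, check.names = FALSE)
        utils::write.csv(df, file.path(dir, file), row.names = FALSE,
                         quote = FALSE)
    }
    wr(pair@omics1, paste0(pair@omics1@modality, ".csv"))
    wr(pair@omics2, paste0(pair@omics2@modality, ".csv"))
    co <- pair@coords
    utils::write.csv(data.frame(spot = co@spotIds,
                                x = co@positions[, 1],
                                y = co@positions[, 2]),
                     file.path(dir, "coords.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(spot = co@spotIds, label = bundle$truth),
                     file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
    invisible(dir)
}
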