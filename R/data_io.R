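## Readers/writers for the canonical tab-delimited layout:
## abundance  - samples in rows, genera in columns, first column = sample id
## labels     - two columns: sample id, label (0/1)
## embeddings - genera in rows, one column per embedding dimension
## network    - edge list: from, to, weight

.readDelimMatrix <- function(path, what = "table") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop(sprintf("duplicate identifier in %s '%s': %s", what, path, dup[[1L]]))
    hdr <- colnames(df)[-1L]
    dup <- hdr[duplicated(hdr)]
    if (length(dup))
        stop(sprintf("duplicate identifier in %s '%s': %s", what, path, dup[[1L]]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(is.na(suppressWarnings(apply(m, 2L, as.numeric))), arr.ind = TRUE)
        bad <- bad[order(bad[, 1L], bad[, 2L]), , drop = FALSE]
        stop(sprintf("non-numeric value in %s '%s' at row %d (%s), column '%s'",
                     what, path, bad[1L, 1L], ids[bad[1L, 1L]], hdr[bad[1L, 2L]]))
    }
    if (anyNA(m) || any(!is.finite(m))) {
        bad <- which(!is.finite(m), arr.ind = TRUE)
        stop(sprintf("non-finite value in %s '%s' at row %d (%s), column '%s'",
                     what, path, bad[1L, 1L], ids[bad[1L, 1L]], hdr[bad[1L, 2L]]))
    }
    rownames(m) <- ids
    m
}

#' Load an abundance/label/embedding dataset from delimited text
#'
#' Reads the three canonical tab-delimited files and assembles a validated
#' [MicrobiomeExperiment-class]. Genera present in the abundance table but
#' absent from the embedding table are dropped with a warning (genomic
#' coverage of reference databases is typically incomplete); samples lacking
#' a label, or labels outside \{0, 1\}, are hard errors naming the offender.
#'
#' @param abundancePath samples x genera TSV (first column sample id).
#' @param labelsPath two-column TSV: sample id, label.
#' @param embeddingsPath genera x d_g TSV (first column genus id), or NULL.
#' @return A [MicrobiomeExperiment-class].
#' @export
loadDataset <- function(abundancePath, labelsPath = NULL, embeddingsPath = NULL) {
    a <- .readDelimMatrix(abundancePath, "abundance table")
    labels <- NULL
    if (!is.null(labelsPath)) {
        if (!file.exists(labelsPath)) stop("file not found: ", labelsPath)
        ldf <- utils::read.delim(labelsPath, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        ids <- as.character(ldf[[1L]])
        dup <- ids[duplicated(ids)]
        if (length(dup)) stop("duplicate sample identifier in labels: ", dup[[1L]])
        labels <- stats::setNames(ldf[[2L]], ids)
    }
    emb <- if (!is.null(embeddingsPath))
        .readDelimMatrix(embeddingsPath, "embedding table") else NULL
    MicrobiomeExperiment(a, labels = labels, embeddings = emb)
}

#' Rescale every sample to a constant sum of 100
#'
#' Each sample (column) is rescaled so its genus abundances sum to 100.
#' Zeros stay zero and within-sample proportions are unchanged; the
#' operation is idempotent.
#'
#' @param x a [MicrobiomeExperiment-class], or a samples x genera matrix.
#' @return object of the same type with normalized abundances.
#' @examples
#' normalizeToPercent(matrix(c(2, 3, 5), 1, dimnames = list("s1", c("a", "b", "c"))))
#' @export
normalizeToPercent <- function(x) {
    if (is(x, "MicrobiomeExperiment")) {
        a <- abundances(x)                       # genera x samples
        tot <- colSums(a)
        if (any(tot == 0))
            stop("sample with all-zero abundance: ",
                 colnames(a)[which(tot == 0)[1L]])
        SummarizedExperiment::assay(x, "abundance") <-
            sweep(a, 2L, tot / 100, "/")
        validObject(x)
        return(x)
    }
    m <- as.matrix(x)                            # samples x genera
    tot <- rowSums(m)
    if (any(tot == 0))
        stop("sample with all-zero abundance: ",
             if (is.null(rownames(m))) which(tot == 0)[1L]
             else rownames(m)[which(tot == 0)[1L]])
    sweep(m, 1L, tot / 100, "/")
}

#' Aggregate a species-level table to genus level
#'
#' Genus abundance is the per-sample sum of its constituent species; the
#' genus genomic vector is the arithmetic mean of the constituent species
#' vectors.
#'
#' @param speciesAbundance samples x species matrix (or data.frame).
#' @param speciesToGenus named character vector mapping every species column
#'   to a genus.
#' @param speciesEmbeddings optional species x d_g matrix (rownames =
#'   species).
#' @return list with `abundance` (samples x genera matrix) and `embeddings`
#'   (genera x d_g matrix or NULL).
#' @export
aggregateSpeciesToGenus <- function(speciesAbundance, speciesToGenus,
                                    speciesEmbeddings = NULL) {
    m <- as.matrix(speciesAbundance)
    unmapped <- setdiff(colnames(m), names(speciesToGenus))
    if (length(unmapped))
        stop("species with no genus mapping: ", paste(unmapped, collapse = ", "))
    genus <- as.character(speciesToGenus[colnames(m)])
    glev <- unique(genus)
    agg <- vapply(glev, function(g)
        rowSums(m[, genus == g, drop = FALSE]), numeric(nrow(m)))
    if (nrow(m) == 1L) agg <- matrix(agg, 1L, dimnames = list(rownames(m), glev))
    else colnames(agg) <- glev
    emb <- NULL
    if (!is.null(speciesEmbeddings)) {
        se <- as.matrix(speciesEmbeddings)
        missing <- setdiff(colnames(m), rownames(se))
        if (length(missing))
            stop("species without embedding: ", paste(missing, collapse = ", "))
        emb <- t(vapply(glev, function(g) {
            sp <- colnames(m)[genus == g]
            colMeans(se[sp, , drop = FALSE])
        }, numeric(ncol(se))))
        rownames(emb) <- glev
    }
    list(abundance = agg, embeddings = emb)
}

#' Write dataset components as deterministic tab-delimited text
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param abundancePath,labelsPath,embeddingsPath output paths (NULL skips).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(x, abundancePath = NULL, labelsPath = NULL,
                         embeddingsPath = NULL) {
    written <- character()
    if (!is.null(abundancePath)) {
        m <- t(abundances(x))                    # samples x genera on disk
        df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, abundancePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, abundancePath)
    }
    if (!is.null(labelsPath)) {
        lab <- sampleLabels(x)
        if (is.null(lab)) stop("no labels to write")
        utils::write.table(
            data.frame(sample_id = names(lab), label = unname(lab)),
            labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, labelsPath)
    }
    if (!is.null(embeddingsPath)) {
        emb <- genomicVectors(x)
        if (is.null(emb)) stop("no genomic vectors to write")
        colnames(emb) <- paste0("d", seq_len(ncol(emb)))
        df <- data.frame(genus_id = rownames(emb), emb, check.names = FALSE)
        utils::write.table(df, embeddingsPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, embeddingsPath)
    }
    invisible(written)
}

#' Write / read a co-expression network edge list
#'
#' The edge list is a three-column TSV (`from`, `to`, `weight`); network
#' parameters travel in a JSON sidecar written next to the edge list when
#' `provenancePath` is given.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path edge-list TSV path.
#' @param provenancePath optional JSON path recording genera, threshold,
#'   subsampling parameters and seed.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(network, path, provenancePath = NULL) {
    utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(provenancePath)) {
        jsonlite::write_json(list(
            genera = network@genera, tau = network@tau,
            n_subsamples = network@nSubsamples,
            subsample_fraction = network@subsampleFraction,
            pseudocount = network@pseudocount, seed = network@seed),
            provenancePath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(path)
}

#' @rdname writeNetwork
#' @param genera node set; defaults to the genera appearing in the edge list
#'   (isolated nodes are then lost, so pass the full set when known).
#' @param tau,nSubsamples,subsampleFraction,pseudocount,seed network
#'   parameters to record on the reconstructed object.
#' @export
readNetwork <- function(path, genera = NULL, tau = 0.1, nSubsamples = 5L,
                        subsampleFraction = 0.8, pseudocount = NA_real_,
                        seed = NA_integer_) {
    e <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (is.null(genera)) genera <- sort(unique(c(e$from, e$to)))
    new("CoexpressionNetwork", genera = as.character(genera),
        edges = data.frame(from = as.character(e$from), to = as.character(e$to),
                           weight = as.numeric(e$weight)),
        tau = tau, nSubsamples = as.integer(nSubsamples),
        subsampleFraction = subsampleFraction,
        pseudocount = as.numeric(pseudocount), seed = as.integer(seed))
}
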