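# Readers and writers for the plain-text formats the pipeline exchanges:
# GeoJSON polygon annotations, TSV matrices and tables, BED intervals and
# bedGraph coverage (via rtracklayer, 0-based half-open on disk), FASTA
# (via Biostrings), and MEME-minimal / CIS-BP motif text.

#' Read polygon annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features in pixel coordinates
#' with \code{properties.layer} one of "green", "yellow", "gland". The
#' physical pixel size is taken from a top-level \code{um_per_px} member
#' or supplied explicitly (an error if neither is present: resolution is
#' never guessed).
#'
#' @param file path to a GeoJSON file.
#' @param umPerPx micrometres per pixel, overriding the file.
#' @return an [AnnotationSet-class].
#' @export
readAnnotationGeoJSON <- function(file, umPerPx = NULL) {
    doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
    if (is.null(umPerPx)) umPerPx <- doc$um_per_px
    if (is.null(umPerPx))
        stop("no um_per_px in the file and none supplied; physical pixel ",
             "size cannot be guessed")
    layers <- list(green = list(), yellow = list(), gland = list())
    for (ft in doc$features) {
        layer <- ft$properties$layer
        if (is.null(layer) || !layer %in% names(layers))
            stop("feature without a valid 'layer' property ",
                 "(green/yellow/gland)")
        ring <- ft$geometry$coordinates[[1]]
        m <- do.call(rbind, lapply(ring, function(v)
            c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
        # GeoJSON rings repeat the first vertex at the end
        if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ]))
            m <- m[-nrow(m), , drop = FALSE]
        layers[[layer]] <- c(layers[[layer]], list(m))
    }
    AnnotationSet(green = layers$green, yellow = layers$yellow,
        gland = layers$gland, umPerPx = as.numeric(umPerPx))
}

#' Write polygon annotations as GeoJSON
#'
#' @param ann an [AnnotationSet-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeAnnotationGeoJSON <- function(ann, file) {
    featureOf <- function(poly, layer) {
        ring <- lapply(seq_len(nrow(poly)), function(i)
            c(poly[i, 1], poly[i, 2]))
        ring[[length(ring) + 1L]] <- ring[[1L]]
        list(type = "Feature",
            properties = list(layer = layer),
            geometry = list(type = "Polygon", coordinates = list(ring)))
    }
    feats <- c(
        lapply(ann@green, featureOf, layer = "green"),
        lapply(ann@yellow, featureOf, layer = "yellow"),
        lapply(ann@gland, featureOf, layer = "gland"))
    doc <- list(type = "FeatureCollection", um_per_px = ann@umPerPx,
        features = feats)
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' Read an expression bundle from TSV files
#'
#' @param intensityFile genes x samples TSV (first column gene ids, header
#'   = sample ids).
#' @param flagsFile optional TSV of P/M/A detection flags, same layout.
#' @param clinicalFile optional per-sample clinical TSV with a
#'   \code{sample_id} column.
#' @return a SummarizedExperiment (see [ExpressionExperiment()]).
#' @export
readExpressionTSV <- function(intensityFile, flagsFile = NULL,
                              clinicalFile = NULL) {
    m <- as.matrix(utils::read.delim(intensityFile, row.names = 1L,
        check.names = FALSE))
    flags <- if (!is.null(flagsFile))
        as.matrix(utils::read.delim(flagsFile, row.names = 1L,
            check.names = FALSE)) else NULL
    clinical <- if (!is.null(clinicalFile))
        utils::read.delim(clinicalFile, check.names = FALSE) else NULL
    ExpressionExperiment(m, flags = flags, clinical = clinical)
}

#' Write an expression bundle to TSV files
#'
#' @param se SummarizedExperiment from [ExpressionExperiment()].
#' @param prefix path prefix; writes \code{<prefix>_intensities.tsv} and,
#'   when present, \code{<prefix>_flags.tsv} and
#'   \code{<prefix>_clinical.tsv}.
#' @return the paths written, invisibly.
#' @export
writeExpressionTSV <- function(se, prefix) {
    paths <- character(0)
    writeMat <- function(m, path) {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
            row.names = FALSE)
        path
    }
    paths <- c(paths, writeMat(
        SummarizedExperiment::assay(se, "intensities"),
        paste0(prefix, "_intensities.tsv")))
    if ("flags" %in% SummarizedExperiment::assayNames(se))
        paths <- c(paths, writeMat(
            SummarizedExperiment::assay(se, "flags"),
            paste0(prefix, "_flags.tsv")))
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    if (ncol(cd) > 0) {
        p <- paste0(prefix, "_clinical.tsv")
        utils::write.table(
            data.frame(sample_id = rownames(cd), cd, check.names = FALSE,
                row.names = NULL),
            p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Read gene TSS positions from BED6
#'
#' BED is 0-based half-open; a width-1 BED interval [t, t+1) is taken as
#' the TSS position t. The name column carries the gene id.
#'
#' @param file BED file path.
#' @param chromSizes named chromosome lengths to attach as seqlengths.
#' @return \code{GRanges} of width-1 TSS positions with \code{gene_id}.
#' @export
readTssBed <- function(file, chromSizes = NULL) {
    gr <- rtracklayer::import(file, format = "BED")
    if (!is.null(chromSizes)) {
        GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
        GenomeInfoDb::seqlengths(gr) <- chromSizes
    }
    GenomicRanges::mcols(gr)$gene_id <- GenomicRanges::mcols(gr)$name
    gr
}

#' Write regions as BED6
#'
#' @param gr \code{GRanges}; a \code{gene_id} or \code{gene_ids} column
#'   becomes the BED name field.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeBedRegions <- function(gr, file) {
    mc <- GenomicRanges::mcols(gr)
    nm <- if (!is.null(mc$gene_id)) as.character(mc$gene_id)
        else if (!is.null(mc$gene_ids))
            vapply(mc$gene_ids, paste, character(1), collapse = ";")
        else as.character(seq_along(gr))
    out <- gr
    GenomicRanges::mcols(out) <- NULL
    GenomicRanges::mcols(out)$name <- nm
    rtracklayer::export(out, file, format = "BED")
    invisible(file)
}

#' Read per-base coverage from a bedGraph file
#'
#' @param file bedGraph path (0-based half-open intervals with a depth
#'   column).
#' @param chromSizes named chromosome lengths; bases not covered by any
#'   record get depth 0.
#' @return an \code{RleList} of per-base depth tiling each chromosome.
#' @export
readBedGraphCoverage <- function(file, chromSizes) {
    gr <- rtracklayer::import(file, format = "bedGraph")
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    GenomeInfoDb::seqlengths(gr) <- chromSizes
    GenomicRanges::coverage(gr, weight = "score")
}

#' Write per-base coverage as bedGraph
#'
#' Zero-depth runs are omitted from the file (the reader restores them
#' from the chromosome sizes).
#'
#' @param track \code{RleList} of per-base depth.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeBedGraphCoverage <- function(track, file) {
    gr <- GenomicRanges::GRanges(track)
    names(GenomicRanges::mcols(gr)) <- "score"
    gr <- gr[GenomicRanges::mcols(gr)$score != 0]
    rtracklayer::export(gr, file, format = "bedGraph")
    invisible(file)
}

#' Read promoter or genome sequences from FASTA
#'
#' @param file FASTA path.
#' @return a named character vector of sequences.
#' @export
readFastaSequences <- function(file) {
    s <- Biostrings::readDNAStringSet(file)
    stats::setNames(as.character(s), names(s))
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeFastaSequences <- function(sequences, file) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(sequences)
    Biostrings::writeXStringSet(sequences, file)
    invisible(file)
}

#' Read motifs from MEME minimal format
#'
#' Parses \code{MOTIF} blocks with their letter-probability matrices (rows
#' = positions, columns = A C G T) and background letter frequencies when
#' present; probabilities are scaled by \code{nsites} (default 20 when the
#' header omits it) to yield count-like PFMs.
#'
#' @param file MEME minimal-format path.
#' @param pseudocount passed to [pfmToPwm()].
#' @return list of [MotifModel-class] objects.
#' @export
readMemeMotifs <- function(file, pseudocount = 0.25) {
    lines <- readLines(file)
    bg <- rep(0.25, 4)
    bgAt <- grep("^Background letter frequencies", lines)
    if (length(bgAt)) {
        toks <- strsplit(trimws(lines[bgAt[1] + 1L]), "\\s+")[[1]]
        vals <- suppressWarnings(as.numeric(toks))
        bg <- vals[!is.na(vals)]
        if (length(bg) != 4L) bg <- rep(0.25, 4)
    }
    motifAt <- grep("^MOTIF", lines)
    models <- list()
    for (m in motifAt) {
        nm <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
        hdrAt <- m + grep("^letter-probability matrix",
            lines[seq(m + 1L, length(lines))])[1]
        hdr <- lines[hdrAt]
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
        nsites <- if (grepl("nsites=", hdr))
            as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)) else 20
        rows <- lines[seq(hdrAt + 1L, hdrAt + w)]
        probs <- do.call(rbind, lapply(rows, function(l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
        pfmMat <- t(probs) * nsites           # 4 x L, rows A C G T
        models[[length(models) + 1L]] <- pfmToPwm(pfmMat, tfName = nm,
            pseudocount = pseudocount, background = bg)
    }
    models
}

#' Write motifs in MEME minimal format
#'
#' @param models list of [MotifModel-class] objects.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeMemeMotifs <- function(models, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
        "strands: + -", "", "Background letter frequencies"), con)
    bg <- models[[1]]@background
    writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f",
        bg[1], bg[2], bg[3], bg[4]), con)
    for (m in models) {
        p <- pfm(m)
        cs <- colSums(p)
        probs <- sweep(p, 2L, cs, "/")
        writeLines(c("", sprintf("MOTIF %s", tfName(m)),
            sprintf("letter-probability matrix: alength= 4 w= %d nsites= %.0f E= 0",
                ncol(p), mean(cs))), con)
        for (j in seq_len(ncol(p)))
            writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                probs[1, j], probs[2, j], probs[3, j], probs[4, j]), con)
    }
    invisible(file)
}

#' Read a CIS-BP-style PFM text file
#'
#' Expects a header row \code{Pos A C G T} followed by one row per motif
#' position; values may be counts or probabilities.
#'
#' @param file path to the PFM text file.
#' @param tfName transcription factor name (default: file base name).
#' @param pseudocount passed to [pfmToPwm()].
#' @return a [MotifModel-class].
#' @export
readCisbpPfm <- function(file, tfName = NULL, pseudocount = 0.25) {
    if (is.null(tfName))
        tfName <- sub("\\.[^.]*$", "", basename(file))
    df <- utils::read.delim(file, check.names = FALSE)
    cols <- toupper(names(df))
    need <- c("A", "C", "G", "T")
    if (!all(need %in% cols))
        stop("PFM file must have columns A, C, G, T")
    pfmMat <- t(as.matrix(df[, match(need, cols)]))
    pfmToPwm(pfmMat, tfName = tfName, pseudocount = pseudocount)
}

#' Read dense single-cell counts and labels from TSV
#'
#' @param countsFile genes x cells TSV (first column gene ids).
#' @param labelsFile TSV with columns \code{cell_id}, \code{cell_type}
#'   and optional \code{cohort}.
#' @param mitoPattern regular expression flagging mitochondrial genes by
#'   id (default \code{"^MT-"}).
#' @return a SingleCellExperiment (see [CellCountsExperiment()]).
#' @export
readCellCountsTSV <- function(countsFile, labelsFile = NULL,
                              mitoPattern = "^MT-") {
    m <- as.matrix(utils::read.delim(countsFile, row.names = 1L,
        check.names = FALSE))
    cellType <- NULL; cohort <- NULL
    if (!is.null(labelsFile)) {
        lab <- utils::read.delim(labelsFile, check.names = FALSE)
        rownames(lab) <- lab$cell_id
        lab <- lab[colnames(m), , drop = FALSE]
        cellType <- lab$cell_type
        cohort <- lab$cohort
    }
    CellCountsExperiment(m, cellType = cellType,
        mitoGenes = grep(mitoPattern, rownames(m), value = TRUE),
        cohort = cohort)
}

#' Write dense single-cell counts and labels to TSV
#'
#' @param sce a SingleCellExperiment.
#' @param prefix path prefix; writes \code{<prefix>_counts.tsv} and
#'   \code{<prefix>_labels.tsv}.
#' @return the paths written, invisibly.
#' @export
writeCellCountsTSV <- function(sce, prefix) {
    m <- SummarizedExperiment::assay(sce, "counts")
    pc <- paste0(prefix, "_counts.tsv")
    utils::write.table(
        data.frame(gene_id = rownames(m), m, check.names = FALSE),
        pc, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(sce))
    pl <- paste0(prefix, "_labels.tsv")
    utils::write.table(
        data.frame(cell_id = colnames(m), cd, check.names = FALSE,
            row.names = NULL),
        pl, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(pc, pl))
}
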