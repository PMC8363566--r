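# PWM motif scanning of promoter sequences and transcription-factor
# ranking. A position frequency matrix is turned into a log2-odds position
# weight matrix with a pseudocount; promoters are scanned on both strands
# and a window is a hit when its score reaches a fraction of the motif's
# maximum attainable score. Transcription factors are ranked by the number
# of distinct gene promoters they hit.

BASES <- c("A", "C", "G", "T")

#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' pwm[b, i] = log2( (pfm[b, i] + pseudocount * background[b]) /
#' (colsum_i + pseudocount) / background[b] ).
#'
#' @param pfm 4 x L non-negative matrix (rows A, C, G, T; counts or
#'   probabilities) with positive column sums.
#' @param tfName transcription factor name.
#' @param pseudocount additive pseudocount (default 0.25).
#' @param background base probabilities, default uniform.
#' @return a [MotifModel-class].
#' @export
pfmToPwm <- function(pfm, tfName = "TF", pseudocount = 0.25,
                     background = rep(0.25, 4)) {
    pfm <- as.matrix(pfm)
    if (nrow(pfm) != 4L) stop("'pfm' must have 4 rows (A, C, G, T)")
    if (any(pfm < 0)) stop("'pfm' must be non-negative")
    cs <- colSums(pfm)
    if (any(cs == 0)) stop("'pfm' has a zero column")
    background <- background / sum(background)
    names(background) <- BASES
    rownames(pfm) <- BASES
    probs <- sweep(pfm + pseudocount * background, 2L, cs + pseudocount, "/")
    pwmMat <- log2(sweep(probs, 1L, background, "/"))
    new("MotifModel", tfName = tfName, pfm = pfm, pwm = pwmMat,
        pseudocount = pseudocount, background = background)
}

#' @describeIn pfmToPwm the per-column argmax consensus sequence
#' @param model a [MotifModel-class]
#' @export
motifConsensus <- function(model) {
    paste(BASES[apply(pwm(model), 2L, which.max)], collapse = "")
}

pwmMaxScore <- function(pwmMat) sum(apply(pwmMat, 2L, max))

# Score every window of an integer-encoded sequence (A=1..T=4, N=NA; NA
# contributes 0, the background score) against a PWM. Returns a numeric
# vector of window scores, one per start position.
scoreWindows <- function(codes, pwmMat) {
    L <- ncol(pwmMat)
    n <- length(codes) - L + 1L
    if (n < 1L) return(numeric(0))
    scores <- numeric(n)
    for (j in seq_len(L)) {
        col <- pwmMat[, j]
        contrib <- col[codes[seq(j, j + n - 1L)]]
        contrib[is.na(contrib)] <- 0
        scores <- scores + contrib
    }
    scores
}

encodeDNA <- function(seqChar) {
    codes <- match(strsplit(toupper(seqChar), "")[[1]], BASES)
    codes
}

revCompCodes <- function(codes) rev(5L - codes)

#' Scan promoter sequences for motif matches
#'
#' Scans each sequence on both strands (the reverse strand via the
#' reverse complement) and reports every window whose score reaches
#' \code{scoreFraction} times the motif's maximum attainable score.
#' Ambiguous bases (N) score as background (zero contribution). Hit
#' coordinates are promoter-relative, 0-based half-open, on the forward
#' sequence.
#'
#' @param model a [MotifModel-class].
#' @param sequences named character vector or \code{DNAStringSet} of
#'   promoter sequences (names = gene ids).
#' @param scoreFraction fraction of the maximum score required for a hit
#'   (default 0.8).
#' @return data.frame with \code{gene_id}, \code{start}, \code{end},
#'   \code{strand}, \code{score}. Sequences shorter than the motif yield
#'   no hits.
#' @export
scanPromoters <- function(model, sequences, scoreFraction = 0.8) {
    if (is(sequences, "DNAStringSet"))
        sequences <- as.character(sequences)
    if (is.null(names(sequences)))
        names(sequences) <- paste0("seq", seq_along(sequences))
    pwmMat <- pwm(model)
    L <- ncol(pwmMat)
    threshold <- scoreFraction * pwmMaxScore(pwmMat)
    hits <- list()
    for (g in names(sequences)) {
        codes <- encodeDNA(sequences[[g]])
        slen <- length(codes)
        if (slen < L) next
        fwd <- scoreWindows(codes, pwmMat)
        rev <- scoreWindows(revCompCodes(codes), pwmMat)
        fi <- which(fwd >= threshold)
        ri <- which(rev >= threshold)
        if (length(fi))
            hits[[length(hits) + 1L]] <- data.frame(
                gene_id = g, start = fi - 1L, end = fi - 1L + L,
                strand = "+", score = fwd[fi], stringsAsFactors = FALSE)
        if (length(ri))
            # window i on the reverse complement covers forward positions
            # [slen - i - L + 1, slen - i + 1) in 0-based coordinates
            hits[[length(hits) + 1L]] <- data.frame(
                gene_id = g, start = slen - ri - L + 1L,
                end = slen - ri + 1L,
                strand = "-", score = rev[ri], stringsAsFactors = FALSE)
    }
    if (!length(hits))
        return(data.frame(gene_id = character(0), start = integer(0),
            end = integer(0), strand = character(0), score = numeric(0)))
    out <- do.call(rbind, hits)
    out[order(out$gene_id, out$start, out$strand), , drop = FALSE]
}

#' Exact p-value of a PWM score under the background model
#'
#' Dynamic programming over a discretised score lattice: the probability,
#' under independent background bases, that a random window scores at
#' least \code{score}. Intended for motifs up to ~15 columns.
#'
#' @param model a [MotifModel-class].
#' @param score the score whose tail probability is wanted.
#' @param granularity lattice step in score units (default 0.001).
#' @return P(window score >= score) for one strand.
#' @export
pwmScorePValue <- function(model, score, granularity = 0.001) {
    pwmMat <- pwm(model)
    bg <- model@background
    scaled <- round(pwmMat / granularity)
    dist <- c(1)          # probability mass, offset tracked separately
    offset <- 0
    for (j in seq_len(ncol(scaled))) {
        col <- scaled[, j]
        lo <- min(col); hi <- max(col)
        newLen <- length(dist) + (hi - lo)
        newDist <- numeric(newLen)
        for (b in 1:4) {
            sh <- col[b] - lo
            idx <- seq_along(dist) + sh
            newDist[idx] <- newDist[idx] + bg[b] * dist
        }
        dist <- newDist
        offset <- offset + lo
    }
    support <- (seq_along(dist) - 1 + offset) * granularity
    # half-lattice tolerance per column absorbs the discretisation error
    sum(dist[support >= score - granularity * (ncol(scaled) + 1)])
}

#' Rank transcription factors by promoter hits
#'
#' For each motif model, counts the distinct genes of a set with at least
#' one promoter hit; duplicate hits within one promoter count once.
#' Sorted by decreasing count, ties broken lexicographically by TF name.
#'
#' @param models list of [MotifModel-class] objects.
#' @param sequences named promoter sequences (names = gene ids) of the
#'   gene set.
#' @param scoreFraction hit threshold passed to [scanPromoters()].
#' @return data.frame with \code{tf_name}, \code{n_promoters_hit}, and a
#'   \code{genes_hit} comma-separated column; TFs with no hits are kept at
#'   the tail with count 0.
#' @export
rankTFs <- function(models, sequences, scoreFraction = 0.8) {
    stopifnot(length(models) >= 1L)
    rows <- lapply(models, function(m) {
        h <- scanPromoters(m, sequences, scoreFraction)
        genes <- sort(unique(h$gene_id))
        data.frame(tf_name = tfName(m),
            n_promoters_hit = length(genes),
            genes_hit = paste(genes, collapse = ","),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$n_promoters_hit, out$tf_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}
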