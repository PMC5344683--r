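# Per-transcript quantification, normalization, ratios, correlations,
# fold changes and the eightfold directional classification.

#' Count reads per transcript
#'
#' Each assigned read contributes one count to the sense-strand transcript
#' with which it shares the largest overlap; ties are broken uniformly at
#' random under `seed`.  Reads overlapping no sense-strand feature are left
#' uncounted.  Features whose biotype is listed in `exclBiotypes`
#' (e.g. dubious ORFs) are excluded from the row set.
#'
#' @param alnList named list of assigned [GenomicRanges::GRanges], one per
#'   sample.
#' @param features annotation [GenomicRanges::GRanges] with `ID`, `biotype`.
#' @param exclBiotypes biotypes excluded from counting.
#' @param seed RNG seed for overlap ties.
#' @param colData optional [S4Vectors::DataFrame] of sample annotation
#'   (factor, time, replicate), one row per sample.
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`, `rowRanges` from `features`, and per-sample `uncounted`
#'   totals in `colData`.
#' @export
countReads <- function(alnList, features, exclBiotypes = "dubious",
                       seed = 1L, colData = NULL) {
  if (!length(features)) stop("empty annotation")
  keep <- !(mcols(features)$biotype %in% exclBiotypes)
  feats <- features[keep]
  ids <- mcols(feats)$ID
  m <- matrix(0L, nrow = length(feats), ncol = length(alnList),
              dimnames = list(ids, names(alnList)))
  uncounted <- integer(length(alnList))
  for (j in seq_along(alnList)) {
    aln <- alnList[[j]]
    if (!length(aln)) { uncounted[j] <- 0L; next }
    ov <- findOverlaps(aln, feats)
    same <- as.character(strand(aln))[S4Vectors::queryHits(ov)] ==
      as.character(strand(feats))[S4Vectors::subjectHits(ov)]
    ov <- ov[same]
    if (!length(ov)) { uncounted[j] <- length(aln); next }
    w <- width(pintersect(aln[S4Vectors::queryHits(ov)],
                          feats[S4Vectors::subjectHits(ov)],
                          ignore.strand = TRUE))
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    u <- withr::with_seed(seed + j, stats::runif(length(ov)))
    ord <- order(q, -w, u)
    first <- !duplicated(q[ord])
    assigned <- s[ord][first]
    tab <- tabulate(assigned, nbins = length(feats))
    m[, j] <- tab
    uncounted[j] <- length(aln) - sum(first)
  }
  cd <- if (is.null(colData)) DataFrame(row.names = names(alnList)) else colData
  cd$uncounted <- uncounted
  cd$n_assigned <- vapply(alnList, length, integer(1))
  SummarizedExperiment(assays = list(counts = m), rowRanges = feats,
                       colData = cd)
}

#' Hits-per-million scaling
#'
#' Scales each sample's counts by 1e6 over the total counts within the
#' stated transcript universe (only transcripts in the universe contribute
#' to the scaling denominator).
#'
#' @param counts count matrix (transcripts x samples) or a
#'   SummarizedExperiment with assay `"counts"`.
#' @param universe transcript ids forming the scaling universe (default: all
#'   rows).
#' @return Matrix of HPM values, same dimensions as the input.
#' @export
hitsPerMillion <- function(counts, universe = NULL) {
  m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts") else counts
  if (is.null(universe)) universe <- rownames(m)
  if (!length(universe)) stop("empty universe")
  tot <- colSums(m[universe, , drop = FALSE])
  if (any(tot == 0))
    stop("zero total counts over the universe in sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2L, tot, "/") * 1e6
}

#' Factor-to-polymerase binding ratio
#'
#' Per transcript, the surveillance-factor HPM divided by the Pol II HPM,
#' with a pseudocount added to both terms.
#'
#' @param factorHpm,polIIHpm named numeric vectors over the same transcript
#'   universe.
#' @param pseudocount added to numerator and denominator (HPM units).
#' @return data.frame with `transcript_id`, `factor_hpm`, `polII_hpm`,
#'   `ratio` and `undefined` flag (TRUE where the denominator is zero and no
#'   pseudocount rescues it).
#' @export
bindingRatio <- function(factorHpm, polIIHpm, pseudocount = 1) {
  stopifnot(length(factorHpm) == length(polIIHpm))
  den <- polIIHpm + pseudocount
  data.frame(
    transcript_id = names(factorHpm),
    factor_hpm = as.numeric(factorHpm),
    polII_hpm = as.numeric(polIIHpm),
    ratio = ifelse(den > 0, (factorHpm + pseudocount) / den, NA_real_),
    undefined = den <= 0,
    row.names = NULL)
}

#' Pairwise Pearson correlation over the top transcribed mRNAs
#'
#' Selects the `topN` transcripts by mean HPM across all samples (so the
#' selection does not depend on sample order) and computes pairwise Pearson
#' correlations on `log2(HPM + pseudocount)`.
#'
#' @param hpm HPM matrix (transcripts x samples), at least two samples.
#' @param topN number of transcripts used.
#' @param pseudocount added before the log transform.
#' @return Symmetric correlation matrix with unit diagonal; constant columns
#'   yield NA entries (with a warning from [stats::cor()] suppressed into a
#'   flag attribute `constant_samples`).
#' @export
pearsonMatrix <- function(hpm, topN = 2000L, pseudocount = 1) {
  if (ncol(hpm) < 2L) stop("need at least two samples")
  topN <- min(topN, nrow(hpm))
  sel <- order(rowMeans(hpm), decreasing = TRUE)[seq_len(topN)]
  lm <- log2(hpm[sel, , drop = FALSE] + pseudocount)
  const <- apply(lm, 2L, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(lm, method = "pearson"))
  diag(r) <- 1
  attr(r, "constant_samples") <- colnames(hpm)[const]
  r
}

#' Per-transcript log2 fold change
#'
#' `log2((sample + pseudocount) / (reference + pseudocount))`, both in HPM.
#' With replicated samples, fold changes are computed per replicate pair and
#' averaged on the log scale.
#'
#' @param sampleHpm matrix (or vector) of treated-sample HPM; columns are
#'   replicates.
#' @param refHpm matrix (or vector) of reference HPM, matching columns.
#' @param pseudocount HPM pseudocount.
#' @return Named numeric vector of averaged log2 fold changes.
#' @export
foldChange <- function(sampleHpm, refHpm, pseudocount = 1) {
  s <- as.matrix(sampleHpm); r <- as.matrix(refHpm)
  if (ncol(r) == 1L && ncol(s) > 1L) r <- r[, rep(1L, ncol(s)), drop = FALSE]
  if (ncol(s) == 1L && ncol(r) > 1L) s <- s[, rep(1L, ncol(r)), drop = FALSE]
  stopifnot(nrow(s) == nrow(r), ncol(s) == ncol(r))
  fc <- log2(s + pseudocount) - log2(r + pseudocount)
  rowMeans(fc)
}

#' Select transcripts with good representation in every factor
#'
#' A transcript is kept when its glucose (time-0) count, summed over
#' replicates, reaches `minCount` in each factor's dataset.
#'
#' @param se counts SummarizedExperiment from [countReads()] with `colData`
#'   columns `factor` and `time`.
#' @param minCount minimum time-0 count per factor.
#' @param factors factors that must all be represented.
#' @return Character vector of transcript ids.
#' @export
selectRepresented <- function(se, minCount = 10L,
                              factors = c("PolII", "Nab3", "Mtr4")) {
  cd <- colData(se)
  m <- assay(se, "counts")
  ok <- rep(TRUE, nrow(m))
  for (f in factors) {
    cols <- which(cd$factor == f & cd$time %in% c("0", 0))
    if (!length(cols)) stop("no time-0 sample for factor ", f)
    ok <- ok & rowSums(m[, cols, drop = FALSE]) >= minCount
  }
  rownames(m)[ok]
}

# cluster id for a sign triple, Pol II as the most significant bit:
# (P,N,M) = (+,+,+) -> 1 ... (-,-,-) -> 8
.clusterId <- function(upP, upN, upM) {
  1L + 4L * (!upP) + 2L * (!upN) + 1L * (!upM)
}

#' Directional cluster assignment from fold-change triples
#'
#' Classifies each transcript by whether Pol II, Nab3 and Mtr4 binding
#' increased or decreased after shift, mapping the sign triple to one of
#' eight clusters with Pol II as the most significant bit:
#' (P,N,M) = (+,+,+) is cluster 1, (+,+,-) 2, (+,-,+) 3, (+,-,-) 4,
#' (-,+,+) 5, (-,+,-) 6, (-,-,+) 7, (-,-,-) 8.  Cluster 5 therefore holds
#' genes losing polymerase but gaining both surveillance factors.  A
#' fold change is called "up" when it exceeds `+epsilon`; values within the
#' dead band `[-epsilon, +epsilon]` are assigned "down" by default
#' (`tieUp = FALSE`).
#'
#' @param fc data.frame or matrix with columns `PolII`, `Nab3`, `Mtr4` of
#'   averaged log2 fold changes; row names are transcript ids.
#' @param epsilon dead-band half width on the log2 scale.
#' @param tieUp whether in-band values count as "up".
#' @return data.frame with `transcript_id`, `sign_polII`, `sign_nab3`,
#'   `sign_mtr4` (`"up"`/`"down"`), `cluster_id` (1-8; NA for rows with a
#'   missing fold change).
#' @examples
#' assignClusters(data.frame(PolII = -1, Nab3 = 1, Mtr4 = 1,
#'                           row.names = "g1"))
#' @export
assignClusters <- function(fc, epsilon = 0, tieUp = FALSE) {
  fc <- as.data.frame(fc)
  stopifnot(all(c("PolII", "Nab3", "Mtr4") %in% colnames(fc)))
  up <- function(x) if (tieUp) x >= -epsilon else x > epsilon
  upP <- up(fc$PolII); upN <- up(fc$Nab3); upM <- up(fc$Mtr4)
  id <- .clusterId(upP, upN, upM)
  miss <- is.na(fc$PolII) | is.na(fc$Nab3) | is.na(fc$Mtr4)
  id[miss] <- NA_integer_
  lab <- function(u) ifelse(u, "up", "down")
  data.frame(
    transcript_id = rownames(fc),
    sign_polII = lab(upP), sign_nab3 = lab(upN), sign_mtr4 = lab(upM),
    cluster_id = id, row.names = NULL)
}
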