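# Metagene profiles and heatmap matrices aligned on TSS, poly(A) site or
# crosslink anchors.

#' Metagene profile matrix
#'
#' A transcripts-by-positions (or bins) coverage matrix with a declared
#' anchor and weighting mode.  In `per_gene_unit` mode every included row is
#' normalized to sum to 1 so each gene contributes equally to the column
#' mean; in `hpm_sum` mode rows keep their (optionally HPM-scaled) coverage
#' so column totals are additive over genes and highly bound genes dominate.
#'
#' @slot matrix numeric matrix, rows = transcripts, columns = relative
#'   positions or bins.
#' @slot anchor one of `"TSS"`, `"pA"`, `"site"`, `"span"`.
#' @slot weighting `"hpm_sum"` or `"per_gene_unit"`.
#' @slot window integer(2) for anchored profiles (NA for binned).
#' @slot nBins bin count for length-normalized profiles (NA otherwise).
#' @slot excluded named integer counts of transcripts dropped (and why).
#' @export
setClass("CracProfile", representation(
  matrix = "matrix",
  anchor = "character",
  weighting = "character",
  window = "integer",
  nBins = "integer",
  excluded = "integer"
))

setValidity("CracProfile", function(object) {
  msg <- character(0)
  if (!object@anchor %in% c("TSS", "pA", "site", "span"))
    msg <- c(msg, "unknown anchor type")
  if (!object@weighting %in% c("hpm_sum", "per_gene_unit"))
    msg <- c(msg, "unknown weighting mode")
  if (object@weighting == "per_gene_unit" && nrow(object@matrix) > 0) {
    rs <- rowSums(object@matrix, na.rm = TRUE)
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, "per_gene_unit rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CracProfile", function(object) {
  cat("CracProfile:", nrow(object@matrix), "transcripts x",
      ncol(object@matrix),
      if (is.na(object@nBins)) "positions" else "bins", "\n")
  cat("  anchor:", object@anchor, " weighting:", object@weighting, "\n")
  if (length(object@excluded))
    cat("  excluded:", paste(names(object@excluded), object@excluded,
                             sep = "=", collapse = ", "), "\n")
})

#' @describeIn CracProfile-class the profile matrix.
#' @param x a `CracProfile`.
#' @export
profileMatrix <- function(x) x@matrix

#' @describeIn CracProfile-class the mean profile across transcripts
#'   (column means, NA-aware).
#' @export
profileMean <- function(x) colMeans(x@matrix, na.rm = TRUE)

# per-transcript coverage vector in transcript sense over genomic [lo, hi]
.covVector <- function(tracks, chrom, lo, hi, strandc) {
  cov <- if (strandc == "-") tracks$minus[[chrom]] else tracks$plus[[chrom]]
  n <- hi - lo + 1L
  v <- numeric(n)
  clo <- max(lo, 1L); chi <- min(hi, length(cov))
  if (chi >= clo)
    v[(clo - lo + 1L):(chi - lo + 1L)] <-
      as.numeric(cov[clo:chi])
  if (strandc == "-") rev(v) else v
}

#' Anchored metagene profile
#'
#' Strand-aware extraction of per-nucleotide coverage relative to an anchor
#' (TSS, poly(A) site, or a supplied per-transcript site such as the
#' strongest crosslink).  Transcripts outside the length filter, or lacking
#' an anchor, are excluded and counted.
#'
#' @param tracks per-strand coverage from [coverageTracks()].
#' @param features annotation [GenomicRanges::GRanges] with `ID`, `tss`,
#'   `pA_site`.
#' @param anchor `"TSS"`, `"pA"` or `"site"`.
#' @param window integer(2), positions relative to the anchor (anchor = 0,
#'   positive downstream in transcript sense).
#' @param weighting `"per_gene_unit"` (each row normalized to sum 1) or
#'   `"hpm_sum"` (additive coverage).
#' @param lengthFilter integer(2) min/max transcript length in nt.
#' @param sites for `anchor = "site"`: GRanges of per-transcript anchors
#'   (e.g. [strongestSitePerGene()]) with `transcript_id`.
#' @return A [CracProfile-class].
#' @export
anchoredProfile <- function(tracks, features, anchor = c("TSS", "pA", "site"),
                            window = c(-100L, 2800L),
                            weighting = c("per_gene_unit", "hpm_sum"),
                            lengthFilter = c(500L, 2800L),
                            sites = NULL) {
  anchor <- match.arg(anchor)
  weighting <- match.arg(weighting)
  excluded <- c(length = 0L, no_anchor = 0L, zero_coverage = 0L)

  len <- width(features)
  okLen <- len >= lengthFilter[1] & len <= lengthFilter[2]
  excluded["length"] <- sum(!okLen)
  feats <- features[okLen]

  ids <- mcols(feats)$ID
  std <- as.character(strand(feats))
  a <- switch(anchor,
    TSS = mcols(feats)$tss,
    pA = mcols(feats)$pA_site,
    site = {
      if (is.null(sites)) stop("sites required for anchor = 'site'")
      start(sites)[match(ids, mcols(sites)$transcript_id)]
    })
  noA <- is.na(a)
  excluded["no_anchor"] <- sum(noA)
  feats <- feats[!noA]; a <- a[!noA]; std <- std[!noA]; ids <- ids[!noA]

  pos <- window[1]:window[2]
  m <- matrix(0, nrow = length(feats), ncol = length(pos),
              dimnames = list(ids, pos))
  chrom <- as.character(seqnames(feats))
  for (i in seq_along(feats)) {
    if (std[i] == "+") {
      v <- .covVector(tracks, chrom[i], a[i] + window[1], a[i] + window[2],
                      "+")
    } else {
      v <- .covVector(tracks, chrom[i], a[i] - window[2], a[i] - window[1],
                      "-")
    }
    m[i, ] <- v
  }
  if (weighting == "per_gene_unit") {
    rs <- rowSums(m)
    excluded["zero_coverage"] <- sum(rs == 0)
    m <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  new("CracProfile", matrix = m, anchor = anchor, weighting = weighting,
      window = as.integer(window), nBins = NA_integer_, excluded = excluded)
}

#' Length-normalized binned profile
#'
#' Splits each transcript span into `nBins` near-equal intervals (any
#' remainder distributed one extra nucleotide to the 5'-most bins) and sums
#' coverage within each interval, so bin totals conserve the raw coverage.
#' Transcripts shorter than `nBins` are excluded and counted.
#'
#' @param tracks per-strand coverage from [coverageTracks()].
#' @param features annotation GRanges.
#' @param nBins number of bins.
#' @param weighting as in [anchoredProfile()] (default additive).
#' @return A [CracProfile-class].
#' @export
binnedProfile <- function(tracks, features, nBins = 50L,
                          weighting = c("hpm_sum", "per_gene_unit")) {
  weighting <- match.arg(weighting)
  excluded <- c(too_short = 0L, zero_coverage = 0L)
  ok <- width(features) >= nBins
  excluded["too_short"] <- sum(!ok)
  feats <- features[ok]
  ids <- mcols(feats)$ID
  m <- matrix(0, nrow = length(feats), ncol = nBins,
              dimnames = list(ids, seq_len(nBins)))
  chrom <- as.character(seqnames(feats))
  std <- as.character(strand(feats))
  for (i in seq_along(feats)) {
    v <- .covVector(tracks, chrom[i], start(feats)[i], end(feats)[i], std[i])
    L <- length(v)
    base <- L %/% nBins; extra <- L %% nBins
    sizes <- rep(base, nBins)
    if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
    idx <- rep(seq_len(nBins), sizes)
    m[i, ] <- as.numeric(tapply(v, idx, sum))
  }
  if (weighting == "per_gene_unit") {
    rs <- rowSums(m)
    excluded["zero_coverage"] <- sum(rs == 0)
    m <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  new("CracProfile", matrix = m, anchor = "span", weighting = weighting,
      window = c(NA_integer_, NA_integer_), nBins = as.integer(nBins),
      excluded = excluded)
}

#' Order a profile matrix for heatmap display
#'
#' @param profile a [CracProfile-class].
#' @param sortBy `"length"` or a named numeric vector (e.g. fold changes)
#'   over the profile's transcripts.
#' @param features annotation (required for `sortBy = "length"`).
#' @param decreasing sort direction (default: longest / largest first, i.e.
#'   top of the heatmap).
#' @return List with `matrix` (reordered) and `order` (row labels).
#' @export
heatmapMatrix <- function(profile, sortBy = "length", features = NULL,
                          decreasing = TRUE) {
  m <- profileMatrix(profile)
  ids <- rownames(m)
  key <- if (is.character(sortBy) && length(sortBy) == 1L &&
             sortBy == "length") {
    if (is.null(features)) stop("features required for length sorting")
    width(features)[match(ids, mcols(features)$ID)]
  } else {
    as.numeric(sortBy[ids])
  }
  ord <- order(key, decreasing = decreasing)
  list(matrix = m[ord, , drop = FALSE], order = ids[ord],
       key = key[ord])
}
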