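#' Simulation configuration for synthetic CRAC experiments
#'
#' `SimConfig` bundles every tunable of the synthetic-data generator: the toy
#' genome layout, the positional binding models of the three bait proteins
#' (RNA Pol II sampling the gene body, Nab3 concentrated at its recognition
#' motif with a time-dependent 5'-to-downstream shift, Mtr4 offset downstream
#' of Nab3 sites), crosslink-induced deletion frequency, the oligo(A) tail
#' model, PCR duplication, and the 5' linker layout (random trimer followed
#' by a sample barcode).
#'
#' @slot seed integer; master seed, fixed seed implies byte-identical output.
#' @slot nTranscripts integer; number of transcription units to plant.
#' @slot transcriptLenRange integer(2); mRNA length range in nt (noncoding
#'   classes are drawn shorter).
#' @slot intronFraction numeric; fraction of mRNAs carrying exactly one intron.
#' @slot motif character; Nab3 recognition motif planted in every transcript
#'   (DNA alphabet, default `"TCTTG"`).
#' @slot deletionProb numeric; probability that a read covering the
#'   crosslinked nucleotide carries the diagnostic 1-nt deletion.
#' @slot tailModel list with `bodyMeanLen`, `paMeanLen` (mean oligo(A) tail
#'   length in nt for gene-body vs poly(A)-site reads), `tailProb` (named per
#'   factor or a single probability) and `nonARate` (per-position probability
#'   of a non-A contaminant inside a planted tail).
#' @slot pcrDupMean numeric; expected extra PCR copies per cDNA molecule
#'   (copies are `1 + Poisson(pcrDupMean)`).
#' @slot barcodeTable named character; sample -> barcode map for the 5' linker.
#' @slot umiLen integer; length of the random trimer (>= 1).
#' @slot mtr4OffsetMean numeric; mean downstream offset (nt) of Mtr4
#'   crosslinks relative to the Nab3 site.
#' @slot readsPerSample integer; cDNA molecules per library before PCR.
#' @slot insertLenRange integer(2); insert (mapped portion) length range.
#' @slot adaptor3 character; 3' sequencing adaptor appended to each read.
#' @slot paSiteFrac named numeric; per-factor fraction of reads whose insert
#'   ends exactly at the poly(A) site.
#' @slot biotypeProps named numeric; sampling proportions of
#'   mRNA/CUT/SUT/snoRNA biotypes (must sum to 1).
#' @slot intergenicLen integer; random spacer length between transcripts.
#' @slot nab3DownstreamWeight named numeric; per time point, probability that
#'   a Nab3 (or Mtr4) molecule binds the downstream rather than the
#'   5'-proximal motif instance.
#' @slot snoMargin integer; nt by which snoRNA transcribed units extend
#'   beyond the mature ends.
#' @slot targetFraction numeric; fraction of mRNAs designated surveillance
#'   targets after nutrient shift.
#' @slot shiftEffect named numeric; per-factor sampling-weight multiplier
#'   applied to target transcripts at the 4 and 8 min time points.
#'
#' @seealso [simConfig()] for the user constructor, [makeGenome()].
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nTranscripts = "integer",
  transcriptLenRange = "integer",
  intronFraction = "numeric",
  motif = "character",
  deletionProb = "numeric",
  tailModel = "list",
  pcrDupMean = "numeric",
  barcodeTable = "character",
  umiLen = "integer",
  mtr4OffsetMean = "numeric",
  readsPerSample = "integer",
  insertLenRange = "integer",
  adaptor3 = "character",
  paSiteFrac = "numeric",
  biotypeProps = "numeric",
  intergenicLen = "integer",
  nab3DownstreamWeight = "numeric",
  snoMargin = "integer",
  targetFraction = "numeric",
  shiftEffect = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  p01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (length(object@transcriptLenRange) != 2L ||
      object@transcriptLenRange[1] > object@transcriptLenRange[2])
    msg <- c(msg, "transcriptLenRange must be an ordered pair")
  if (length(object@insertLenRange) != 2L ||
      object@insertLenRange[1] > object@insertLenRange[2])
    msg <- c(msg, "insertLenRange must be an ordered pair")
  if (!p01(object@intronFraction)) msg <- c(msg, "intronFraction not in [0,1]")
  if (!p01(object@deletionProb)) msg <- c(msg, "deletionProb not in [0,1]")
  if (!p01(object@targetFraction)) msg <- c(msg, "targetFraction not in [0,1]")
  if (!p01(object@tailModel$tailProb)) msg <- c(msg, "tailProb not in [0,1]")
  if (!p01(object@tailModel$nonARate)) msg <- c(msg, "nonARate not in [0,1]")
  if (!p01(object@paSiteFrac)) msg <- c(msg, "paSiteFrac not in [0,1]")
  if (!p01(object@nab3DownstreamWeight))
    msg <- c(msg, "nab3DownstreamWeight not in [0,1]")
  if (object@umiLen < 1L) msg <- c(msg, "umiLen must be >= 1")
  if (grepl("[^ACGT]", object@motif)) msg <- c(msg, "motif must be ACGT only")
  if (abs(sum(object@biotypeProps) - 1) > 1e-8)
    msg <- c(msg, "biotypeProps must sum to 1")
  if (anyDuplicated(object@barcodeTable))
    msg <- c(msg, "barcodes must be unique")
  if (length(object@barcodeTable) &&
      length(unique(nchar(object@barcodeTable))) != 1L)
    msg <- c(msg, "barcodes must have equal length")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: Mtr4
#' crosslinks peak ~25 nt downstream of Nab3 sites, gene-body oligo(A) tails
#' average ~4 nt while poly(A)-site tails are markedly longer, and tailed
#' reads are frequent in Mtr4 libraries (~25%) but rare for Pol II (~3%).
#' After nutrient shift (time points "4" and "8"), target transcripts lose
#' Pol II and gain Nab3/Mtr4 binding, and Nab3 occupancy moves from the
#' 5'-proximal motif toward downstream sites.
#'
#' @param seed integer master seed.
#' @param nTranscripts,transcriptLenRange,intronFraction genome layout.
#' @param motif planted recognition motif (DNA).
#' @param deletionProb crosslink-deletion probability per covering read.
#' @param tailModel list; see [SimConfig-class].
#' @param pcrDupMean expected extra PCR copies per molecule.
#' @param barcodeTable named character sample->barcode map (filled on demand
#'   by [makeBarcodeTable()] when empty).
#' @param umiLen random-trimer length.
#' @param mtr4OffsetMean mean Mtr4 offset downstream of the Nab3 site (nt).
#' @param readsPerSample molecules per library.
#' @param insertLenRange insert length range (nt).
#' @param adaptor3 3' adaptor sequence.
#' @param paSiteFrac per-factor fraction of poly(A)-site-anchored reads.
#' @param biotypeProps biotype sampling proportions.
#' @param intergenicLen spacer length (nt).
#' @param nab3DownstreamWeight per-time downstream-site mixture weight.
#' @param snoMargin snoRNA transcribed-unit margin (nt).
#' @param targetFraction fraction of mRNAs that are surveillance targets.
#' @param shiftEffect per-factor weight multiplier on targets after shift.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nTranscripts = 12)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nTranscripts = 60L,
                      transcriptLenRange = c(500L, 2000L),
                      intronFraction = 0.3,
                      motif = "TCTTG",
                      deletionProb = 0.2,
                      tailModel = list(),
                      pcrDupMean = 1,
                      barcodeTable = character(0),
                      umiLen = 3L,
                      mtr4OffsetMean = 25,
                      readsPerSample = 2000L,
                      insertLenRange = c(36L, 50L),
                      adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                      paSiteFrac = c(PolII = 0.05, Nab3 = 0, Mtr4 = 0.3),
                      biotypeProps = c(mRNA = 0.7, CUT = 0.1, SUT = 0.1,
                                       snoRNA = 0.1),
                      intergenicLen = 200L,
                      nab3DownstreamWeight = c("0" = 0.1, "mock" = 0.1,
                                               "4" = 0.5, "8" = 0.8),
                      snoMargin = 50L,
                      targetFraction = 0.25,
                      shiftEffect = c(PolII = 0.25, Nab3 = 4, Mtr4 = 4)) {
  tm <- utils::modifyList(
    list(bodyMeanLen = 4, paMeanLen = 12,
         tailProb = c(PolII = 0.03, Nab3 = 0.05, Mtr4 = 0.25),
         nonARate = 0),
    tailModel)
  new("SimConfig",
      seed = as.integer(seed),
      nTranscripts = as.integer(nTranscripts),
      transcriptLenRange = as.integer(transcriptLenRange),
      intronFraction = intronFraction,
      motif = motif,
      deletionProb = deletionProb,
      tailModel = tm,
      pcrDupMean = pcrDupMean,
      barcodeTable = barcodeTable,
      umiLen = as.integer(umiLen),
      mtr4OffsetMean = mtr4OffsetMean,
      readsPerSample = as.integer(readsPerSample),
      insertLenRange = as.integer(insertLenRange),
      adaptor3 = adaptor3,
      paSiteFrac = paSiteFrac,
      biotypeProps = biotypeProps,
      intergenicLen = as.integer(intergenicLen),
      nab3DownstreamWeight = nab3DownstreamWeight,
      snoMargin = as.integer(snoMargin),
      targetFraction = targetFraction,
      shiftEffect = shiftEffect)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  seed:", object@seed,
      " transcripts:", object@nTranscripts,
      " mRNA length:", paste(object@transcriptLenRange, collapse = "-"), "\n")
  cat("  motif:", object@motif,
      " deletionProb:", object@deletionProb,
      " pcrDupMean:", object@pcrDupMean, "\n")
  cat("  tails: body", object@tailModel$bodyMeanLen, "nt / pA",
      object@tailModel$paMeanLen, "nt, prob",
      paste(sprintf("%s=%g", names(object@tailModel$tailProb),
                    object@tailModel$tailProb), collapse = " "), "\n")
  cat("  reads/sample:", object@readsPerSample,
      " Mtr4 offset:", object@mtr4OffsetMean, "nt\n")
})

#' Deterministic sample barcode table
#'
#' Assigns each sample a distinct 5-nt barcode from a fixed pool (minimum
#' pairwise Hamming distance 2), in sample order.  Purely positional, no RNG.
#'
#' @param samples character vector of sample identifiers.
#' @return Named character vector sample -> barcode.
#' @examples
#' makeBarcodeTable(c("PolII_0_1", "Nab3_0_1"))
#' @export
makeBarcodeTable <- function(samples) {
  pool <- c("ACTGA", "CAGTC", "GTCAG", "TGACT", "AGGCA", "CTTAG",
            "GACCT", "TCAAC", "ACCTG", "CGATA", "GTTCA", "TAGGC",
            "ATCGT", "CCATG", "GGTAC", "TTGCA", "AAGTG", "CTCAA",
            "GCGTT", "TACAG", "AGTCC", "CATGG", "GTACT", "TCCGA")
  samples <- unique(samples)
  if (length(samples) > length(pool))
    stop("barcode pool exhausted: at most ", length(pool), " samples")
  stats::setNames(pool[seq_along(samples)], samples)
}
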