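# Crosslink-site calling, ranking, windows, consensus scoring, motif scan.

test_that("deletion sites are tallied per position with conservation", {
  aln0 <- .mkAln("chrA", c(10L, 50L), c(40L, 80L))  # no deletions
  expect_length(callDeletionSites(aln0), 0L)

  aln <- .mkAln("chrA", rep(80L, 9), rep(120L, 9),
                deletion_pos = c(rep(100L, 7), 110L, 110L))
  sites <- callDeletionSites(aln)
  expect_identical(start(sites), c(100L, 110L))
  expect_identical(mcols(sites)$deletion_count, c(7L, 2L))
  # conservation: site counts sum to the number of deletion-bearing reads
  expect_identical(sum(mcols(sites)$deletion_count),
                   sum(!is.na(mcols(aln)$deletion_pos)))
})

test_that("top sites rank by count with deterministic tie-breaking", {
  aln <- .mkAln("chrA",
                c(rep(10L, 5), rep(200L, 3), rep(400L, 9), rep(600L, 3)),
                c(rep(40L, 5), rep(230L, 3), rep(430L, 9), rep(630L, 3)),
                deletion_pos = c(rep(20L, 5), rep(210L, 3), rep(410L, 9),
                                 rep(610L, 3)))
  sites <- callDeletionSites(aln)
  expect_identical(start(topSites(sites, 1L)), 410L)
  top2 <- topSites(sites, 2L)
  expect_identical(start(top2), c(410L, 20L))
  # tie at the cutoff: coordinate order decides
  top3 <- topSites(sites, 3L)
  expect_identical(start(top3)[3], 210L)
  expect_warning(topSites(sites, 99L), "available")
})

test_that("windows are strand-aware, centred, and padded at contig ends", {
  sim <- .tinySim()
  g <- genomeSeq(sim)
  sP <- GenomicRanges::GRanges("chrSim1", IRanges::IRanges(500L, 500L),
                               strand = "+")
  wP <- extractWindows(sP, g)
  expect_identical(width(wP), 13L)
  expect_identical(as.character(wP[[1]]),
                   as.character(Biostrings::subseq(g[["chrSim1"]], 494, 506)))
  sM <- GenomicRanges::GRanges("chrSim1", IRanges::IRanges(500L, 500L),
                               strand = "-")
  wM <- extractWindows(sM, g)
  expect_identical(as.character(wM[[1]]),
                   as.character(Biostrings::reverseComplement(wP[[1]])))
  # centre base equals the genome base (round trip)
  expect_identical(substr(as.character(wP[[1]]), 7, 7),
                   as.character(Biostrings::subseq(g[["chrSim1"]], 500, 500)))
  sEdge <- GenomicRanges::GRanges("chrSim1", IRanges::IRanges(3L, 3L),
                                  strand = "+")
  wE <- extractWindows(sEdge, g)
  expect_true(startsWith(as.character(wE[[1]]), "NNNN"))
  expect_true(mcols(wE)$clipped)
})

test_that("consensus conformance is exact-substring occurrence", {
  win <- Biostrings::DNAStringSet(rep("ACGTCTTGACGTA", 50))
  rep50 <- consensusScore(win, "TCTTG", shuffles = 5)
  expect_equal(rep50$fraction, 1)
  expect_identical(rep50$n_conforming, 50L)
  empty <- consensusScore(Biostrings::DNAStringSet(character(0)))
  expect_true(is.na(empty$fraction))
})

test_that("random-window conformance matches the closed-form rate", {
  # P(a 13-nt uniform window contains a fixed 5-mer) ~ 1 - (1 - 4^-5)^9
  p <- 1 - (1 - 4^-5)^9
  n <- 4000
  set.seed(31)
  win <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 13, TRUE), collapse = ""),
    character(1)))
  got <- consensusScore(win, "TCTTG", shuffles = 0)$fraction
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(got - p), 2.576 * se + 1e-12)
})

test_that("dinucleotide shuffling preserves composition and endpoints", {
  set.seed(9)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    sh <- shuffleDinucleotides(s)
    expect_identical(nchar(sh), nchar(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    dins <- function(x) sort(paste0(head(strsplit(x, "")[[1]], -1),
                                    strsplit(x, "")[[1]][-1]))
    expect_identical(dins(sh), dins(s))
  }
})

test_that("strongest site per gene breaks ties toward the 5' end", {
  sites <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(100L, 150L, 300L, 350L), width = 1L),
    strand = c("+", "+", "-", "-"),
    deletion_count = c(3L, 9L, 5L, 5L),
    transcript_id = c("g1", "g1", "g2", "g2"))
  top <- strongestSitePerGene(sites)
  expect_identical(start(top[mcols(top)$transcript_id == "g1"]), 150L)
  # minus strand: 5'-most is the larger coordinate
  expect_identical(start(top[mcols(top)$transcript_id == "g2"]), 350L)
})

test_that("motif scan counts overlapping occurrences per TSS window", {
  g <- Biostrings::DNAStringSet(c(chrA = paste0("CTTCTT", strrep("G", 94))))
  f <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1L, 100L),
                              strand = "+", ID = "g1", biotype = "mRNA",
                              tss = 1L, pA_site = 100L)
  sc <- motifScan(f, g, motif = "CTT", regionLen = 100L)
  expect_identical(sc$n_hits, 2L)
  scNone <- motifScan(f, g, motif = "AAA", regionLen = 100L)
  expect_identical(scNone$n_hits, 0L)
})

test_that("planted crosslink sites are recovered and conform to consensus", {
  cfg <- simConfig(seed = 29, nTranscripts = 15, deletionProb = 1,
                   tailModel = list(tailProb = 0), pcrDupMean = 0)
  sim <- makeGenome(cfg)
  lib <- simulateCracReads(sim, "Nab3", sample = "Nab3_0_1", nReads = 800,
                           seed = 6)
  pr <- prepReads(lib$reads,
                  prepConfig(barcodeTable = makeBarcodeTable("Nab3_0_1")))
  aln <- assignMultimappers(alignReads(pr$reads, genomeSeq(sim)), 3)
  sites <- callDeletionSites(aln, txFeatures(sim))
  planted <- sort(unique(lib$truth$planted_deletion_pos[
    !is.na(lib$truth$planted_deletion_pos)]))
  expect_identical(sort(start(sites)), planted)
  win <- extractWindows(suppressWarnings(topSites(sites, 50L)),
                        genomeSeq(sim))
  expect_equal(consensusScore(win, cfg@motif, shuffles = 2)$fraction, 1)
})
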