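# Metagene profiles, binning, heatmap ordering, junction ratios.

.profFeatures <- function() {
  gr <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(101L, 1201L), c(800L, 1800L)),
    strand = c("+", "-"),
    ID = c("g1", "g2"), biotype = c("mRNA", "mRNA"),
    tss = c(101L, 1800L), pA_site = c(800L, 1201L))
  GenomeInfoDb::seqlengths(gr) <- c(chrA = 3000L)
  gr
}

.uniformTracks <- function(mult = c(1, 1)) {
  # uniform coverage over each gene body; gene 2 scaled by mult[2]
  f <- .profFeatures()
  alnP <- .mkAln("chrA", rep(start(f)[1], mult[1]),
                 rep(end(f)[1], mult[1]), seqlen = 3000L)
  alnM <- .mkAln("chrA", rep(start(f)[2], mult[2]),
                 rep(end(f)[2], mult[2]), strand = "-", seqlen = 3000L,
                 read_id = sprintf("m%03d", seq_len(mult[2])))
  coverageTracks(c(alnP, alnM))
}

test_that("per-gene-unit rows are flat densities summing to one", {
  f <- .profFeatures()
  tr <- .uniformTracks()
  p <- anchoredProfile(tr, f, "TSS", window = c(0L, 299L),
                       weighting = "per_gene_unit",
                       lengthFilter = c(500L, 2800L))
  m <- profileMatrix(p)
  expect_identical(nrow(m), 2L)
  expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-9)
  expect_true(all(abs(m - 1 / 300) < 1e-12))
})

test_that("equal weighting removes coverage differences; hpm_sum keeps them", {
  f <- .profFeatures()
  tr <- .uniformTracks(c(1, 10))
  pu <- anchoredProfile(tr, f, "TSS", window = c(0L, 299L),
                        weighting = "per_gene_unit",
                        lengthFilter = c(500L, 2800L))
  m <- profileMatrix(pu)
  expect_equal(m["g1", ], m["g2", ], tolerance = 1e-12)
  ps <- anchoredProfile(tr, f, "TSS", window = c(0L, 299L),
                        weighting = "hpm_sum",
                        lengthFilter = c(500L, 2800L))
  ms <- profileMatrix(ps)
  expect_equal(unname(ms["g2", 1] / ms["g1", 1]), 10)
  # additivity of column totals over genes
  expect_equal(colSums(ms), ms["g1", ] + ms["g2", ])
})

test_that("length filter and missing anchors exclude transcripts", {
  f <- .profFeatures()
  tr <- .uniformTracks()
  p <- anchoredProfile(tr, f, "TSS", window = c(0L, 99L),
                       weighting = "per_gene_unit",
                       lengthFilter = c(601L, 2800L))
  expect_identical(nrow(profileMatrix(p)), 1L)  # g2 (600 nt) filtered out
  expect_identical(unname(p@excluded["length"]), 1L)
})

test_that("minus-strand profiles mirror plus-strand profiles", {
  f <- .profFeatures()
  # one read at the 5' end of each gene (strand-aware)
  aln <- .mkAln("chrA", c(101L, 1771L), c(130L, 1800L),
                strand = c("+", "-"), seqlen = 3000L)
  tr <- coverageTracks(aln)
  p <- anchoredProfile(tr, f, "TSS", window = c(0L, 49L),
                       weighting = "per_gene_unit",
                       lengthFilter = c(500L, 2800L))
  m <- profileMatrix(p)
  expect_equal(m["g1", ], m["g2", ], tolerance = 1e-12)
})

test_that("binned profiles follow the 5'-first remainder rule and conserve", {
  f <- GenomicRanges::GRanges("chrA", IRanges::IRanges(11L, 63L),
                              strand = "+", ID = "g1", biotype = "mRNA",
                              tss = 11L, pA_site = 63L)
  GenomeInfoDb::seqlengths(f) <- c(chrA = 200L)
  aln <- .mkAln("chrA", 11L, 63L, seqlen = 200L)
  tr <- coverageTracks(aln)
  p <- binnedProfile(tr, f, nBins = 50L)
  m <- profileMatrix(p)
  # 53 nt into 50 bins: the first three bins get 2 nt, the rest 1
  expect_equal(unname(m[1, 1:3]), c(2, 2, 2))
  expect_equal(unname(m[1, 4:50]), rep(1, 47))
  expect_equal(sum(m), 53)  # conservation of total coverage
  # uniform coverage over an exact multiple: every bin equal
  f2 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1L, 100L),
                               strand = "+", ID = "g2", biotype = "mRNA",
                               tss = 1L, pA_site = 100L)
  GenomeInfoDb::seqlengths(f2) <- c(chrA = 200L)
  aln2 <- .mkAln("chrA", c(1L, 1L, 1L), c(100L, 100L, 100L), seqlen = 200L)
  p2 <- binnedProfile(coverageTracks(aln2), f2, nBins = 50L)
  expect_true(all(profileMatrix(p2) == 6))  # 3 reads x 2-nt bins
  # too-short transcripts are excluded and counted
  f3 <- f2; end(f3) <- 30L
  p3 <- binnedProfile(coverageTracks(aln2), f3, nBins = 50L)
  expect_identical(nrow(profileMatrix(p3)), 0L)
  expect_identical(unname(p3@excluded["too_short"]), 1L)
})

test_that("heatmap ordering sorts by length or an external key", {
  f <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(1L, 201L, 501L), c(90L, 270L, 550L)),
    strand = "+", ID = c("g900", "g700", "g500"),
    biotype = "mRNA", tss = c(1L, 201L, 501L),
    pA_site = c(90L, 270L, 550L))
  GenomeInfoDb::seqlengths(f) <- c(chrA = 1000L)
  aln <- .mkAln("chrA", c(1L, 201L, 501L), c(90L, 270L, 550L),
                seqlen = 1000L)
  p <- binnedProfile(coverageTracks(aln), f, nBins = 10L)
  hm <- heatmapMatrix(p, "length", features = f)
  expect_identical(hm$order, c("g900", "g700", "g500"))
  expect_identical(nrow(hm$matrix), 3L)
  fcKey <- c(g900 = -1, g700 = 2, g500 = 0.5)
  hm2 <- heatmapMatrix(p, fcKey)
  expect_identical(hm2$order, c("g700", "g500", "g900"))
})

test_that("junction ratios follow the arithmetic and flag zero denominators", {
  allm <- c(mRNA = 1, CUT = 0, SUT = 0, snoRNA = 0)
  sim <- makeGenome(simConfig(seed = 37, nTranscripts = 4,
                              intronFraction = 1, biotypeProps = allm))
  j <- simulateJunctionReads(sim, 0.8, 10, seed = 3)
  # construct exactly 8 spliced and 2 unspliced reads on one transcript
  tid <- j$truth$transcript_id[1]
  spl <- j$reads$seq[j$truth$is_spliced][1]
  uns <- j$reads$seq[!j$truth$is_spliced][1]
  strip <- function(s) substr(s, 9L, nchar(s) - nchar(sim@config@adaptor3))
  seqs <- c(rep(strip(spl), 8), rep(strip(uns), 2))
  jr <- junctionRatio(seqs, sim)
  expect_equal(jr$aggregate$ratio, 4)
  # all-spliced input: unspliced zero, ratio undefined for that transcript
  jrS <- junctionRatio(rep(strip(spl), 5), sim)
  row <- jrS$perTranscript[jrS$perTranscript$n_spliced > 0, ]
  expect_true(row$undefined)
  expect_true(is.na(row$ratio))
  expect_error(junctionRatio(seqs, makeGenome(simConfig(seed = 37,
                                                        intronFraction = 0))),
               "introns")
})

test_that("junction counting is exact on truth-labelled reads", {
  allm <- c(mRNA = 1, CUT = 0, SUT = 0, snoRNA = 0)
  sim <- makeGenome(simConfig(seed = 41, nTranscripts = 6,
                              intronFraction = 1, biotypeProps = allm))
  j <- simulateJunctionReads(sim, 0.6, 400, minOverhang = 5L, seed = 9)
  strip <- function(s) substr(s, 9L, nchar(s) - nchar(sim@config@adaptor3))
  jr <- junctionRatio(strip(j$reads$seq), sim, minOverhang = 3L)
  expect_identical(jr$aggregate$n_spliced, sum(j$truth$is_spliced))
  expect_identical(jr$aggregate$n_unspliced, sum(!j$truth$is_spliced))
})
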