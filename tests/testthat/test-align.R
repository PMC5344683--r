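# Aligner: 5'-anchored maximal extension, deletion capture, non-templated
# tails, multi-mapper assignment, SAM round trip, tracks.

# a fixed random genome for constructed-read tests
.alnGenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(99)
      cache <<- Biostrings::DNAStringSet(
        c(chrA = paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                       collapse = "")))
    }
    cache
  }
})

.g <- function() as.character(.alnGenome()[[1]])

test_that("an exact substring aligns uniquely with no deletion or tail", {
  g <- .g()
  r <- data.frame(id = "r1", seq = substr(g, 101, 140))
  aln <- alignReads(r, .alnGenome())
  expect_length(aln, 1L)
  expect_identical(start(aln), 101L)
  expect_identical(end(aln), 140L)
  expect_true(is.na(mcols(aln)$deletion_pos))
  expect_identical(mcols(aln)$tail_seq, "")
})

test_that("a skipped genomic base is recovered as a deletion at that position", {
  g <- .g()
  # read = genome 101..140 with base 125 removed
  r <- data.frame(id = "r1",
                  seq = paste0(substr(g, 101, 124), substr(g, 126, 140)))
  aln <- alignReads(r, .alnGenome())
  expect_length(aln, 1L)
  expect_identical(start(aln), 101L)
  expect_identical(end(aln), 140L)
  # within a homopolymer run the 5'-most equivalent position is reported
  eq <- 125L
  while (eq > 101L && substr(g, eq - 1L, eq - 1L) == substr(g, eq, eq))
    eq <- eq - 1L
  expect_identical(mcols(aln)$deletion_pos, eq)
})

test_that("non-templated 3' additions become the tail; templated ones extend", {
  g <- .g()
  # pick an insert end whose next genomic base is not A
  e <- 160L
  while (substr(g, e + 1L, e + 1L) == "A") e <- e + 1L
  r1 <- data.frame(id = "r1", seq = paste0(substr(g, 121, e), "AAAA"))
  a1 <- alignReads(r1, .alnGenome())
  expect_identical(end(a1), e)
  expect_identical(mcols(a1)$tail_seq, "AAAA")
  # a suffix that equals the continuing genome is absorbed (maximal
  # extension), documenting the templated-A ambiguity
  r2 <- data.frame(id = "r2",
                   seq = paste0(substr(g, 121, e), substr(g, e + 1L, e + 2L)))
  a2 <- alignReads(r2, .alnGenome())
  expect_identical(end(a2), e + 2L)
  expect_identical(mcols(a2)$tail_seq, "")
})

test_that("brute-force maximal extension agrees with the aligner", {
  g <- .g()
  # brute-force oracle: over every start, longest 5'-anchored contiguous
  # match; the read below has a 6-nt tail that must not be extended
  set.seed(3)
  insert <- substr(g, 201, 235)
  tail <- "AATAAG"
  if (substr(g, 236, 236) == substr(tail, 1, 1)) tail <- paste0("C", tail)
  read <- paste0(insert, tail)
  bf <- function(read, g) {
    best <- c(start = NA, len = -1)
    for (s in seq_len(nchar(g) - 18L)) {
      l <- 0L
      while (s + l <= nchar(g) && l < nchar(read) &&
             substr(read, l + 1L, l + 1L) == substr(g, s + l, s + l))
        l <- l + 1L
      if (l > best["len"]) best <- c(start = s, len = l)
    }
    best
  }
  oracle <- bf(read, g)
  aln <- alignReads(data.frame(id = "r", seq = read), .alnGenome(),
                    maxDel = 0L)
  expect_identical(start(aln), as.integer(oracle[["start"]]))
  expect_identical(mcols(aln)$matched, as.integer(oracle[["len"]]))
  expect_identical(mcols(aln)$tail_seq,
                   substr(read, oracle[["len"]] + 1L, nchar(read)))
})

.revcompChr <- function(s)
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))

test_that("minus-strand reads map with correct coordinates and tail", {
  g <- .g()
  sense <- .revcompChr(substr(g, 301, 345))  # read from the minus strand
  prev <- substr(g, 300, 300)
  tail <- if (chartr("ACGT", "TGCA", prev) == "A") "CCAA" else "AAAA"
  r <- data.frame(id = "r1", seq = paste0(sense, tail))
  aln <- alignReads(r, .alnGenome())
  expect_identical(as.character(strand(aln)), "-")
  expect_identical(start(aln), 301L)
  expect_identical(end(aln), 345L)
  expect_identical(mcols(aln)$tail_seq, tail)
})

test_that("multi-mappers are assigned uniformly and deterministically", {
  set.seed(7)
  seg <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrD = paste0(pad(50), seg, pad(80), seg,
                                                pad(50))))
  reads <- data.frame(id = sprintf("r%04d", 1:2000),
                      seq = substr(seg, 1, 40))
  cand <- alignReads(reads, g)
  expect_true(all(table(mcols(cand)$read_id) == 2L))
  a1 <- assignMultimappers(cand, seed = 123)
  expect_true(all(mcols(a1)$n_loci == 2L))
  p <- mean(start(a1) == 51L)
  ci <- 0.5 + c(-1, 1) * 2.576 * sqrt(0.25 / 2000)
  expect_gt(p, ci[1]); expect_lt(p, ci[2])
  a2 <- assignMultimappers(cand, seed = 123)
  expect_identical(start(a1), start(a2))
})

test_that("SAM import honours CIGAR deletions and the extension check", {
  g <- .g()
  gs <- .alnGenome()
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:chrA\tLN:%d", nchar(g)))
  mkline <- function(id, pos, cig, seq)
    paste(id, 0L, "chrA", pos, 255, cig, "*", 0, 0, seq,
          strrep("I", nchar(seq)), sep = "\t")
  # 20M1D15M: deletion of the 21st reference base
  s1 <- paste0(substr(g, 101, 120), substr(g, 122, 136))
  # 30M5S with a non-templated clip
  clip <- if (substr(g, 231, 231) == "A") "CCCCC" else "AAAAA"
  s2 <- paste0(substr(g, 201, 230), clip)
  # 30M5S where the clip matches the genome: absorbed
  s3 <- paste0(substr(g, 301, 330), substr(g, 331, 335))
  sam <- file.path(tempdir(), "import_cases.sam")
  writeLines(c(hdr,
               mkline("d1", 101, "20M1D15M", s1),
               mkline("t1", 201, "30M5S", s2),
               mkline("t2", 301, "30M5S", s3)), sam)
  aln <- importSam(sam, gs)
  d1 <- aln[mcols(aln)$read_id == "d1"]
  expect_identical(mcols(d1)$deletion_pos, 121L)
  expect_identical(end(d1), 136L)
  t1 <- aln[mcols(aln)$read_id == "t1"]
  expect_identical(mcols(t1)$tail_seq, clip)
  expect_identical(end(t1), 230L)
  t2 <- aln[mcols(aln)$read_id == "t2"]
  expect_identical(mcols(t2)$tail_seq, "")
  expect_identical(end(t2), 335L)
})

test_that("SAM export/import round trip is lossless on synthetic data", {
  fx <- .tinyAligned()
  sam <- file.path(tempdir(), "roundtrip.sam")
  exportSam(fx$aln, genomeSeq(fx$sim), sam)
  back <- importSam(sam, genomeSeq(fx$sim))
  ord <- order(mcols(back)$read_id)
  ord0 <- order(mcols(fx$aln)$read_id)
  expect_identical(start(back)[ord], start(fx$aln)[ord0])
  expect_identical(end(back)[ord], end(fx$aln)[ord0])
  expect_identical(as.character(strand(back))[ord],
                   as.character(strand(fx$aln))[ord0])
  expect_identical(mcols(back)$deletion_pos[ord],
                   mcols(fx$aln)$deletion_pos[ord0])
  expect_identical(mcols(back)$tail_seq[ord],
                   mcols(fx$aln)$tail_seq[ord0])
})

test_that("coverage tracks step correctly and conserve mass", {
  aln <- .mkAln("chrA", c(11L, 21L), c(40L, 50L), seqlen = 100L)
  tr <- coverageTracks(aln)
  v <- as.numeric(tr$plus[["chrA"]])
  expect_identical(v[11:20], rep(1, 10))
  expect_identical(v[21:40], rep(2, 20))
  expect_identical(v[41:50], rep(1, 10))
  expect_equal(sum(v), sum(width(aln)))
  # deletion track: 7 reads deleting position 70
  alnD <- .mkAln("chrA", rep(60L, 7), rep(90L, 7), deletion_pos = 70L,
                 seqlen = 100L)
  trD <- coverageTracks(alnD, "deletions")
  vd <- as.numeric(trD$plus[["chrA"]])
  expect_equal(vd[70], 7)
  expect_equal(sum(vd), 7)
  # bedgraph files round-trip through rtracklayer
  pre <- file.path(tempdir(), "bgtest")
  writeBedgraph(tr, pre)
  bg <- rtracklayer::import(paste0(pre, ".plus.bedgraph"), format = "bedGraph")
  expect_equal(sum(bg$score * width(bg)), sum(width(aln)))
})

test_that("planted alignments are recovered exactly on the toy genome", {
  fx <- .tinyAligned()
  m <- match(mcols(fx$aln)$read_id, fx$lib$truth$read_id)
  tr <- fx$lib$truth[m, ]
  expect_identical(start(fx$aln), tr$genomic_start)
  expect_identical(end(fx$aln), tr$genomic_end)
  expect_identical(mcols(fx$aln)$tail_seq, tr$planted_tail_seq)
  delOK <- (is.na(tr$planted_deletion_pos) &
              is.na(mcols(fx$aln)$deletion_pos)) |
    (!is.na(tr$planted_deletion_pos) &
       tr$planted_deletion_pos == mcols(fx$aln)$deletion_pos)
  expect_true(all(delOK, na.rm = TRUE))
})
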