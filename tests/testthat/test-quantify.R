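# Counting, HPM scaling, ratios, correlations, fold changes, clusters.

.mkFeatures <- function() {
  gr <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(101L, 501L), c(400L, 900L)),
    strand = c("+", "-"),
    ID = c("g1", "g2"), biotype = c("mRNA", "mRNA"),
    tss = c(101L, 900L), pA_site = c(400L, 501L))
  GenomeInfoDb::seqlengths(gr) <- c(chrA = 2000L)
  gr
}

test_that("reads count to the sense transcript with the largest overlap", {
  f <- .mkFeatures()
  aln <- .mkAln("chrA", c(150L, 550L, 150L, 1500L),
                c(180L, 580L, 180L, 1530L),
                strand = c("+", "+", "-", "+"),
                seqlen = 2000L)
  se <- countReads(list(s1 = aln), f)
  cts <- SummarizedExperiment::assay(se, "counts")
  expect_identical(cts["g1", "s1"], 1L)   # sense read inside g1
  expect_identical(cts["g2", "s1"], 0L)   # g2 is minus; plus read uncounted
  expect_identical(SummarizedExperiment::colData(se)$uncounted, 3L)
  expect_error(countReads(list(s1 = aln), GenomicRanges::GRanges()), "empty")
})

test_that("counts match the truth tally exactly on synthetic data", {
  fx <- .tinyAligned()
  se <- countReads(list(Nab3_0_1 = fx$aln), txFeatures(fx$sim))
  cts <- SummarizedExperiment::assay(se, "counts")[, 1]
  truth <- fx$lib$truth[match(mcols(fx$aln)$read_id,
                              fx$lib$truth$read_id), ]
  want <- table(truth$transcript_id)
  expect_identical(cts[names(want)], stats::setNames(as.integer(want),
                                                     names(want)))
})

test_that("hits-per-million scales over the stated universe", {
  m <- matrix(c(5L, 15L), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  h <- hitsPerMillion(m, c("A", "B"))
  expect_equal(h["A", "s1"], 250000)
  expect_equal(hitsPerMillion(m, "A")["A", "s1"], 1e6)  # single-gene universe
  expect_equal(hitsPerMillion(m * 2L), h)                # scale invariance
  expect_equal(unname(colSums(h)), 1e6)                  # conservation
  expect_error(hitsPerMillion(matrix(0L, 1, 1,
                                     dimnames = list("A", "s"))), "zero")
})

test_that("binding ratios divide factor HPM by polymerase HPM", {
  r <- bindingRatio(c(g = 100), c(g = 50), pseudocount = 0)
  expect_equal(r$ratio, 2)
  expect_equal(bindingRatio(c(g = 0), c(g = 50), 0)$ratio, 0)
  # scaling both libraries leaves the ratio unchanged
  r2 <- bindingRatio(c(g = 300), c(g = 150), pseudocount = 0)
  expect_equal(r2$ratio, r$ratio)
  expect_true(bindingRatio(c(g = 1), c(g = 0), 0)$undefined)
})

test_that("Pearson matrix matches the textbook formula on the selection", {
  set.seed(42)
  hpm <- matrix(rexp(3000, 1 / 100), ncol = 3,
                dimnames = list(sprintf("g%d", 1:1000),
                                c("a", "b", "b2")))
  hpm[, "b2"] <- hpm[, "b"]               # duplicated sample
  r <- pearsonMatrix(hpm, topN = 500)
  expect_equal(r["b", "b2"], 1)
  expect_equal(r, t(r))
  # oracle: explicit sum formula on the same selection
  sel <- order(rowMeans(hpm), decreasing = TRUE)[1:500]
  x <- log2(hpm[sel, "a"] + 1); y <- log2(hpm[sel, "b"] + 1)
  n <- length(x)
  manual <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(r["a", "b"], manual)
})

test_that("independent samples are near-uncorrelated", {
  set.seed(7)
  hpm <- matrix(rexp(4000, 1), ncol = 2,
                dimnames = list(sprintf("g%d", 1:2000), c("a", "b")))
  r <- pearsonMatrix(hpm, topN = 2000)
  expect_lt(abs(r["a", "b"]), 0.1)
})

test_that("fold changes are log2 ratios averaged over replicates", {
  expect_equal(unname(foldChange(c(g = 8), c(g = 8))), 0)
  expect_equal(unname(foldChange(c(g = 400), c(g = 100),
                                 pseudocount = 1e-9)), 2, tolerance = 1e-6)
  s <- matrix(c(2, 8), nrow = 1, dimnames = list("g", c("r1", "r2")))
  r <- matrix(c(1, 1), nrow = 1, dimnames = list("g", c("r1", "r2")))
  expect_equal(unname(foldChange(s, r, pseudocount = 1e-9)),
               mean(c(1, 3)), tolerance = 1e-6)
})

test_that("representation filtering keys on time-0 counts per factor", {
  m <- rbind(g1 = c(20L, 20L, 20L),
             g2 = c(20L, 0L, 20L),   # absent in the Nab3 dataset
             g3 = c(5L, 5L, 5L))
  colnames(m) <- c("PolII_0", "Nab3_0", "Mtr4_0")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(factor = c("PolII", "Nab3", "Mtr4"),
                                   time = "0",
                                   row.names = colnames(m)))
  expect_identical(selectRepresented(se, minCount = 0L),
                   c("g1", "g2", "g3"))
  expect_identical(selectRepresented(se, minCount = 1L), c("g1", "g3"))
  expect_identical(selectRepresented(se, minCount = 10L), "g1")
})

test_that("cluster assignment maps sign triples as documented", {
  expect_identical(assignClusters(data.frame(PolII = 1, Nab3 = 1, Mtr4 = 1,
                                             row.names = "g"))$cluster_id, 1L)
  expect_identical(assignClusters(data.frame(PolII = -1, Nab3 = -1,
                                             Mtr4 = -1,
                                             row.names = "g"))$cluster_id, 8L)
  expect_identical(assignClusters(data.frame(PolII = -1, Nab3 = 1, Mtr4 = 1,
                                             row.names = "g"))$cluster_id, 5L)
  # all eight sign triples map to eight distinct ids
  grid <- expand.grid(PolII = c(1, -1), Nab3 = c(1, -1), Mtr4 = c(1, -1))
  rownames(grid) <- sprintf("t%d", 1:8)
  expect_setequal(assignClusters(grid)$cluster_id, 1:8)
  # missing fold change -> unclassified
  expect_true(is.na(assignClusters(data.frame(PolII = NA, Nab3 = 1,
                                              Mtr4 = 1,
                                              row.names = "g"))$cluster_id))
})

test_that("cluster assignment equals brute-force enumeration", {
  set.seed(11)
  fc <- data.frame(PolII = rnorm(1000), Nab3 = rnorm(1000),
                   Mtr4 = rnorm(1000),
                   row.names = sprintf("g%04d", 1:1000))
  got <- assignClusters(fc)$cluster_id
  # independent oracle: explicit lookup table over sign triples
  key <- paste0(ifelse(fc$PolII > 0, "+", "-"),
                ifelse(fc$Nab3 > 0, "+", "-"),
                ifelse(fc$Mtr4 > 0, "+", "-"))
  lut <- c("+++" = 1L, "++-" = 2L, "+-+" = 3L, "+--" = 4L,
           "-++" = 5L, "-+-" = 6L, "--+" = 7L, "---" = 8L)
  expect_identical(got, unname(lut[key]))
})
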