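# End-to-end orchestration of the synthetic CRAC experiment.

#' Build a factor x time x replicate sample sheet
#'
#' @param factors bait proteins.
#' @param times time point labels.
#' @param replicates replicate indices.
#' @return data.frame with `sample_id`, `factor`, `time`, `replicate`;
#'   `sample_id` is `<factor>_<time>_<replicate>`.
#' @export
makeSampleSheet <- function(factors = c("PolII", "Nab3", "Mtr4"),
                            times = c("0", "4", "8"),
                            replicates = 1:2) {
  g <- expand.grid(replicate = replicates, time = times, factor = factors,
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d", g$factor, g$time, g$replicate),
    factor = g$factor, time = as.character(g$time),
    replicate = g$replicate, stringsAsFactors = FALSE)
}

#' Read a sample sheet from TSV
#'
#' Expects columns `sample_id`, `factor`, `time`, `replicate` (and
#' optionally `path` for pre-aligned SAM input).  (factor, time, replicate)
#' must be unique.
#'
#' @param path TSV path.
#' @return data.frame sample sheet.
#' @export
readSampleSheet <- function(path) {
  sheet <- .read_tsv(path)
  need <- c("sample_id", "factor", "time", "replicate")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$time <- as.character(sheet$time)
  key <- paste(sheet$factor, sheet$time, sheet$replicate)
  if (anyDuplicated(key)) stop("duplicate (factor, time, replicate) rows")
  sheet
}

#' Average replicate columns
#'
#' Arithmetic mean over replicates of the same condition, intended for HPM
#' values or log2 fold changes (already log-scale).  Conditions with a
#' single replicate pass through and are flagged.
#'
#' @param m matrix with one column per sample.
#' @param groups character vector assigning each column to a condition.
#' @return List with `mean` (matrix, one column per condition) and
#'   `single_replicate` (logical per condition).
#' @export
replicateAverage <- function(m, groups) {
  stopifnot(ncol(m) == length(groups))
  ug <- unique(groups)
  out <- matrix(NA_real_, nrow = nrow(m), ncol = length(ug),
                dimnames = list(rownames(m), ug))
  single <- stats::setNames(logical(length(ug)), ug)
  for (g in ug) {
    cols <- which(groups == g)
    out[, g] <- rowMeans(m[, cols, drop = FALSE])
    single[g] <- length(cols) == 1L
  }
  list(mean = out, single_replicate = single)
}

.stage <- function(name, sample, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed",
         if (!is.null(sample)) paste0(" for sample '", sample, "'"),
         ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic CRAC experiment
#'
#' Generates the toy genome, simulates one library per sample-sheet row,
#' preprocesses, aligns and assigns reads, writes per-sample tracks, and
#' produces the cross-sample result tables: counts, HPM, factor:Pol II
#' ratios, Pearson matrix, fold changes and clusters, crosslink sites with
#' the consensus-motif report, oligo(A) tail statistics, metagene profiles,
#' and spliced:unspliced junction ratios.  Every artifact is a file under
#' `outDir`, listed with its MD5 checksum in `manifest.json`, so two runs
#' with the same seed are byte-identical.
#'
#' When a factor needed by a stage is absent from the sample sheet (e.g. no
#' Mtr4 libraries), that stage is skipped and the reason recorded in the
#' manifest; all other stages still run.
#'
#' @param simCfg a [SimConfig-class] (the barcode table is filled from the
#'   sample sheet automatically).
#' @param sheet sample sheet from [makeSampleSheet()] or [readSampleSheet()].
#' @param outDir run directory (created).
#' @param seed master seed for all pipeline randomness.
#' @param minCount representation threshold for clustering.
#' @param profileWindow,profileLengthFilter TSS-profile geometry (defaults
#'   scaled to the toy genome).
#' @param siteWindow window around the strongest crosslink site.
#' @param junctionReads,splicedFraction junction-library settings
#'   (`junctionReads = 0` skips the junction stage).
#' @param verbose emit per-stage log lines (read-count conservation
#'   included).
#' @return Invisibly, a list with in-memory results (`se`, `hpm`, `fc`,
#'   `clusters`, `sites`, `motifReport`, `tailStats`, ...) and the manifest.
#' @export
runPipeline <- function(simCfg, sheet = makeSampleSheet(), outDir,
                        seed = simCfg@seed,
                        minCount = 10L,
                        profileWindow = c(-50L, 500L),
                        profileLengthFilter = c(500L, 2800L),
                        siteWindow = c(-100L, 150L),
                        junctionReads = 1000L,
                        splicedFraction = 0.8,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("genome", "reads", "prep", "align", "tracks", "tables",
              "profiles"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  skipped <- list()

  simCfg@barcodeTable <- makeBarcodeTable(sheet$sample_id)
  sim <- .stage("genome", NULL, makeGenome(simCfg))
  writeGenomeFiles(sim, file.path(outDir, "genome"))
  feats <- sim@features

  alnBySample <- list()
  prepBySample <- list()
  truthBySample <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    sseed <- seed + 7919L * i
    lib <- .stage("simulate", sid,
                  simulateCracReads(sim, sheet$factor[i], sheet$time[i],
                                    sample = sid,
                                    seed = sseed))
    writeReadsFastq(lib$reads, file.path(outDir, "reads",
                                         paste0(sid, ".fastq")))
    .write_tsv(lib$truth, file.path(outDir, "reads",
                                    paste0(sid, ".truth.tsv")))
    truthBySample[[sid]] <- lib$truth

    pcfg <- prepConfig(adaptor3 = simCfg@adaptor3,
                       barcodeTable = simCfg@barcodeTable,
                       umiLen = simCfg@umiLen)
    pr <- .stage("prep", sid, prepReads(lib$reads, pcfg))
    say(sprintf("[prep] %s: input=%d kept=%d (conservation: %d = %d)",
                sid, pr$stats["input"], pr$stats["kept"],
                pr$stats["input"], sum(pr$stats[-1])))
    jsonlite::write_json(as.list(pr$stats),
                         file.path(outDir, "prep", paste0(sid, ".stats.json")),
                         auto_unbox = TRUE)
    prepBySample[[sid]] <- pr$reads

    cand <- .stage("align", sid, alignReads(pr$reads, sim@genome))
    asn <- assignMultimappers(cand, seed = sseed + 1L)
    exportSam(asn, sim@genome,
              file.path(outDir, "align", paste0(sid, ".sam")))
    alnBySample[[sid]] <- asn
    say(sprintf("[align] %s: %d assigned, %d unmapped", sid, length(asn),
                length(attr(cand, "unmapped"))))
    tr <- coverageTracks(asn)
    writeBedgraph(tr, file.path(outDir, "tracks", sid))
    if (any(!is.na(mcols(asn)$deletion_pos)))
      writeBedgraph(coverageTracks(asn, "deletions"),
                    file.path(outDir, "tracks", paste0(sid, ".deletions")))
  }

  se <- .stage("count", NULL,
               countReads(alnBySample, feats, seed = seed,
                          colData = DataFrame(factor = sheet$factor,
                                              time = sheet$time,
                                              replicate = sheet$replicate,
                                              row.names = sheet$sample_id)))
  cts <- assay(se, "counts")
  .write_tsv(data.frame(transcript_id = rownames(cts),
                        biotype = mcols(feats)$biotype[
                          match(rownames(cts), mcols(feats)$ID)],
                        cts, check.names = FALSE),
             file.path(outDir, "tables", "counts.tsv"))
  hpm <- hitsPerMillion(se)
  .write_tsv(data.frame(transcript_id = rownames(hpm), hpm,
                        check.names = FALSE),
             file.path(outDir, "tables", "hpm.tsv"))

  cond <- paste(sheet$factor, sheet$time, sep = "_")
  ra <- replicateAverage(hpm, cond)
  avg <- ra$mean

  factors <- unique(sheet$factor)
  times <- unique(sheet$time)

  # factor : Pol II ratios per time point
  if ("PolII" %in% factors) {
    for (f in setdiff(intersect(c("Nab3", "Mtr4"), factors), NA)) {
      for (tp in times) {
        cf <- paste(f, tp, sep = "_"); cp <- paste("PolII", tp, sep = "_")
        if (!cf %in% colnames(avg) || !cp %in% colnames(avg)) next
        rr <- bindingRatio(stats::setNames(avg[, cf], rownames(avg)),
                           stats::setNames(avg[, cp], rownames(avg)))
        .write_tsv(rr, file.path(outDir, "tables",
                                 sprintf("ratio_%s_vs_PolII_t%s.tsv", f, tp)))
      }
    }
  } else {
    skipped$ratios <- "no PolII samples"
  }

  pear <- pearsonMatrix(hpm, topN = min(2000L, nrow(hpm)))
  .write_tsv(data.frame(sample = rownames(pear), round(pear, 6),
                        check.names = FALSE),
             file.path(outDir, "tables", "pearson.tsv"))

  # fold changes (latest time vs 0, replicates averaged) and clusters
  fcTab <- NULL; clusters <- NULL
  shiftT <- intersect(c("8", "4"), times)[1]
  if (!is.na(shiftT) && "0" %in% times) {
    fcs <- list()
    for (f in factors) {
      sc <- which(sheet$factor == f & sheet$time == shiftT)
      rc <- which(sheet$factor == f & sheet$time == "0")
      if (!length(sc) || !length(rc)) next
      fcs[[f]] <- foldChange(hpm[, sheet$sample_id[sc], drop = FALSE],
                             hpm[, sheet$sample_id[rc], drop = FALSE])
    }
    if (all(c("PolII", "Nab3", "Mtr4") %in% names(fcs))) {
      fcTab <- data.frame(PolII = fcs$PolII, Nab3 = fcs$Nab3,
                          Mtr4 = fcs$Mtr4,
                          row.names = rownames(hpm))
      rep_ids <- selectRepresented(se, minCount = minCount)
      clusters <- assignClusters(fcTab[rep_ids, , drop = FALSE])
      .write_tsv(data.frame(transcript_id = rownames(fcTab),
                            round(fcTab, 6), check.names = FALSE),
                 file.path(outDir, "tables", "fold_changes.tsv"))
      .write_tsv(clusters, file.path(outDir, "tables", "clusters.tsv"))
    } else {
      skipped$clustering <- paste(
        "need PolII, Nab3 and Mtr4 at times 0 and", shiftT, "- have:",
        paste(names(fcs), collapse = ", "))
      say("[cluster] skipped: ", skipped$clustering)
    }
  } else {
    skipped$clustering <- "need time 0 and a post-shift time point"
  }

  # crosslink sites from post-shift Nab3 libraries (fall back to all Nab3)
  sites <- NULL; motifReport <- NULL; anchors <- NULL
  nab3post <- sheet$sample_id[sheet$factor == "Nab3" &
                                sheet$time %in% c("4", "8")]
  if (!length(nab3post)) nab3post <- sheet$sample_id[sheet$factor == "Nab3"]
  if (length(nab3post)) {
    pooled <- unlist(GenomicRanges::GRangesList(
      unname(alnBySample[nab3post])))
    sites <- callDeletionSites(pooled, feats)
    if (length(sites)) {
      top <- suppressWarnings(topSites(sites, 50L))
      win <- extractWindows(top, sim@genome)
      motifReport <- consensusScore(win, consensus = simCfg@motif,
                                    seed = seed)
      anchors <- strongestSitePerGene(sites)
      rtracklayer::export(sites, file.path(outDir, "tables", "sites.bed"),
                          format = "BED")
      writeXStringSet(win, file.path(outDir, "tables", "site_windows.fasta"))
      jsonlite::write_json(
        list(n_windows = motifReport$n_windows,
             n_conforming = motifReport$n_conforming,
             fraction = motifReport$fraction),
        file.path(outDir, "tables", "motif_report.json"), auto_unbox = TRUE)
    }
  } else {
    skipped$crosslink <- "no Nab3 samples"
  }

  # oligo(A) tails per sample
  tailStats <- list()
  for (sid in names(alnBySample)) {
    calls <- callTails(alnBySample[[sid]], prepBySample[[sid]], feats)
    tailStats[[sid]] <- tailFraction(calls)
    if (sheet$factor[match(sid, sheet$sample_id)] == "Mtr4") {
      tt <- tailedReadTrack(alnBySample[[sid]], calls)
      writeBedgraph(tt, file.path(outDir, "tracks", paste0(sid, ".tailed")))
    }
  }
  .write_tsv(data.frame(
    sample = names(tailStats),
    total_reads_with_adaptor = vapply(tailStats, `[[`, numeric(1),
                                      "total_reads_with_adaptor"),
    n_tailed = vapply(tailStats, `[[`, numeric(1), "n_tailed"),
    fraction_tailed = vapply(tailStats, `[[`, numeric(1),
                             "fraction_tailed")),
    file.path(outDir, "tables", "tail_stats.tsv"))

  # metagene profiles
  profiles <- list()
  for (f in intersect(c("PolII", "Nab3", "Mtr4"), factors)) {
    for (tp in times) {
      sids <- sheet$sample_id[sheet$factor == f & sheet$time == tp]
      if (!length(sids)) next
      pooled <- unlist(GenomicRanges::GRangesList(unname(alnBySample[sids])))
      trk <- coverageTracks(pooled, hpm = TRUE)
      p <- anchoredProfile(trk, feats, "TSS", window = profileWindow,
                           weighting = "per_gene_unit",
                           lengthFilter = profileLengthFilter)
      key <- sprintf("%s_t%s_TSS", f, tp)
      profiles[[key]] <- p
      .write_tsv(data.frame(position = as.integer(colnames(profileMatrix(p))),
                            mean = profileMean(p)),
                 file.path(outDir, "profiles", paste0(key, ".tsv")))
      if (f == "Mtr4" && !is.null(anchors) && length(anchors)) {
        ps <- anchoredProfile(trk, feats, "site", window = siteWindow,
                              weighting = "per_gene_unit",
                              lengthFilter = profileLengthFilter,
                              sites = anchors)
        key2 <- sprintf("Mtr4_t%s_site", tp)
        profiles[[key2]] <- ps
        .write_tsv(data.frame(
          position = as.integer(colnames(profileMatrix(ps))),
          mean = profileMean(ps)),
          file.path(outDir, "profiles", paste0(key2, ".tsv")))
      }
    }
  }

  # junction stage
  junctions <- NULL
  if (junctionReads > 0L &&
      any(!is.na(mcols(feats)$intron_start))) {
    jl <- simulateJunctionReads(sim, splicedFraction, junctionReads,
                                sample = "JUNC", seed = seed + 77L)
    pcJ <- prepConfig(adaptor3 = simCfg@adaptor3,
                      barcodeTable = makeBarcodeTable("JUNC"),
                      umiLen = simCfg@umiLen)
    prJ <- prepReads(jl$reads, pcJ)
    junctions <- junctionRatio(prJ$reads$seq, sim)
    .write_tsv(junctions$perTranscript,
               file.path(outDir, "tables", "junction_ratios.tsv"))
  }

  # manifest with checksums of every artifact
  files <- sort(list.files(outDir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- list(
    n_samples = nrow(sheet),
    skipped = skipped,
    files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sim = sim, se = se, hpm = hpm, pearson = pear,
                 fc = fcTab, clusters = clusters, sites = sites,
                 motifReport = motifReport, anchors = anchors,
                 tailStats = tailStats, profiles = profiles,
                 junctions = junctions,
                 truth = truthBySample, prep = prepBySample,
                 aln = alnBySample,
                 manifest = manifest, skipped = skipped))
}
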