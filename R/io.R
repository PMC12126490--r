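#' Read a family-labelled BED annotation
#'
#' Expects the package's 6+2-column BED dialect: chrom, start, end, name
#' (locus id), role (carried in place of the unused BED score column),
#' strand, family, integration_id; coordinates 0-based half-open.
#' Malformed lines are reported with their line numbers; overlapping loci or
#' start >= end abort with the offenders listed.
#'
#' @param path BED file path.
#' @return a [RepeatAnnotation-class].
#' @export
readBedAnnotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 8L)
  if (length(bad)) {
    stopf("malformed BED line(s) (expected 8 tab-separated columns): %s",
          paste(bad, collapse = ", "))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stopf("invalid interval(s) (non-numeric or start >= end) at line(s): %s",
          paste(bad, collapse = ", "))
  }
  bad <- which(!m[, 6L] %in% c("+", "-"))
  if (length(bad)) {
    stopf("invalid strand at line(s): %s", paste(bad, collapse = ", "))
  }
  gr <- GRanges(m[, 1L], IRanges(start = start + 1L, end = end),
                strand = m[, 6L])
  mcols(gr)$family <- m[, 7L]
  mcols(gr)$role <- m[, 5L]
  mcols(gr)$integration_id <- m[, 8L]
  mcols(gr)$locus_id <- m[, 4L]
  RepeatAnnotation(gr)
}

#' Write a RepeatAnnotation in the 6+2-column BED dialect
#'
#' @param annotation a [RepeatAnnotation-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBedAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "RepeatAnnotation"))
  gr <- annotationRanges(annotation)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = mcols(gr)$locus_id, role = mcols(gr)$role,
                   strand = as.character(strand(gr)),
                   family = mcols(gr)$family,
                   integration_id = mcols(gr)$integration_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a locus count table
#'
#' TSV with header `locus_id dataset chip_count input_count`; library totals
#' travel in `#library_total <dataset> <chip_total> <input_total>` header
#' comments so one file round-trips the whole object.
#'
#' @param path TSV path.
#' @return a [LocusCounts-class].
#' @export
readCountsTsv <- function(path) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#library_total\t", lines, value = TRUE)
  if (!length(hdr)) stopf("counts file lacks #library_total header lines")
  parts <- do.call(rbind, strsplit(hdr, "\t", fixed = TRUE))
  lt <- data.frame(dataset = parts[, 2L],
                   chip_total = as.numeric(parts[, 3L]),
                   input_total = as.numeric(parts[, 4L]))
  body <- lines[!startsWith(lines, "#")]
  cc <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  LocusCounts(cc, lt)
}

#' @param counts a [LocusCounts-class].
#' @rdname readCountsTsv
#' @export
writeCountsTsv <- function(counts, path) {
  stopifnot(is(counts, "LocusCounts"))
  lt <- libraryTotals(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#library_total\t%s\t%s\t%s", lt$dataset,
                     format(lt$chip_total, scientific = FALSE, trim = TRUE),
                     format(lt$input_total, scientific = FALSE, trim = TRUE)),
             con)
  utils::write.table(countTable(counts), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a titration, peak-list or FRAP table
#'
#' Plain TSVs with headers: titrations `L I_obs`, peak lists
#' `residue dH dN intensity`, FRAP `time intensity_bleached
#' intensity_unbleached`.
#'
#' @param path TSV path.
#' @param p_total protein concentration attached to the titration series.
#' @return data.frame (titration series carry a `p_total` attribute).
#' @export
readTitrationTsv <- function(path, p_total) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("L", "I_obs") %in% names(df))) {
    stopf("titration TSV needs columns L and I_obs")
  }
  attr(df, "p_total") <- p_total
  df
}

#' @rdname readTitrationTsv
#' @export
readPeakListTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("residue", "dH", "dN", "intensity")
  if (!all(need %in% names(df))) {
    stopf("peak-list TSV needs columns %s", paste(need, collapse = ", "))
  }
  df
}

#' @rdname readTitrationTsv
#' @export
readFrapTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("time", "intensity_bleached", "intensity_unbleached")
  if (!all(need %in% names(df))) {
    stopf("FRAP TSV needs columns %s", paste(need, collapse = ", "))
  }
  df
}

#' Read / write per-base coverage as bedGraph
#'
#' Coverage is held in memory as one numeric vector per chromosome (element
#' p covers 0-based base p-1). On disk it is standard 4-column bedGraph;
#' zero runs are written too, so round-trips are exact given the chromosome
#' lengths.
#'
#' @param path bedGraph file path.
#' @param chrom_lengths named integer vector of chromosome lengths; bases
#'   beyond the last record are zero-filled up to these lengths.
#' @return named list of per-base numeric vectors.
#' @export
readBedGraphCoverage <- function(path, chrom_lengths) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("bedGraph I/O needs the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(chrom_lengths), function(chrom) {
    v <- numeric(chrom_lengths[[chrom]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    for (i in seq_along(g)) {
      v[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <-
        S4Vectors::mcols(g)$score[i]
    }
    v
  })
  stats::setNames(out, names(chrom_lengths))
}

#' @param coverage named list of per-base numeric vectors.
#' @rdname readBedGraphCoverage
#' @export
writeBedGraphCoverage <- function(coverage, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("bedGraph I/O needs the rtracklayer package")
  }
  runs <- lapply(names(coverage), function(chrom) {
    r <- rle(coverage[[chrom]])
    ends <- cumsum(r$lengths)
    data.frame(chrom = chrom, start = ends - r$lengths + 1L, end = ends,
               score = r$values)
  })
  df <- do.call(rbind, runs)
  gr <- GRanges(df$chrom, IRanges(start = df$start, end = df$end),
                score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

writeTsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Derive a deterministic per-base coverage track from locus counts
#'
#' Spreads each locus's ChIP count uniformly over its interval (count /
#' width per base) on an otherwise flat low background. A deterministic
#' stand-in for an aligned coverage track, used by the demo pipeline and
#' tests.
#'
#' @param annotation a [RepeatAnnotation-class].
#' @param counts a [LocusCounts-class].
#' @param dataset dataset id to extract.
#' @param genome_length chromosome length in bp (defaults to the annotation's
#'   recorded genome length).
#' @param background per-base background level.
#' @return named list with one per-base numeric vector.
#' @export
coverageFromCounts <- function(annotation, counts, dataset,
                               genome_length = NULL, background = 0.01) {
  gr <- annotationRanges(annotation)
  if (is.null(genome_length)) {
    genome_length <- S4Vectors::metadata(gr)$genome_length
    if (is.null(genome_length)) genome_length <- max(end(gr)) + 1000L
  }
  cc <- countTable(counts)
  cc <- cc[cc$dataset == dataset, ]
  if (!nrow(cc)) stopf("dataset '%s' absent from the count table", dataset)
  v <- rep(background, genome_length)
  idx <- match(mcols(gr)$locus_id, cc$locus_id)
  for (i in seq_along(gr)) {
    if (is.na(idx[i])) next
    v[start(gr)[i]:end(gr)[i]] <-
      cc$chip_count[idx[i]] / width(gr)[i]
  }
  stats::setNames(list(v), as.character(seqnames(gr))[1L] %||% "chrSim")
}

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers become numeric.
#'
#' @param path config file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stopf("malformed config line(s): %s", paste(bad, collapse = ", "))
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}

#' Run the full demo pipeline: simulate, enrich, LTR, bins
#'
#' Executes the stages in a fixed order, writes every artifact under the
#' output directory, and finishes with a manifest of MD5 content hashes.
#' Identical config and seed yield byte-identical artifacts and therefore an
#' identical manifest. A stage failure aborts with the stage name and leaves
#' the partial outputs under a `failed/` marker directory.
#'
#' @param config named list (see [readRunConfig()]) or path to a flat config
#'   file. Recognized keys: `seed`, `outdir`, `n_families`,
#'   `loci_per_family`, `genome_length`, `input_mean`, `nb_dispersion`,
#'   `orphan_fraction`, `bin_width`, `window_up`, `window_down`, `bin_size`.
#' @return data.frame manifest (file, md5), invisibly written to
#'   `manifest.tsv`.
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  getc <- function(key, default) config[[key]] %||% default
  outdir <- getc("outdir", tempfile("ervscape_run_"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # full parameter provenance: every effective value, echoed machine-readably
  params <- list(
    seed = getc("seed", 1), n_families = getc("n_families", 8),
    loci_per_family = getc("loci_per_family", 30),
    genome_length = getc("genome_length", 8e6),
    input_mean = getc("input_mean", 20),
    nb_dispersion = getc("nb_dispersion", 10),
    orphan_fraction = getc("orphan_fraction", 0.3),
    bin_width = getc("bin_width", 5000),
    window_up = getc("window_up", 1500),
    window_down = getc("window_down", 8000),
    bin_size = getc("bin_size", 50))
  writeTsv(data.frame(key = names(params), value = unlist(params)),
           file.path(outdir, "run_params.tsv"))

  stage <- "simulate"
  result <- tryCatch({
    fams <- sprintf("family_%02d", seq_len(params$n_families))
    ef <- stats::setNames(2^seq(0, 3, length.out = params$n_families), fams)
    cfg <- simulationConfig(
      seed = params$seed, n_families = params$n_families,
      loci_per_family = params$loci_per_family,
      genome_length = params$genome_length,
      enrichment_factors = list(chip1 = ef, chip2 = rev(ef)),
      nb_dispersion = params$nb_dispersion,
      library_sizes = list(chip1 = list(chip = 2e6, input = 1e6),
                           chip2 = list(chip = 1e6, input = 1e6)),
      input_mean = params$input_mean,
      orphan_fraction = params$orphan_fraction)
    ann <- simulateRepeatAnnotation(cfg)
    cnt <- simulateCountTable(ann, cfg)
    writeBedAnnotation(ann, file.path(outdir, "annotation.bed"))
    writeCountsTsv(cnt, file.path(outdir, "counts.tsv"))

    stage <- "enrich"
    fe <- runEnrichmentPipeline(ann, cnt)
    writeTsv(as.data.frame(rawMedian(fe)), file.path(outdir, "raw_median.tsv"),
             row_names = TRUE)
    writeTsv(as.data.frame(zscores(fe)), file.path(outdir, "zscore.tsv"),
             row_names = TRUE)
    writeTsv(as.data.frame(nLociUsed(fe)), file.path(outdir, "n_loci_used.tsv"),
             row_names = TRUE)
    if (!is.null(fe@clustering$families)) {
      writeLines(hclustToNewick(fe@clustering$families),
                 file.path(outdir, "family_dendrogram.nwk"))
    }

    stage <- "ltr"
    anchors <- dedupLtrs(ann)
    cov1 <- coverageFromCounts(ann, cnt, "chip1", params$genome_length)
    pm <- buildProfileMatrix(cov1, anchors, params$window_up,
                             params$window_down, params$bin_size)
    writeTsv(averageProfile(pm), file.path(outdir, "average_profile.tsv"))
    writeTsv(data.frame(profileAnchors(pm),
                        round(profileValues(pm), 6), check.names = FALSE),
             file.path(outdir, "profile_matrix.tsv"))
    cc <- countTable(cnt)
    ltr_ids <- mcols(annotationRanges(ann))$locus_id[
      mcols(annotationRanges(ann))$role %in% c("LTR5", "LTR3", "orphanLTR")]
    a <- cc[cc$dataset == "chip1" & cc$locus_id %in% ltr_ids, ]
    b <- cc[cc$dataset == "chip2" & cc$locus_id %in% ltr_ids, ]
    fam_of <- stats::setNames(mcols(annotationRanges(ann))$family,
                              mcols(annotationRanges(ann))$locus_id)
    dt <- ltrDifferentialTest(a$chip_count, b$chip_count,
                              list(fam_of[a$locus_id], fam_of[b$locus_id]))
    writeTsv(dt, file.path(outdir, "ltr_differential.tsv"))

    stage <- "bins"
    cov2 <- coverageFromCounts(ann, cnt, "chip2", params$genome_length)
    bc <- binCorrelation(cov1, cov2, params$bin_width)
    writeTsv(bc$bins, file.path(outdir, "bins.tsv"))
    writeTsv(data.frame(rho = bc$rho, p = bc$p, n = bc$n, method = bc$method),
             file.path(outdir, "bin_correlation.tsv"))
    TRUE
  }, error = function(e) {
    dir.create(file.path(outdir, "failed"), showWarnings = FALSE)
    writeLines(c(stage, conditionMessage(e)),
               file.path(outdir, "failed", "stage.txt"))
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })

  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))))
  writeTsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

# Serialize an hclust tree as newick text (labels only, merge heights as
# branch lengths).
hclustToNewick <- function(hc) {
  n <- length(hc$labels)
  build <- function(i, parent_h) {
    if (i < 0) {
      lab <- hc$labels[-i]
      sprintf("%s:%.6g", lab, parent_h)
    } else {
      l <- build(hc$merge[i, 1L], hc$height[i])
      r <- build(hc$merge[i, 2L], hc$height[i])
      sprintf("(%s,%s):%.6g", l, r, max(parent_h - hc$height[i], 0))
    }
  }
  paste0(sub(":[^:]*$", "", build(nrow(hc$merge), max(hc$height))), ";")
}
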