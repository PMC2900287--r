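# Readers and writers.  Internal coordinates are 1-based site positions;
# all emitted interval files (BED, bedGraph) are 0-based half-open.

#' Read a site table and sample matrix from tab-delimited files
#'
#' The site table has columns \code{chrom, pos, snp_id, alleleA, alleleB,
#' genic}; the sample matrix has \code{chrom, pos} followed by three columns
#' per individual named \code{geno.<id>}, \code{E.<id>}, \code{R.<id>}.
#' Rows are matched on (chrom, pos), sorted, and all
#' \linkS4class{AIData} invariants are enforced (duplicate positions and R
#' values at non-het sites are hard errors).
#'
#' @param sitePath,matrixPath paths to the two TSV files.
#' @return an \linkS4class{AIData} object.
#' @seealso [writeDataset()]
#' @export
readDataset <- function(sitePath, matrixPath) {
  sites <- read.table(sitePath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  mat <- read.table(matrixPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "snp_id", "alleleA", "alleleB", "genic")
  if (!all(need %in% names(sites)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  key <- paste(sites$chrom, sites$pos)
  mkey <- paste(mat$chrom, mat$pos)
  if (!setequal(key, mkey) || length(key) != length(mkey))
    stop("site table and sample matrix cover different sites")
  mat <- mat[match(key, mkey), , drop = FALSE]
  ids <- sub("^geno\\.", "", grep("^geno\\.", names(mat), value = TRUE))
  if (!length(ids)) stop("no geno.<id> columns found in sample matrix")
  getm <- function(prefix, mode) {
    cols <- paste0(prefix, ".", ids)
    if (!all(cols %in% names(mat)))
      stop("missing columns: ", paste(setdiff(cols, names(mat)), collapse = ", "))
    m <- as.matrix(mat[, cols, drop = FALSE])
    storage.mode(m) <- mode
    colnames(m) <- ids
    m
  }
  AIData(sites, getm("geno", "character"), getm("E", "double"),
         getm("R", "double"), individuals = ids)
}

#' Write an AIData object as a site table and sample matrix
#'
#' Inverse of [readDataset()]; values survive a round trip to within
#' printed-decimal precision.
#'
#' @param x an \linkS4class{AIData} object.
#' @param sitePath,matrixPath output paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(x, sitePath, matrixPath) {
  rr <- rowRanges(x)
  sites <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      snp_id = mcols(rr)$snp_id,
                      alleleA = mcols(rr)$alleleA,
                      alleleB = mcols(rr)$alleleB,
                      genic = mcols(rr)$genic)
  write.table(sites, sitePath, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    check.names = FALSE)
  fmt <- function(v) vapply(v, format, "", digits = 17)
  for (id in individuals(x)) {
    out[[paste0("geno.", id)]] <- genoCalls(x)[, id]
    out[[paste0("E.", id)]] <- fmt(exprValues(x)[, id])
    out[[paste0("R.", id)]] <- fmt(ratioValues(x)[, id])
  }
  write.table(out, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sitePath, matrixPath))
}

#' Write per-individual score tracks as bedGraph files
#'
#' One bedGraph file per individual, named \code{<prefix><id>.bedGraph},
#' with a track header line and one line per scored site
#' (\code{chrom start end score}, 0-based half-open, so a site at 1-based
#' position p spans \code{[p-1, p)}).  Missing scores are omitted.
#'
#' @param track numeric matrix of per-site per-individual scores (NA where
#'   undefined), as returned by the \code{score*} functions.
#' @param sites the matching site \code{GRanges} (or an
#'   \linkS4class{AIData}, whose sites are used).
#' @param prefix output path prefix.
#' @param method method tag written into the track name.
#' @return invisibly, the vector of paths written.
#' @export
writeScores <- function(track, sites, prefix, method = "aiscan") {
  if (is(sites, "AIData")) sites <- rowRanges(sites)
  stopifnot(length(sites) == nrow(track))
  ids <- colnames(track)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(track)))
  paths <- character(0)
  for (j in seq_along(ids)) {
    path <- paste0(prefix, ids[j], ".bedGraph")
    con <- file(path, "w")
    writeLines(sprintf("track type=bedGraph name=\"%s_%s\"", method,
                       ids[j]), con)
    keep <- !is.na(track[, j])
    if (any(keep)) {
      writeLines(paste(as.character(seqnames(sites))[keep],
                       start(sites)[keep] - 1L, start(sites)[keep],
                       vapply(track[keep, j], format, "", digits = 17)),
                 con)
    }
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a bedGraph score file
#'
#' @param path a bedGraph file as written by [writeScores()].
#' @return a \code{GRanges} with a \code{score} column (1-based positions).
#' @export
readScores <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  if (!length(lines))
    return(GRanges(score = numeric(0)))
  tab <- read.table(text = lines,
                    col.names = c("chrom", "start", "end", "score"))
  GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end), score = tab$score)
}

#' Write called regions as BED6(+1)
#'
#' Columns: chrom, 0-based start, end, individual, mean score, strand
#' (region sign), plus \code{nSnps} as a seventh column.  Overlapping
#' regions for one individual are an error.
#'
#' @param regions a \code{GRanges} as returned by [callRegions()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRegions <- function(regions, path) {
  for (id in unique(mcols(regions)$individual)) {
    rr <- regions[mcols(regions)$individual == id]
    if (length(rr) > 1L && !isDisjoint(rr))
      stop("overlapping regions for individual ", id)
  }
  con <- file(path, "w")
  if (length(regions)) {
    writeLines(paste(as.character(seqnames(regions)), start(regions) - 1L,
                     end(regions), mcols(regions)$individual,
                     format(mcols(regions)$meanScore, digits = 17,
                            trim = TRUE),
                     as.character(strand(regions)),
                     mcols(regions)$nSnps, sep = "\t"), con)
  }
  close(con)
  invisible(path)
}

#' Read regions written by [writeRegions()]
#'
#' @param path a BED6+1 file.
#' @return a \code{GRanges} with \code{individual}, \code{sign},
#'   \code{meanScore} and \code{nSnps} metadata columns.
#' @export
readRegions <- function(path) {
  if (file.size(path) == 0)
    return(GRanges(individual = character(0), sign = integer(0),
                   meanScore = numeric(0), nSnps = integer(0)))
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand", "nSnps"))
  GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end), strand = tab$strand,
          individual = tab$name,
          sign = ifelse(tab$strand == "+", 1L, -1L),
          meanScore = tab$score, nSnps = as.integer(tab$nSnps))
}

#' Read a BED file of intervals (duplication masks, gene annotation)
#'
#' Thin wrapper over \code{rtracklayer::import}; the 0-based half-open BED
#' coordinates are converted to the 1-based convention used internally.
#'
#' @param path a BED3/BED6/BED12 file.
#' @return a \code{GRanges}.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
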