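#' Construct an AIData object
#'
#' Bundles site metadata and per-individual genotype / expression / allelic
#' log-ratio matrices into an \linkS4class{AIData} container.  Sites are
#' sorted by (chromosome, position); all invariants (unique positions, R
#' only at heterozygous sites, finite E at non-missing genotypes) are
#' enforced and violated ones raise an error naming the offending site.
#'
#' @param sites a \code{GRanges} of width-1 site positions with metadata
#'   columns \code{snp_id}, \code{alleleA}, \code{alleleB}, \code{genic},
#'   or a data.frame with columns \code{chrom}, \code{pos} plus the same
#'   metadata.
#' @param geno character matrix (sites x individuals) of \code{"het"},
#'   \code{"hom"}, \code{"missing"} calls.
#' @param E,R numeric matrices of total expression and allelic log-ratio,
#'   same shape as \code{geno}; \code{R} must be \code{NA} off het sites.
#' @param individuals optional individual ids (defaults to the column names
#'   of \code{geno}).
#' @return an \linkS4class{AIData} object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500), width = 1),
#'   snp_id = c("rs1", "rs2"), alleleA = "A", alleleB = "G", genic = TRUE)
#' geno <- matrix(c("het", "hom"), 2, 1, dimnames = list(NULL, "NA1"))
#' E <- matrix(c(1.2, -0.5), 2, 1)
#' R <- matrix(c(0.8, NA), 2, 1)
#' AIData(gr, geno, E, R)
#' @export
AIData <- function(sites, geno, E, R, individuals = colnames(geno)) {
  if (is.data.frame(sites)) {
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                     snp_id = as.character(sites$snp_id),
                     alleleA = as.character(sites$alleleA),
                     alleleB = as.character(sites$alleleB),
                     genic = as.logical(sites$genic))
  }
  geno <- as.matrix(geno); E <- as.matrix(E); R <- as.matrix(R)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(ncol(geno)))
  stopifnot(length(sites) == nrow(geno),
            all(dim(geno) == dim(E)), all(dim(geno) == dim(R)))
  key <- paste(seqnames(sites), start(sites))
  if (anyDuplicated(key))
    stop("duplicate site positions: ", key[duplicated(key)][1])
  ord <- order(as.factor(seqnames(sites)), start(sites))
  sites <- sites[ord]
  geno <- geno[ord, , drop = FALSE]
  E <- E[ord, , drop = FALSE]
  R <- R[ord, , drop = FALSE]
  dimnames(geno) <- dimnames(E) <- dimnames(R) <-
    list(NULL, as.character(individuals))
  obj <- new("AIData", SummarizedExperiment(
    assays = list(geno = geno, E = E, R = R), rowRanges = sites))
  validObject(obj)
  obj
}

#' Accessors for AIData
#'
#' \code{siteInfo} returns the site-level \code{GRanges};
#' \code{genoCalls}, \code{exprValues} and \code{ratioValues} return the
#' genotype, E and R matrices; \code{isHet} the logical heterozygosity
#' matrix; \code{individuals} the sample ids.
#'
#' @param x an \linkS4class{AIData} object.
#' @return see above.
#' @name AIData-accessors
#' @aliases siteInfo genoCalls exprValues ratioValues isHet individuals
NULL

#' @rdname AIData-accessors
#' @export
siteInfo <- function(x) rowRanges(x)

#' @rdname AIData-accessors
#' @export
genoCalls <- function(x) assay(x, "geno")

#' @rdname AIData-accessors
#' @export
exprValues <- function(x) assay(x, "E")

#' @rdname AIData-accessors
#' @export
ratioValues <- function(x) assay(x, "R")

#' @rdname AIData-accessors
#' @export
isHet <- function(x) assay(x, "geno") == "het"

#' @rdname AIData-accessors
#' @export
individuals <- function(x) colnames(x)

## split site indices by chromosome, preserving order
chromIndex <- function(x) {
  split(seq_len(nrow(x)), as.factor(seqnames(rowRanges(x))), drop = TRUE)
}

#' Mean inter-SNP gap
#'
#' Average distance in base pairs between consecutive sites, pooled over
#' chromosomes.  This is the constant \code{D} used to define the unit
#' (per-bp) transition matrix of the HMMs.
#' @param x an \linkS4class{AIData} object.
#' @return a single number (bp).
#' @export
meanGap <- function(x) {
  gaps <- unlist(lapply(chromIndex(x), function(i)
    siteGaps(start(rowRanges(x))[i])), use.names = FALSE)
  if (!length(gaps)) stop("need at least two sites on one chromosome")
  mean(gaps)
}
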