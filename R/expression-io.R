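#' @import SummarizedExperiment
#' @import S4Vectors
NULL

#' FPKM expression matrix with genotype/time/replicate annotation
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{fpkm} assay of
#' non-negative locus x sample values. Samples are annotated with
#' \code{genotype} (\code{"ancestor"} or \code{"derived"}), \code{time}
#' (hours post transfer; the reference design samples 18, 22 and 24 h) and
#' \code{replicate}. Every replicate index must cover the complete
#' genotype x time crossing and locus ids must be unique.
#'
#' @export
setClass("FPKMExperiment", contains = "SummarizedExperiment")

setValidity("FPKMExperiment", function(object) {
  if (!"fpkm" %in% assayNames(object))
    return("an assay named 'fpkm' is required")
  cd <- colData(object)
  need <- c("genotype", "time", "replicate")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (!all(cd$genotype %in% c("ancestor", "derived")))
    return("genotype must be 'ancestor' or 'derived'")
  if (anyDuplicated(rownames(object)))
    return("locus ids must be unique")
  a <- assay(object, "fpkm")
  if (any(a < 0))
    return(sprintf("negative FPKM value at locus '%s'",
                   rownames(object)[which(rowSums(a < 0) > 0)[1]]))
  cells <- expand.grid(genotype = unique(cd$genotype),
                       time = unique(cd$time))
  for (r in unique(cd$replicate)) {
    sub <- cd[cd$replicate == r, ]
    have <- paste(sub$genotype, sub$time)
    want <- paste(cells$genotype, cells$time)
    if (!setequal(have, want) || anyDuplicated(have))
      return(sprintf(
        "replicate %s does not cover the genotype x time crossing exactly once",
        r))
  }
  if (length(unique(cd$genotype)) != 2L)
    return("both genotypes must be present")
  TRUE
})

#' Construct an FPKMExperiment from a matrix and sample annotation
#'
#' @param fpkm numeric matrix, loci in rows (rownames = locus ids), samples
#'   in columns.
#' @param genotype,time,replicate per-sample annotation vectors.
#' @return A validated \linkS4class{FPKMExperiment}.
#' @export
fpkmExperiment <- function(fpkm, genotype, time, replicate) {
  cd <- DataFrame(genotype = as.character(genotype),
                  time = as.numeric(time),
                  replicate = as.integer(replicate))
  rownames(cd) <- sprintf("%s_%gh_r%d", cd$genotype, cd$time, cd$replicate)
  colnames(fpkm) <- rownames(cd)
  new("FPKMExperiment",
      SummarizedExperiment(assays = list(fpkm = fpkm), colData = cd))
}

.parseSampleNames <- function(nms) {
  m <- regmatches(nms, regexec("^(ancestor|derived)_([0-9.]+)h_r([0-9]+)$",
                               nms))
  bad <- nms[vapply(m, length, 0L) != 4L]
  if (length(bad))
    stop("malformed sample column header(s): ", paste(bad, collapse = ", "),
         " (expected <genotype>_<time>h_r<rep>, e.g. ancestor_18h_r1)")
  data.frame(genotype = vapply(m, `[`, "", 2L),
             time = as.numeric(vapply(m, `[`, "", 3L)),
             replicate = as.integer(vapply(m, `[`, "", 4L)))
}

#' Read an FPKM expression table
#'
#' Tab-separated file with a \code{locus_id} column followed by sample
#' columns named \code{<genotype>_<time>h_r<rep>} (e.g.
#' \code{ancestor_18h_r1}) holding decimal FPKM values. Duplicate locus
#' rows, negative values and malformed headers each raise a distinct
#' validation error.
#'
#' @param path TSV file path.
#' @return A validated \linkS4class{FPKMExperiment}.
#' @export
loadExpression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "locus_id")
    stop("first column must be 'locus_id', found '", names(d)[1], "'")
  if (anyDuplicated(d$locus_id))
    stop("duplicate locus id(s): ",
         paste(unique(d$locus_id[duplicated(d$locus_id)]), collapse = ", "))
  ann <- .parseSampleNames(names(d)[-1])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric FPKM values in ", path)
  rownames(m) <- d$locus_id
  neg <- which(rowSums(m < 0) > 0)
  if (length(neg))
    stop(sprintf("negative FPKM at locus '%s' (row %d)",
                 d$locus_id[neg[1]], neg[1]))
  fpkmExperiment(m, ann$genotype, ann$time, ann$replicate)
}

#' Write an FPKM expression table
#'
#' Inverse of [loadExpression()]; the written file round-trips through
#' [loadExpression()] bit-identically for finite decimal values.
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "FPKMExperiment"))
  d <- data.frame(locus_id = rownames(x), assay(x, "fpkm"),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus-to-GO-term map
#'
#' Two-column tab-separated file (\code{locus_id}, \code{go_term}), one row
#' per membership; loci may appear under several terms.
#'
#' @param path TSV file path.
#' @return A validated \linkS4class{GOMap}.
#' @export
loadGOMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus_id", "go_term") %in% names(d)))
    stop("GO map must have columns 'locus_id' and 'go_term'")
  goMap(d)
}

#' Write a locus-to-GO-term map
#' @param x a \linkS4class{GOMap}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGOMap <- function(x, path) {
  stopifnot(is(x, "GOMap"))
  utils::write.table(x@map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
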