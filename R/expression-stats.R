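# Transcriptome statistics downstream of FPKM: fold-change locus filter,
# log-share normalization, GO-grouped global cell-mean ANOVA, per-term
# directional/temporal tests, and deviation profiles.

#' Per-locus normalized expression shares
#'
#' A \linkS4class{SummarizedExperiment} with one \code{share} assay of
#' locus x (genotype, time) cells. For each locus the replicate-averaged
#' FPKM is transformed as log(x + 1) and divided by the sum of the
#' transformed values across all genotype x time cells, so the shares of a
#' locus sum to 1 (all-zero loci get zero shares and are flagged in
#' \code{rowData(x)$all_zero}). The natural log is used here; base-2 logs
#' are reserved for fold changes.
#'
#' @export
setClass("NormalizedShares", contains = "SummarizedExperiment")

setValidity("NormalizedShares", function(object) {
  if (!"share" %in% assayNames(object))
    return("an assay named 'share' is required")
  if (!all(c("genotype", "time") %in% names(colData(object))))
    return("colData must carry genotype and time")
  if (!"all_zero" %in% names(rowData(object)))
    return("rowData must carry the all_zero flag")
  s <- assay(object, "share")
  if (any(s < 0)) return("shares must be non-negative")
  sums <- rowSums(s)
  ok <- ifelse(rowData(object)$all_zero, abs(sums) < 1e-9,
               abs(sums - 1) < 1e-9)
  if (!all(ok))
    return(sprintf("shares of locus '%s' do not sum to 1",
                   rownames(object)[which(!ok)[1]]))
  TRUE
})

## replicate-mean FPKM per genotype x time cell; columns ordered by
## (genotype, time), cell names "<genotype>_<time>h"
.cellMeans <- function(x) {
  cd <- colData(x)
  key <- paste0(cd$genotype, "_", cd$time, "h")
  cells <- unique(data.frame(genotype = cd$genotype, time = cd$time,
                             key = key))
  cells <- cells[order(cells$genotype, cells$time), ]
  a <- assay(x, "fpkm")
  m <- vapply(cells$key, function(k)
    rowMeans(a[, key == k, drop = FALSE]), numeric(nrow(a)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(rownames(a), cells$key))
  list(means = m, cells = cells)
}

#' Loci passing the two-fold between-genotype filter
#'
#' A locus is retained when the absolute base-2 log fold change between the
#' derived and ancestral replicate-mean FPKM exceeds the threshold at one
#' or more timepoints. A pseudocount guards against zero FPKM; the default
#' of 0.1 FPKM is configurable.
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @param thresholdLog2 |log2 fold change| cutoff (default 1, i.e.
#'   two-fold).
#' @param pseudocount FPKM added to both genotypes before the ratio.
#' @return Character vector of locus ids.
#' @export
foldChangeLoci <- function(x, thresholdLog2 = 1, pseudocount = 0.1) {
  stopifnot(is(x, "FPKMExperiment"))
  cm <- .cellMeans(x)
  times <- unique(cm$cells$time)
  hit <- rep(FALSE, nrow(x))
  for (t in times) {
    a <- cm$means[, cm$cells$key[cm$cells$genotype == "ancestor" &
                                 cm$cells$time == t]]
    d <- cm$means[, cm$cells$key[cm$cells$genotype == "derived" &
                                 cm$cells$time == t]]
    hit <- hit | abs(log2((d + pseudocount) / (a + pseudocount))) >
      thresholdLog2
  }
  rownames(x)[hit]
}

#' Normalize FPKM to per-locus log shares
#'
#' Averages replicates within each genotype x time cell, applies the
#' log(x + 1) transform (natural log), and divides by the per-locus sum
#' over all cells, so each locus's shares sum to 1 and changes are read as
#' relative, not absolute, expression. Loci with zero FPKM everywhere get
#' zero shares and are flagged.
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @return A \linkS4class{NormalizedShares} object with one column per
#'   genotype x time cell.
#' @export
normalizeExpression <- function(x) {
  stopifnot(is(x, "FPKMExperiment"))
  cm <- .cellMeans(x)
  v <- log(cm$means + 1)
  tot <- rowSums(v)
  allZero <- tot == 0
  share <- v / ifelse(tot == 0, 1, tot)
  share[allZero, ] <- 0
  cd <- DataFrame(genotype = cm$cells$genotype, time = cm$cells$time,
                  row.names = cm$cells$key)
  se <- SummarizedExperiment(assays = list(share = share), colData = cd,
                             rowData = DataFrame(all_zero = allZero))
  new("NormalizedShares", se)
}

.termLoci <- function(norm, gomap) {
  m <- gomap@map[gomap@map$locus_id %in% rownames(norm), ]
  split(m$locus_id, factor(m$go_term, levels = gomap@terms))
}

#' Global GO-grouped cell-mean ANOVA
#'
#' Collapses the normalized shares to a G x 2 x 3 cell-mean table (mean
#' share over the member loci of each GO term, per genotype x time cell;
#' loci mapped to several terms contribute to each) and fits the
#' fixed-effects model \code{share ~ GO + genotype + time + GO:genotype +
#' GO:time} on the 6G cells. The residual therefore pools the
#' genotype:time and GO:genotype:time strata, giving model df 4G - 1 and
#' residual df 2G; on the reference 28-term design these are the familiar
#' 111 and 56. The F statistic and adjusted R-squared are data-dependent.
#'
#' @param norm a \linkS4class{NormalizedShares}.
#' @param gomap a \linkS4class{GOMap}; terms with no loci present in
#'   \code{norm} are dropped with a warning.
#' @return A \linkS4class{GlobalAnovaFit}.
#' @export
globalFit <- function(norm, gomap) {
  stopifnot(is(norm, "NormalizedShares"), is(gomap, "GOMap"))
  byTerm <- .termLoci(norm, gomap)
  empty <- names(byTerm)[lengths(byTerm) == 0]
  if (length(empty)) {
    warning("dropping GO term(s) with no mapped loci: ",
            paste(empty, collapse = ", "))
    byTerm <- byTerm[lengths(byTerm) > 0]
  }
  G <- length(byTerm)
  if (G < 2) stop("at least two GO terms with mapped loci are required")
  s <- assay(norm, "share")
  cd <- colData(norm)
  cellMeans <- t(vapply(byTerm, function(loci)
    colMeans(s[loci, , drop = FALSE]), numeric(ncol(s))))
  long <- data.frame(
    term = factor(rep(rownames(cellMeans), times = ncol(s))),
    genotype = factor(rep(as.character(cd$genotype),
                          each = nrow(cellMeans))),
    time = factor(rep(cd$time, each = nrow(cellMeans))),
    share = as.vector(cellMeans))
  fit <- lm(share ~ term + genotype + time + term:genotype + term:time,
            data = long)
  # a flat cell-mean table fits perfectly; the F-test warning is expected
  an <- withCallingHandlers(anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  ssModel <- sum(an$`Sum Sq`[-nrow(an)])
  dfModel <- sum(an$Df[-nrow(an)])
  ssRes <- an$`Sum Sq`[nrow(an)]
  dfRes <- an$Df[nrow(an)]
  ssTot <- ssModel + ssRes
  n <- nrow(long)
  if (ssTot <= 1e-24) {              # constant response: define F = 0
    fStat <- 0; adjR2 <- 0
  } else if (ssModel <= 1e-24) {
    fStat <- 0
    adjR2 <- 1 - (ssRes / dfRes) / (ssTot / (n - 1))
  } else {
    fStat <- (ssModel / dfModel) / (ssRes / dfRes)
    adjR2 <- 1 - (ssRes / dfRes) / (ssTot / (n - 1))
  }
  new("GlobalAnovaFit", dfModel = as.integer(dfModel),
      dfResidual = as.integer(dfRes), fStatistic = fStat,
      adjRsquared = adjR2, nTerms = as.integer(G))
}

#' Per-GO-term directional and temporal statistics
#'
#' For each GO term, runs a locus-level two-way ANOVA of the normalized
#' shares with genotype and time as fixed factors and the member loci as
#' the error stratum (a within-locus, repeated-measures layout). Because
#' every locus's shares sum to one across its genotype x time cells, cells
#' of the same locus are negatively correlated and a naive fixed-effects
#' residual would be anticonservative; testing each effect against its
#' locus-interaction stratum keeps the type-I rate at its nominal level.
#' Concretely, with d_l(t) the derived-minus-ancestor share difference of
#' locus l at time t: the genotype main effect is the paired t-test of the
#' per-locus means of d_l across loci (equivalently the F against the
#' locus:genotype stratum, df 1 and m-1), and the genotype:time
#' interaction is the repeated-measures F for a time effect on d_l (df
#' T-1 and (T-1)(m-1)). The signed effect estimate is the mean
#' derived-minus-ancestor share; the temporal slope sign comes from
#' regressing the per-time mean difference on time. P-values are adjusted
#' across terms (Benjamini-Hochberg by default); terms with fewer than two
#' member loci are reported untested (NA statistics).
#'
#' @param norm a \linkS4class{NormalizedShares}.
#' @param gomap a \linkS4class{GOMap}.
#' @param alpha significance level on the adjusted scale (default 0.05).
#' @param correction a \code{\link[stats]{p.adjust}} method (default
#'   \code{"BH"}).
#' @return A \code{DataFrame} with one row per term: \code{term},
#'   \code{n_loci}, \code{effect}, \code{p}, \code{q}, \code{direction},
#'   \code{interaction_p}, \code{interaction_q}, \code{directional},
#'   \code{temporal}, \code{slope_sign}.
#' @export
goGroupTests <- function(norm, gomap, alpha = 0.05, correction = "BH") {
  stopifnot(is(norm, "NormalizedShares"), is(gomap, "GOMap"))
  byTerm <- .termLoci(norm, gomap)
  terms <- names(byTerm)
  n <- length(terms)
  out <- data.frame(term = terms, n_loci = lengths(byTerm),
                    effect = NA_real_, p = NA_real_, q = NA_real_,
                    direction = NA_integer_, interaction_p = NA_real_,
                    interaction_q = NA_real_, directional = NA,
                    temporal = NA, slope_sign = NA_integer_,
                    row.names = NULL)
  s <- assay(norm, "share")
  cd <- colData(norm)
  times <- sort(unique(cd$time))
  nT <- length(times)
  derCols <- vapply(times, function(t)
    which(cd$genotype == "derived" & cd$time == t), 0L)
  ancCols <- vapply(times, function(t)
    which(cd$genotype == "ancestor" & cd$time == t), 0L)
  for (i in seq_len(n)) {
    loci <- byTerm[[i]]
    m <- length(loci)
    if (m < 2) next
    # per-locus derived-minus-ancestor differences, loci x times
    d <- s[loci, derCols, drop = FALSE] - s[loci, ancCols, drop = FALSE]
    g <- rowMeans(d)                        # per-locus genotype contrast
    out$effect[i] <- mean(g)
    out$direction[i] <- sign(out$effect[i])
    vg <- stats::var(g)
    out$p[i] <- if (vg > 0)
      2 * stats::pt(-abs(mean(g) / sqrt(vg / m)), df = m - 1)
    else NaN
    # time effect on d: repeated-measures F against locus:genotype:time
    cellDev <- d - g                        # d_l(t) - per-locus mean
    colDev <- colMeans(cellDev)
    ssTime <- m * sum(colDev^2)
    ssErr <- sum(sweep(cellDev, 2, colDev)^2)
    dfTime <- nT - 1L
    dfErr <- (nT - 1L) * (m - 1L)
    out$interaction_p[i] <- if (ssErr > 0)
      stats::pf((ssTime / dfTime) / (ssErr / dfErr), dfTime, dfErr,
                lower.tail = FALSE)
    else NaN
    slope <- coef(lm(colMeans(d) ~ times))[2]
    out$slope_sign[i] <- sign(slope)
  }
  tested <- !is.na(out$p)
  out$q[tested] <- p.adjust(out$p[tested], method = correction)
  out$interaction_q[tested] <- p.adjust(out$interaction_p[tested],
                                        method = correction)
  out$directional <- out$q < alpha
  out$temporal <- out$interaction_q < alpha
  DataFrame(out)
}

#' Directional (genotype main-effect) tests per GO term
#'
#' Convenience view of [goGroupTests()]: terms flagged \code{directional}
#' show a consistent derived-versus-ancestor shift in mean normalized
#' expression, with \code{direction} +1 for higher expression in the
#' derived genotype and -1 for lower.
#'
#' @inheritParams goGroupTests
#' @return The [goGroupTests()] \code{DataFrame}.
#' @export
directionalTests <- function(norm, gomap, alpha = 0.05, correction = "BH") {
  goGroupTests(norm, gomap, alpha = alpha, correction = correction)
}

#' Temporal (genotype-by-time interaction) tests per GO term
#'
#' Convenience view of [goGroupTests()]: terms flagged \code{temporal} show
#' between-genotype divergence that changes across the sampled timepoints;
#' \code{slope_sign} is +1 when the derived-minus-ancestor difference grows
#' from the earliest to the latest time and -1 when it declines.
#'
#' @inheritParams goGroupTests
#' @return The [goGroupTests()] \code{DataFrame}.
#' @export
temporalTests <- function(norm, gomap, alpha = 0.05, correction = "BH") {
  goGroupTests(norm, gomap, alpha = alpha, correction = correction)
}

#' Deviations from average expression per GO term
#'
#' For each term, subtracts the grand mean share (over all member-locus
#' cells) from each genotype x time cell mean, yielding the deviation
#' profile of relative expression across the time course. Per term, the
#' deviations sum to zero across the genotype x time cells.
#'
#' @param norm a \linkS4class{NormalizedShares}.
#' @param gomap a \linkS4class{GOMap}.
#' @return Long-format data.frame: \code{term}, \code{genotype},
#'   \code{time}, \code{deviation}.
#' @export
deviationProfile <- function(norm, gomap) {
  stopifnot(is(norm, "NormalizedShares"), is(gomap, "GOMap"))
  byTerm <- .termLoci(norm, gomap)
  byTerm <- byTerm[lengths(byTerm) > 0]
  s <- assay(norm, "share")
  cd <- colData(norm)
  res <- lapply(names(byTerm), function(term) {
    m <- s[byTerm[[term]], , drop = FALSE]
    cellMean <- colMeans(m)
    data.frame(term = term, genotype = as.character(cd$genotype),
               time = cd$time, deviation = cellMean - mean(cellMean),
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Write per-term statistics, global fit and deviation profile
#'
#' @param stats the [goGroupTests()] \code{DataFrame}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGroupStats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroupStats
#' @param fit a \linkS4class{GlobalAnovaFit}.
#' @export
writeGlobalFit <- function(fit, path) {
  stopifnot(is(fit, "GlobalAnovaFit"))
  jsonlite::write_json(list(df_model = fit@dfModel,
                            df_resid = fit@dfResidual,
                            F = fit@fStatistic,
                            adj_r2 = fit@adjRsquared),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroupStats
#' @param profile the [deviationProfile()] data.frame.
#' @export
writeDeviationProfile <- function(profile, path) {
  utils::write.table(profile, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
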