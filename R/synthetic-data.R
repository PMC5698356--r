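# Synthetic-data generators: GO universes, FPKM matrices with planted
# genotype-direction and genotype-by-time effects, and simulator scenario
# fixtures. Every input the pipeline consumes can be produced here with a
# machine-readable record of the planted truth.

#' Planted ground truth for a synthetic expression matrix
#'
#' @slot directionalEffects named numeric: signed derived-minus-ancestor
#'   share shift per planted GO term (share units).
#' @slot temporalSlopes named numeric: per-hour divergence slope of the
#'   derived-minus-ancestor share difference per planted term.
#' @slot foldChangeMultipliers named numeric: FPKM multipliers applied to
#'   the derived genotype of individual loci (for the fold-change filter).
#' @slot noiseSd replicate noise sd on the share scale.
#' @slot baselineMeanlog,baselineSdlog log-normal baseline FPKM parameters.
#' @export
setClass("PlantedTruth",
  representation(directionalEffects = "numeric", temporalSlopes = "numeric",
                 foldChangeMultipliers = "numeric", noiseSd = "numeric",
                 baselineMeanlog = "numeric", baselineSdlog = "numeric"),
  prototype(directionalEffects = setNames(numeric(0), character(0)),
            temporalSlopes = setNames(numeric(0), character(0)),
            foldChangeMultipliers = setNames(numeric(0), character(0)),
            noiseSd = 0.005, baselineMeanlog = 2, baselineSdlog = 1.5))

setValidity("PlantedTruth", function(object) {
  if (!all(is.finite(object@directionalEffects)) ||
      !all(is.finite(object@temporalSlopes)))
    return("planted effects must be finite")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@baselineSdlog < 0) return("baselineSdlog must be >= 0")
  TRUE
})

#' Construct a PlantedTruth
#' @param directionalEffects,temporalSlopes,foldChangeMultipliers,noiseSd,baselineMeanlog,baselineSdlog
#'   see [PlantedTruth-class].
#' @return A validated \linkS4class{PlantedTruth}.
#' @export
plantedTruth <- function(directionalEffects = setNames(numeric(0), character(0)),
                         temporalSlopes = setNames(numeric(0), character(0)),
                         foldChangeMultipliers = setNames(numeric(0), character(0)),
                         noiseSd = 0.005, baselineMeanlog = 2,
                         baselineSdlog = 1.5) {
  new("PlantedTruth", directionalEffects = directionalEffects,
      temporalSlopes = temporalSlopes,
      foldChangeMultipliers = foldChangeMultipliers,
      noiseSd = noiseSd, baselineMeanlog = baselineMeanlog,
      baselineSdlog = baselineSdlog)
}

setMethod("show", "PlantedTruth", function(object) {
  cat(sprintf(
    "PlantedTruth: %d directional, %d temporal term(s), %d fold-change loci, noise sd %g\n",
    length(object@directionalEffects), length(object@temporalSlopes),
    length(object@foldChangeMultipliers), object@noiseSd))
})

#' Generate a synthetic GO universe
#'
#' Assigns \code{lociPerTerm} fresh loci to each of \code{nTerms} GO terms;
#' each locus then gains one extra membership in a uniformly chosen other
#' term with probability \code{multiMembershipProb}, mirroring the
#' multi-term assignments a GO slim mapper produces.
#'
#' @param nTerms number of terms (>= 2); the reference design groups loci
#'   into 28 GO slim process terms.
#' @param lociPerTerm primary loci per term.
#' @param multiMembershipProb probability of one extra membership per locus.
#' @param seed optional integer seed for reproducibility.
#' @return A \linkS4class{GOMap}.
#' @examples
#' makeGOUniverse(28, 25, seed = 1)   # 700 memberships over 28 terms
#' @export
makeGOUniverse <- function(nTerms = 28, lociPerTerm = 25,
                           multiMembershipProb = 0, seed = NULL) {
  if (nTerms < 2) stop("'nTerms' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  terms <- sprintf("GO%02d", seq_len(nTerms))
  loci <- sprintf("L%05d", seq_len(nTerms * lociPerTerm))
  map <- data.frame(locus_id = loci,
                    go_term = rep(terms, each = lociPerTerm))
  if (multiMembershipProb > 0) {
    extra <- runif(length(loci)) < multiMembershipProb
    if (any(extra)) {
      home <- map$go_term[match(loci[extra], map$locus_id)]
      other <- vapply(home, function(h)
        sample(setdiff(terms, h), 1L), "")
      map <- rbind(map, data.frame(locus_id = loci[extra],
                                   go_term = other))
    }
  }
  goMap(map, terms = terms)
}

#' Default planted truth mirroring the reference study's structure
#'
#' Plants directional effects in 12 of the universe's terms (8 with higher
#' expression in the derived genotype, 4 lower, 0.02 share units each) and
#' temporal divergence in 6 further terms (4 increasing, 2 declining,
#' 0.005 share units per hour), with replicate noise of 0.005 share units
#' and a right-skewed log-normal FPKM baseline. Fifty unmapped background
#' loci carry a 4-fold derived shift for the fold-change filter.
#'
#' @param gomap the \linkS4class{GOMap} the effects refer to.
#' @return A \linkS4class{PlantedTruth}.
#' @export
defaultPlantedTruth <- function(gomap) {
  terms <- goTerms(gomap)
  nDir <- min(12L, length(terms))
  dir <- setNames(rep(c(0.02, -0.02), times = c(ceiling(nDir * 2 / 3),
                                                nDir - ceiling(nDir * 2 / 3))),
                  terms[seq_len(nDir)])
  rest <- terms[-seq_len(nDir)]
  nTmp <- min(6L, length(rest))
  tmp <- setNames(rep(c(0.005, -0.005), times = c(ceiling(nTmp * 2 / 3),
                                                  nTmp - ceiling(nTmp * 2 / 3))),
                  rest[seq_len(nTmp)])
  fc <- setNames(rep(4, 50), sprintf("B%05d", seq_len(50)))
  plantedTruth(directionalEffects = dir, temporalSlopes = tmp,
               foldChangeMultipliers = fc)
}

#' Simulate an FPKM expression matrix with planted structure
#'
#' Emulates the reference design: two genotypes (ancestor, derived), three
#' timepoints (18, 22, 24 h), \code{nReps} replicates, the mapped loci of
#' \code{gomap} plus \code{nBackgroundLoci} unmapped loci (about 10^4 loci
#' in total under the defaults).
#'
#' Each locus draws a log-normal baseline FPKM \code{x0}; writing
#' \code{v0 = log(x0 + 1)}, a planted share shift of \code{delta} for the
#' derived genotype is realized by adding \code{6 * v0 * delta} to the
#' derived cells on the \code{v} scale (a first-order calibration: under
#' the six-cell share normalization this moves the derived-minus-ancestor
#' share by approximately \code{delta}). Temporal slopes contribute
#' \code{slope * (t - mean(t))} in the same units; replicate noise is
#' multiplicative log-normal on \code{x + 1} with sd \code{6 * v0 *
#' noiseSd} on the log scale, i.e. about \code{noiseSd} on the share
#' scale. Fold-change loci have the derived FPKM multiplied directly.
#'
#' @param gomap a \linkS4class{GOMap}; loci in several planted terms sum
#'   their effects.
#' @param truth a \linkS4class{PlantedTruth}.
#' @param nReps replicates per genotype x time cell (default 2, matching a
#'   duplicated sequencing design).
#' @param nBackgroundLoci unmapped loci appended to the matrix (default
#'   9300; fold-change multipliers refer to these ids).
#' @param times sampling times in hours.
#' @param seed optional integer seed.
#' @return list(expression = \linkS4class{FPKMExperiment},
#'   truth = the \linkS4class{PlantedTruth} used).
#' @export
simulateExpression <- function(gomap, truth = defaultPlantedTruth(gomap),
                               nReps = 2, nBackgroundLoci = 9300,
                               times = c(18, 22, 24), seed = NULL) {
  stopifnot(is(gomap, "GOMap"), is(truth, "PlantedTruth"))
  validObject(truth)
  if (!is.null(seed)) set.seed(seed)
  mapped <- unique(gomap@map$locus_id)
  bg <- if (nBackgroundLoci > 0) sprintf("B%05d", seq_len(nBackgroundLoci))
        else character(0)
  loci <- c(mapped, bg)
  nL <- length(loci)
  x0 <- rlnorm(nL, truth@baselineMeanlog, truth@baselineSdlog)
  names(x0) <- loci
  v0 <- log(x0 + 1)

  ## per-locus planted share shift: directional + temporal components
  dirShift <- setNames(rep(0, nL), loci)
  slope <- setNames(rep(0, nL), loci)
  if (length(truth@directionalEffects)) {
    m <- gomap@map[gomap@map$go_term %in% names(truth@directionalEffects), ]
    if (nrow(m)) {
      add <- tapply(truth@directionalEffects[m$go_term], m$locus_id, sum)
      dirShift[names(add)] <- dirShift[names(add)] + as.numeric(add)
    }
  }
  if (length(truth@temporalSlopes)) {
    m <- gomap@map[gomap@map$go_term %in% names(truth@temporalSlopes), ]
    if (nrow(m)) {
      add <- tapply(truth@temporalSlopes[m$go_term], m$locus_id, sum)
      slope[names(add)] <- slope[names(add)] + as.numeric(add)
    }
  }
  fcMult <- setNames(rep(1, nL), loci)
  known <- intersect(names(truth@foldChangeMultipliers), loci)
  fcMult[known] <- truth@foldChangeMultipliers[known]

  cells <- expand.grid(replicate = seq_len(nReps), time = times,
                       genotype = c("ancestor", "derived"),
                       stringsAsFactors = FALSE)
  tbar <- mean(times)
  nCells <- 2L * length(times)          # genotype x time cells per locus
  mat <- matrix(0, nL, nrow(cells), dimnames = list(loci, NULL))
  for (j in seq_len(nrow(cells))) {
    g <- cells$genotype[j]; t <- cells$time[j]
    x <- x0
    if (g == "derived") x <- x * fcMult
    v <- log(x + 1)
    if (g == "derived") {
      delta <- dirShift + slope * (t - tbar)
      v <- v + nCells * v0 * delta
    }
    if (truth@noiseSd > 0)
      v <- v + rnorm(nL, 0, nCells * v0 * truth@noiseSd)
    mat[, j] <- pmax(exp(v) - 1, 0)
  }
  se <- fpkmExperiment(mat, cells$genotype, cells$time, cells$replicate)
  list(expression = se, truth = truth)
}

#' Write a planted-truth record as JSON
#'
#' The record is sufficient to score every detection stage exactly
#' (confusion matrices for the fold-change filter and the per-term tests).
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "PlantedTruth"))
  jsonlite::write_json(list(
    directional_effects = as.list(truth@directionalEffects),
    temporal_slopes = as.list(truth@temporalSlopes),
    fold_change_multipliers = as.list(truth@foldChangeMultipliers),
    noise_sd = truth@noiseSd,
    baseline_meanlog = truth@baselineMeanlog,
    baseline_sdlog = truth@baselineSdlog), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Named simulator scenario fixtures
#'
#' Three qualitative parameter sets for the serial-transfer simulator, all
#' synthetic stand-ins shaped after the contrasts a serial-selection
#' experiment produces:
#' \describe{
#'   \item{ancestor-like}{submerged growth with conidiation suppressed past
#'     the cycle end (t_c = T): zero conidia within a 24 h cycle, few
#'     transferable propagules.}
#'   \item{derived-like}{early onset and fast production: the conidia
#'     plateau within one cycle is orders of magnitude above ancestor-like
#'     (>= 10^6 conidia-equivalents per culture-mL scale at 24 h).}
#'   \item{near-extinction}{per-capita transferable yield below one through
#'     the 1:100 bottleneck, so [runSerial()] drives the population extinct
#'     within a few daily transfers.}
#' }
#'
#' @param name one of \code{"ancestor-like"}, \code{"derived-like"},
#'   \code{"near-extinction"}.
#' @return list(lifeHistory, regime, initialCount, expected) where
#'   \code{expected} is a one-line qualitative outcome description.
#' @export
makeScenarioFixture <- function(name = c("ancestor-like", "derived-like",
                                         "near-extinction")) {
  name <- match.arg(name)
  switch(name,
    "ancestor-like" = list(
      lifeHistory = lifeHistory(r_h = 0.45, r_c = 1.5, f = 0.02, T = 24,
                                t_c = 24, P0 = 1e4),
      regime = transferRegime(carryingCapacity = 1e8, nTransfers = 10L),
      initialCount = 1e4,
      expected = "no conidia within the 24 h cycle"),
    "derived-like" = list(
      lifeHistory = lifeHistory(r_h = 0.45, r_c = 1.5, f = 0.05, T = 24,
                                t_c = 18, P0 = 1e4),
      regime = transferRegime(carryingCapacity = 1e8, nTransfers = 10L),
      initialCount = 1e4,
      expected = paste("conidia plateau >= 1e6 per culture-mL scale at 24 h,",
                       "onset earlier than ancestor-like")),
    "near-extinction" = list(
      lifeHistory = lifeHistory(r_h = 0.3, r_c = 0.01, f = 0.001, T = 24,
                                t_c = 23.5, P0 = 1e4),
      regime = transferRegime(carryingCapacity = 1e9, nTransfers = 10L),
      initialCount = 1e4,
      expected = "extinction within 5 daily transfers"))
}

#' Write a scenario fixture as a YAML config
#'
#' Emits the dialect [readScenario()] consumes.
#'
#' @param fixture a [makeScenarioFixture()] list.
#' @param path output YAML path.
#' @param mutation optional \linkS4class{MutationModel} block to embed.
#' @return \code{path}, invisibly.
#' @export
writeScenario <- function(fixture, path, mutation = NULL) {
  lh <- fixture$lifeHistory
  rg <- fixture$regime
  cfg <- list(
    regime = list(culture_volume = rg@cultureVolume,
                  transfer_volume = rg@transferVolume,
                  period = rg@period,
                  carrying_capacity = rg@carryingCapacity,
                  n_transfers = rg@nTransfers),
    genotypes = list(list(r_h = lh@r_h, r_c = lh@r_c, f = lh@f,
                          t_c = lh@t_c, count = fixture$initialCount)))
  if (!is.null(mutation))
    cfg$mutation <- list(rate = mutation@rate, onset_sd = mutation@onsetSd,
                         frag_sd = mutation@fragSd)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
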