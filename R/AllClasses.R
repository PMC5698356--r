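#' @import methods
#' @importFrom stats rnorm rpois rbinom rlnorm runif anova lm coef p.adjust
#'   plogis qlogis setNames
#' @importFrom utils read.delim write.table
NULL

.check_scalar <- function(x, field, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    return(sprintf("'%s' must be a single finite number", field))
  if (x < lower || x > upper)
    return(sprintf("'%s' = %g is outside [%g, %g]", field, x, lower, upper))
  NULL
}

#' Life-history parameter vector for one growth-and-transfer cycle
#'
#' Holds the parameters of the propagule-production model: hyphae founded by
#' \code{P0} propagules grow exponentially at rate \code{r_h} until the
#' conidiation onset time \code{t_c}, after which conidia are produced
#' linearly at rate \code{r_c} per hyphal unit until the transfer at time
#' \code{T}. A fraction \code{f} of the hyphae fragments into transferable
#' suspended particles.
#'
#' @slot r_h hyphal specific growth rate (per hour, >= 0).
#' @slot r_c conidia production rate (conidia per hyphal unit per hour, >= 0).
#' @slot f hyphal fragmentation fraction, in [0, 1].
#' @slot T transfer interval (hours, > 0); defaults to the daily 24 h regime.
#' @slot t_c conidiation onset time (hours, in [0, T]).
#' @slot P0 founding propagule count (a real-valued expectation, >= 0).
#'
#' @seealso [census()], [optimalOnset()]
#' @export
setClass("LifeHistory",
  representation(r_h = "numeric", r_c = "numeric", f = "numeric",
                 T = "numeric", t_c = "numeric", P0 = "numeric"),
  prototype(r_h = 0.3, r_c = 1, f = 0, T = 24, t_c = 18, P0 = 1))

setValidity("LifeHistory", function(object) {
  msgs <- c(
    .check_scalar(object@r_h, "r_h", lower = 0),
    .check_scalar(object@r_c, "r_c", lower = 0),
    .check_scalar(object@f,   "f",   lower = 0, upper = 1),
    .check_scalar(object@T,   "T"),
    .check_scalar(object@P0,  "P0",  lower = 0))
  if (is.null(msgs) && object@T <= 0)
    msgs <- sprintf("'T' = %g must be > 0", object@T)
  if (is.null(msgs))
    msgs <- .check_scalar(object@t_c, "t_c", lower = 0, upper = object@T)
  if (is.null(msgs)) TRUE else msgs
})

#' Construct a LifeHistory parameter set
#'
#' @param r_h,r_c,f,T,t_c,P0 see the slot documentation in
#'   [LifeHistory-class].
#' @return A validated \linkS4class{LifeHistory} object.
#' @examples
#' lifeHistory(r_h = 0.5, r_c = 1, f = 0, t_c = 22)
#' @export
lifeHistory <- function(r_h = 0.3, r_c = 1, f = 0, T = 24, t_c = 18, P0 = 1) {
  new("LifeHistory", r_h = r_h, r_c = r_c, f = f, T = T, t_c = t_c, P0 = P0)
}

setMethod("show", "LifeHistory", function(object) {
  cat(sprintf(
    "LifeHistory: r_h=%g/h, r_c=%g/h, f=%g, T=%g h, t_c=%g h, P0=%g\n",
    object@r_h, object@r_c, object@f, object@T, object@t_c, object@P0))
})

#' End-of-cycle propagule census
#'
#' The model's outputs for one growth cycle: total hyphal biomass,
#' its suspended (fragmented) part, conidia, and the total transferable
#' propagule count. Totals are real-valued expectations; integerization
#' happens only at the sampling step of the serial-transfer simulator.
#'
#' @slot hyphalTotal total hyphal units at transfer.
#' @slot fragments suspended hyphal particles, \code{f * hyphalTotal}.
#' @slot conidia conidia produced between onset and transfer.
#' @slot total transferable propagules, \code{fragments + conidia}.
#' @export
setClass("PropaguleCensus",
  representation(hyphalTotal = "numeric", fragments = "numeric",
                 conidia = "numeric", total = "numeric"))

setValidity("PropaguleCensus", function(object) {
  if (any(c(object@hyphalTotal, object@fragments, object@conidia,
            object@total) < 0))
    return("census fields must be non-negative")
  if (object@fragments > object@hyphalTotal * (1 + 1e-12))
    return("fragments cannot exceed total hyphae")
  if (abs(object@total - (object@fragments + object@conidia)) >
      1e-9 * max(1, object@total))
    return("total must equal fragments + conidia")
  TRUE
})

setMethod("show", "PropaguleCensus", function(object) {
  cat(sprintf(
    "PropaguleCensus: hyphae=%.4g (fragments=%.4g), conidia=%.4g, total=%.4g\n",
    object@hyphalTotal, object@fragments, object@conidia, object@total))
})

#' Serial-transfer regime
#'
#' Bookkeeping for a daily serial-dilution experiment: a fixed aliquot of
#' \code{transferVolume} mL out of \code{cultureVolume} mL is passaged every
#' \code{period} hours, giving a dilution factor
#' \code{D = cultureVolume / transferVolume}. The default 0.1 mL of 10 mL
#' gives D = 100. \code{carryingCapacity} caps the summed hyphal biomass a
#' culture can produce within one cycle.
#'
#' @slot cultureVolume culture volume in mL (> 0).
#' @slot transferVolume transferred aliquot in mL (> 0, <= cultureVolume).
#' @slot period hours between transfers (the cycle length T).
#' @slot carryingCapacity maximum summed hyphal units per culture (> 0).
#' @slot nTransfers number of transfers to simulate.
#' @export
setClass("TransferRegime",
  representation(cultureVolume = "numeric", transferVolume = "numeric",
                 period = "numeric", carryingCapacity = "numeric",
                 nTransfers = "integer"),
  prototype(cultureVolume = 10, transferVolume = 0.1, period = 24,
            carryingCapacity = 1e9, nTransfers = 85L))

setValidity("TransferRegime", function(object) {
  msgs <- c(
    .check_scalar(object@cultureVolume, "cultureVolume"),
    .check_scalar(object@transferVolume, "transferVolume"),
    .check_scalar(object@period, "period"),
    .check_scalar(object@carryingCapacity, "carryingCapacity"))
  if (!is.null(msgs)) return(msgs)
  if (object@cultureVolume <= 0 || object@transferVolume <= 0)
    return("volumes must be positive")
  if (object@transferVolume > object@cultureVolume)
    return("transferVolume cannot exceed cultureVolume")
  if (object@cultureVolume / object@transferVolume <= 1)
    return("dilution factor D must exceed 1")
  if (object@period <= 0) return("period must be positive")
  if (object@carryingCapacity <= 0)
    return("carryingCapacity must be positive")
  if (object@nTransfers < 0L) return("nTransfers must be >= 0")
  TRUE
})

#' Construct a TransferRegime
#'
#' @param cultureVolume,transferVolume,period,carryingCapacity,nTransfers see
#'   [TransferRegime-class].
#' @return A validated \linkS4class{TransferRegime}.
#' @examples
#' transferRegime()            # the daily 1:100 regime
#' @export
transferRegime <- function(cultureVolume = 10, transferVolume = 0.1,
                           period = 24, carryingCapacity = 1e9,
                           nTransfers = 85L) {
  new("TransferRegime", cultureVolume = cultureVolume,
      transferVolume = transferVolume, period = period,
      carryingCapacity = carryingCapacity,
      nTransfers = as.integer(nTransfers))
}

#' @describeIn TransferRegime-class dilution factor D.
#' @param regime a \linkS4class{TransferRegime}.
#' @export
dilutionFactor <- function(regime) {
  stopifnot(is(regime, "TransferRegime"))
  regime@cultureVolume / regime@transferVolume
}

setMethod("show", "TransferRegime", function(object) {
  cat(sprintf(
    "TransferRegime: %g mL of %g mL every %g h (D = %g), K = %.3g, %d transfers\n",
    object@transferVolume, object@cultureVolume, object@period,
    dilutionFactor(object), object@carryingCapacity, object@nTransfers))
})

#' Mutation model for the evolutionary simulator
#'
#' Mutation is supplied per transferred propagule: each propagule that
#' survives the dilution bottleneck founds a new genotype with probability
#' \code{rate}. A mutant's onset time t_c takes a Gaussian step (sd
#' \code{onsetSd} hours) reflected back into [0, T]; its fragmentation
#' fraction f takes a Gaussian step of sd \code{fragSd} on the log-odds
#' scale, which keeps f inside (0, 1).
#'
#' @slot rate mutation probability per transferred propagule, in [0, 1].
#' @slot onsetSd step sd for t_c in hours (0 disables t_c mutation).
#' @slot fragSd step sd for f on the log-odds scale (0 disables f mutation).
#' @export
setClass("MutationModel",
  representation(rate = "numeric", onsetSd = "numeric", fragSd = "numeric"),
  prototype(rate = 0.01, onsetSd = 1, fragSd = 0))

setValidity("MutationModel", function(object) {
  msgs <- c(.check_scalar(object@rate, "rate", 0, 1),
            .check_scalar(object@onsetSd, "onsetSd", 0),
            .check_scalar(object@fragSd, "fragSd", 0))
  if (is.null(msgs)) TRUE else msgs
})

#' Construct a MutationModel
#' @param rate,onsetSd,fragSd see [MutationModel-class].
#' @return A validated \linkS4class{MutationModel}.
#' @export
mutationModel <- function(rate = 0.01, onsetSd = 1, fragSd = 0) {
  new("MutationModel", rate = rate, onsetSd = onsetSd, fragSd = fragSd)
}

#' Population state of the serial-transfer simulator
#'
#' Integer propagule counts per genotype, with each genotype carrying its own
#' life-history traits. The population is extinct exactly when the total
#' count is zero.
#'
#' @slot genotypes data.frame with columns id, parent_id, birth_transfer,
#'   r_h, r_c, f, t_c.
#' @slot counts non-negative integer-valued counts, one per genotype row.
#' @slot transferIndex index of the last completed transfer.
#' @export
setClass("PopulationState",
  representation(genotypes = "data.frame", counts = "numeric",
                 transferIndex = "integer"))

setValidity("PopulationState", function(object) {
  g <- object@genotypes
  need <- c("id", "parent_id", "birth_transfer", "r_h", "r_c", "f", "t_c")
  if (!all(need %in% names(g)))
    return(paste("genotypes must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) != length(object@counts))
    return("one count per genotype row required")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (any(g$f < 0 | g$f > 1)) return("'f' must lie in [0, 1]")
  if (any(g$t_c < 0)) return("'t_c' must be >= 0")
  TRUE
})

#' Construct a single- or multi-genotype PopulationState
#'
#' @param traits a \linkS4class{LifeHistory} (one genotype) or a data.frame
#'   with columns r_h, r_c, f, t_c (one row per genotype).
#' @param counts initial propagule count(s).
#' @return A \linkS4class{PopulationState} at transfer index 0.
#' @examples
#' populationState(lifeHistory(t_c = 20, f = 0.5), counts = 1e4)
#' @export
populationState <- function(traits, counts) {
  if (is(traits, "LifeHistory")) {
    traits <- data.frame(r_h = traits@r_h, r_c = traits@r_c,
                         f = traits@f, t_c = traits@t_c)
  }
  n <- nrow(traits)
  g <- data.frame(id = seq_len(n), parent_id = NA_integer_,
                  birth_transfer = 0L,
                  r_h = traits$r_h, r_c = traits$r_c,
                  f = traits$f, t_c = traits$t_c)
  new("PopulationState", genotypes = g, counts = round(rep_len(counts, n)),
      transferIndex = 0L)
}

#' @describeIn PopulationState-class TRUE when no propagules remain.
#' @param state a \linkS4class{PopulationState}.
#' @export
isExtinct <- function(state) sum(state@counts) == 0

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState: %d genotype(s), %g propagules, transfer %d%s\n",
              nrow(object@genotypes), sum(object@counts),
              object@transferIndex,
              if (isExtinct(object)) " [extinct]" else ""))
})

#' Serial-transfer trajectory
#'
#' Per-transfer records of a [runSerial()] or [runEvolution()] run: the total
#' transferred count, count-weighted trait means, the expected conidia share
#' of the pre-transfer census, and the extinction flag. Trait means are NA
#' once the population is extinct.
#'
#' @slot records data.frame with columns transfer, total_transferred,
#'   mean_t_c, mean_f, conidia_fraction, extinct.
#' @slot extinctionTransfer index of the first transfer with zero propagules,
#'   or NA if the population persisted.
#' @slot finalState the \linkS4class{PopulationState} after the last transfer.
#' @export
setClass("Trajectory",
  representation(records = "data.frame", extinctionTransfer = "integer",
                 finalState = "PopulationState"))

setValidity("Trajectory", function(object) {
  need <- c("transfer", "total_transferred", "mean_t_c", "mean_f",
            "conidia_fraction", "extinct")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' @describeIn Trajectory-class extinction transfer index (NA if persistent).
#' @param x a \linkS4class{Trajectory}.
#' @export
extinctionTransfer <- function(x) x@extinctionTransfer

#' @describeIn Trajectory-class the per-transfer record table.
#' @export
trajectoryRecords <- function(x) x@records

setMethod("show", "Trajectory", function(object) {
  n <- nrow(object@records)
  cat(sprintf("Trajectory: %d transfer(s) recorded; %s\n", n,
              if (is.na(object@extinctionTransfer)) "population persisted"
              else sprintf("extinct at transfer %d",
                           object@extinctionTransfer)))
})

#' Global GO-grouped ANOVA fit
#'
#' Summary of the fixed-effects linear model
#' \code{share ~ GO + genotype + time + GO:genotype + GO:time} fitted to the
#' G x 2 x 3 cell-mean table of normalized expression shares. For G GO terms
#' the model has 4G - 1 model degrees of freedom and 2G residual degrees of
#' freedom (the residual pools genotype:time and GO:genotype:time).
#'
#' @slot dfModel model degrees of freedom (4G - 1).
#' @slot dfResidual residual degrees of freedom (2G).
#' @slot fStatistic overall model F statistic.
#' @slot adjRsquared adjusted R-squared.
#' @slot nTerms number of GO terms fitted.
#' @export
setClass("GlobalAnovaFit",
  representation(dfModel = "integer", dfResidual = "integer",
                 fStatistic = "numeric", adjRsquared = "numeric",
                 nTerms = "integer"))

setValidity("GlobalAnovaFit", function(object) {
  if (object@adjRsquared > 1) return("adjusted R-squared cannot exceed 1")
  if (object@dfModel != 4L * object@nTerms - 1L)
    return("model df must equal 4G - 1")
  if (object@dfResidual != 2L * object@nTerms)
    return("residual df must equal 2G")
  TRUE
})

setMethod("show", "GlobalAnovaFit", function(object) {
  cat(sprintf(
    "GlobalAnovaFit: %d GO terms; F(%d, %d) = %.4g, adj. R^2 = %.4g\n",
    object@nTerms, object@dfModel, object@dfResidual,
    object@fStatistic, object@adjRsquared))
})

#' @describeIn GlobalAnovaFit-class model degrees of freedom.
#' @param x a \linkS4class{GlobalAnovaFit}.
#' @export
modelDf <- function(x) x@dfModel

#' @describeIn GlobalAnovaFit-class residual degrees of freedom.
#' @export
residualDf <- function(x) x@dfResidual

#' @describeIn GlobalAnovaFit-class overall F statistic.
#' @export
fStatistic <- function(x) x@fStatistic

#' @describeIn GlobalAnovaFit-class adjusted R-squared.
#' @export
adjRsquared <- function(x) x@adjRsquared

#' Locus-to-GO-term membership map
#'
#' Maps locus ids to GO slim process terms. Loci may belong to several
#' terms and unmapped loci are permitted (expression tables routinely carry
#' many loci without a GO assignment).
#'
#' @slot map data.frame with columns locus_id and go_term, one row per
#'   membership.
#' @slot terms the term universe (includes terms with zero mapped loci).
#' @export
setClass("GOMap",
  representation(map = "data.frame", terms = "character"))

setValidity("GOMap", function(object) {
  if (!all(c("locus_id", "go_term") %in% names(object@map)))
    return("map must have columns locus_id and go_term")
  if (anyDuplicated(object@map[, c("locus_id", "go_term")]))
    return("duplicate locus/term memberships")
  if (!all(object@map$go_term %in% object@terms))
    return("map references terms outside the term universe")
  TRUE
})

#' Construct a GOMap
#' @param map data.frame with columns locus_id, go_term.
#' @param terms optional term universe; defaults to the terms present.
#' @return A validated \linkS4class{GOMap}.
#' @export
goMap <- function(map, terms = NULL) {
  map$locus_id <- as.character(map$locus_id)
  map$go_term <- as.character(map$go_term)
  if (is.null(terms)) terms <- sort(unique(map$go_term))
  new("GOMap", map = map[, c("locus_id", "go_term")], terms = terms)
}

#' @describeIn GOMap-class the term universe.
#' @param x a \linkS4class{GOMap}.
#' @export
goTerms <- function(x) x@terms

#' @describeIn GOMap-class the membership table.
#' @export
goMemberships <- function(x) x@map

setMethod("show", "GOMap", function(object) {
  cat(sprintf("GOMap: %d memberships, %d loci, %d terms\n",
              nrow(object@map), length(unique(object@map$locus_id)),
              length(object@terms)))
})
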