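# Stochastic serial-dilution simulator: repeated growth cycles, 1/D
# volumetric bottlenecks, extinction detection and generation accounting,
# plus an evolutionary mode with mutable life-history traits.

#' One growth cycle for a multi-genotype population
#'
#' Applies the propagule model per genotype with P0 equal to its count. The
#' summed hyphal biomass is capped at the regime's carrying capacity; when
#' the cap binds, every genotype's hyphal total is rescaled by the same
#' factor so that per-genotype shares stay proportional to their uncapped
#' values, and fragments and conidia are computed from the capped biomass.
#'
#' @param state a \linkS4class{PopulationState}.
#' @param regime a \linkS4class{TransferRegime}.
#' @return data.frame with one row per genotype: hyphal_total, fragments,
#'   conidia, total (real-valued expectations).
#' @export
growCycle <- function(state, regime) {
  stopifnot(is(state, "PopulationState"), is(regime, "TransferRegime"))
  g <- state@genotypes
  Tt <- regime@period
  H <- state@counts * exp(g$r_h * pmin(g$t_c, Tt))
  sumH <- sum(H)
  if (sumH > regime@carryingCapacity)
    H <- H * (regime@carryingCapacity / sumH)
  frag <- g$f * H
  conidia <- g$r_c * H * pmax(Tt - g$t_c, 0)
  data.frame(id = g$id, hyphal_total = H, fragments = frag,
             conidia = conidia, total = frag + conidia)
}

#' Sample the transferred aliquot
#'
#' Models the 1/D volumetric subsample of a well-mixed culture: each
#' genotype's transferred count is Poisson with mean \code{total / D}
#' (propagules dilute independently). In deterministic mode the rounded
#' expectation is returned instead (round-half-even, the R default).
#'
#' @param totals per-genotype expected transferable totals (>= 0).
#' @param regime a \linkS4class{TransferRegime}.
#' @param stochastic draw Poisson counts (TRUE) or round expectations.
#' @return Integer-valued counts, one per genotype.
#' @export
sampleTransfer <- function(totals, regime, stochastic = TRUE) {
  stopifnot(all(totals >= 0))
  mu <- totals / dilutionFactor(regime)
  if (stochastic) rpois(length(mu), mu) else round(mu)
}

.emptyRecords <- function() {
  data.frame(transfer = integer(), total_transferred = numeric(),
             mean_t_c = numeric(), mean_f = numeric(),
             conidia_fraction = numeric(), extinct = logical())
}

.recordTransfer <- function(i, counts, g, cen) {
  tot <- sum(counts)
  extinct <- tot == 0
  totalCensus <- sum(cen$total)
  data.frame(
    transfer = i, total_transferred = tot,
    mean_t_c = if (extinct) NA_real_ else sum(counts * g$t_c) / tot,
    mean_f = if (extinct) NA_real_ else sum(counts * g$f) / tot,
    conidia_fraction = if (totalCensus > 0) sum(cen$conidia) / totalCensus
                       else NA_real_,
    extinct = extinct)
}

#' Run a serial-transfer experiment without mutation
#'
#' Iterates [growCycle()] and [sampleTransfer()] for \code{nTransfers}
#' cycles or until extinction (total transferred count of zero). Extinct
#' populations stay extinct; the first all-zero transfer is recorded as the
#' extinction transfer.
#'
#' @param state initial \linkS4class{PopulationState}.
#' @param regime a \linkS4class{TransferRegime}.
#' @param stochastic Poisson bottleneck sampling (TRUE) or rounded
#'   expectations.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' st <- populationState(lifeHistory(r_h = 0.2, r_c = 0.01, f = 0, t_c = 20),
#'                       counts = 1000)
#' runSerial(st, transferRegime(nTransfers = 10), stochastic = FALSE)
#' @export
runSerial <- function(state, regime, stochastic = TRUE) {
  stopifnot(is(state, "PopulationState"), is(regime, "TransferRegime"))
  validObject(state); validObject(regime)
  recs <- vector("list", regime@nTransfers)
  extinctionAt <- NA_integer_
  counts <- state@counts
  g <- state@genotypes
  i <- 0L
  while (i < regime@nTransfers) {
    i <- i + 1L
    cur <- new("PopulationState", genotypes = g, counts = counts,
               transferIndex = i - 1L)
    cen <- growCycle(cur, regime)
    counts <- sampleTransfer(cen$total, regime, stochastic = stochastic)
    recs[[i]] <- .recordTransfer(i, counts, g, cen)
    if (sum(counts) == 0) { extinctionAt <- i; break }
    keep <- counts > 0                      # drop empty lineages
    g <- g[keep, , drop = FALSE]
    counts <- counts[keep]
  }
  final <- new("PopulationState", genotypes = g, counts = counts,
               transferIndex = i)
  new("Trajectory", records = do.call(rbind, recs[seq_len(i)]),
      extinctionTransfer = extinctionAt, finalState = final)
}

## reflect a vector into [lo, hi] (Gaussian steps folded at the boundaries)
.reflect <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + pmin(y, 2 * width - y)
}

#' Mutate a genotype's life-history traits
#'
#' Perturbs the onset time by a Gaussian step reflected into [0, T] and the
#' fragmentation fraction by a Gaussian step on the log-odds scale (f is
#' clamped to [1e-6, 1 - 1e-6] before the log-odds transform so boundary
#' values remain mutable). The mutant gets a fresh id and records its
#' parent; growth and production rates are fixed within a scenario.
#'
#' @param genotype one-row data.frame with columns r_h, r_c, f, t_c.
#' @param model a \linkS4class{MutationModel}.
#' @param T transfer interval bounding t_c.
#' @param newId id to assign, parentId parent id, birth transfer index.
#' @param newId,parentId,birth bookkeeping for the mutant row.
#' @return A one-row genotypes data.frame for the mutant.
#' @export
mutateGenotype <- function(genotype, model, T = 24, newId = NA_integer_,
                           parentId = NA_integer_, birth = NA_integer_) {
  stopifnot(is(model, "MutationModel"))
  t_c <- genotype$t_c
  f <- genotype$f
  if (model@onsetSd > 0)
    t_c <- .reflect(t_c + rnorm(length(t_c), 0, model@onsetSd), 0, T)
  if (model@fragSd > 0) {
    lo <- qlogis(pmin(pmax(f, 1e-6), 1 - 1e-6))
    f <- plogis(lo + rnorm(length(f), 0, model@fragSd))
  }
  data.frame(id = newId, parent_id = parentId, birth_transfer = birth,
             r_h = genotype$r_h, r_c = genotype$r_c, f = f, t_c = t_c)
}

#' Run a serial-transfer experiment with mutation and selection
#'
#' As [runSerial()], but after each bottleneck every transferred propagule
#' founds a new mutant genotype with probability \code{model@rate}
#' ([mutateGenotype()] steps). Selection is emergent: genotypes differ only
#' in their per-cycle propagule yield, so lineages with onset times closer
#' to the [optimalOnset()] value displace the rest.
#'
#' @param state initial \linkS4class{PopulationState}.
#' @param regime a \linkS4class{TransferRegime}.
#' @param model a \linkS4class{MutationModel}.
#' @param stochastic Poisson bottleneck sampling (TRUE); deterministic mode
#'   still mutates stochastically and is intended for debugging only.
#' @return A \linkS4class{Trajectory} whose records carry the per-transfer
#'   count-weighted trait means.
#' @export
runEvolution <- function(state, regime, model, stochastic = TRUE) {
  stopifnot(is(state, "PopulationState"), is(regime, "TransferRegime"),
            is(model, "MutationModel"))
  validObject(state); validObject(regime); validObject(model)
  counts <- state@counts
  g <- state@genotypes
  nextId <- max(g$id) + 1L
  recs <- vector("list", regime@nTransfers)
  extinctionAt <- NA_integer_
  i <- 0L
  while (i < regime@nTransfers) {
    i <- i + 1L
    cur <- new("PopulationState", genotypes = g, counts = counts,
               transferIndex = i - 1L)
    cen <- growCycle(cur, regime)
    counts <- sampleTransfer(cen$total, regime, stochastic = stochastic)
    if (model@rate > 0 && sum(counts) > 0) {
      nMut <- rbinom(length(counts), counts, model@rate)
      m <- sum(nMut)
      if (m > 0) {
        parents <- rep.int(seq_along(counts), nMut)
        counts <- counts - nMut
        mut <- mutateGenotype(g[parents, , drop = FALSE], model,
                              T = regime@period,
                              newId = seq.int(nextId, length.out = m),
                              parentId = g$id[parents], birth = i)
        nextId <- nextId + m
        g <- rbind(g, mut)
        counts <- c(counts, rep.int(1L, m))
      }
    }
    recs[[i]] <- .recordTransfer(i, counts, g, cen)
    if (sum(counts) == 0) { extinctionAt <- i; break }
    keep <- counts > 0
    g <- g[keep, , drop = FALSE]
    counts <- counts[keep]
  }
  final <- new("PopulationState", genotypes = g, counts = counts,
               transferIndex = i)
  new("Trajectory", records = do.call(rbind, recs[seq_len(i)]),
      extinctionTransfer = extinctionAt, finalState = final)
}

#' Generations elapsed within one transfer bout
#'
#' Regrowing from the 1/D bottleneck back to the pre-dilution population
#' size takes log2(D) doublings, so a dilution factor of 100 corresponds to
#' about 6.64 generations per daily bout.
#'
#' @param dilution dilution factor D (>= 1).
#' @return log2(D).
#' @examples
#' generationsPerBout(100)   # 6.643856
#' @export
generationsPerBout <- function(dilution) {
  if (any(dilution < 1)) stop("'dilution' must be >= 1")
  log2(dilution)
}

#' Total generations over a serial-transfer experiment
#'
#' Multiplies the per-bout generation count by the number of transfers,
#' under an explicitly named rounding rule. \code{"exact"} applies no
#' rounding; \code{"one-decimal-floor"} floors the per-bout value to one
#' decimal before multiplying (85 transfers at D = 100 give 85 x 6.6 =
#' 561); \code{"nearest-ten"} rounds the exact product to the nearest ten
#' (45 and 85 transfers at D = 100 give ~300 and ~560).
#'
#' @param nTransfers number of transfers (>= 0).
#' @param dilution dilution factor D.
#' @param rule rounding rule, never applied silently.
#' @return Generations under the chosen rule.
#' @examples
#' totalGenerations(85, 100, "one-decimal-floor")  # 561
#' totalGenerations(45, 100, "nearest-ten")        # 300
#' @export
totalGenerations <- function(nTransfers, dilution,
                             rule = c("exact", "one-decimal-floor",
                                      "nearest-ten")) {
  rule <- match.arg(rule)
  if (nTransfers < 0) stop("'nTransfers' must be >= 0")
  perBout <- generationsPerBout(dilution)
  switch(rule,
    "exact" = nTransfers * perBout,
    "one-decimal-floor" = nTransfers * floor(perBout * 10) / 10,
    "nearest-ten" = round(nTransfers * perBout / 10) * 10)
}

#' Write a trajectory to CSV and its summary to JSON
#'
#' The CSV carries one row per transfer (transfer, total_transferred,
#' mean_t_c, mean_f, conidia_fraction, extinct); the JSON summary records
#' the extinction transfer (null when the population persisted) and the
#' final count-weighted trait means.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param csvPath output CSV path.
#' @param jsonPath optional JSON summary path.
#' @return \code{csvPath}, invisibly.
#' @export
writeTrajectory <- function(trajectory, csvPath, jsonPath = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  r <- trajectory@records
  utils::write.table(r, csvPath, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    last <- r[nrow(r), ]
    jsonlite::write_json(list(
      extinction_transfer = trajectory@extinctionTransfer,
      n_transfers_recorded = nrow(r),
      final_mean_t_c = last$mean_t_c,
      final_mean_f = last$mean_f), jsonPath, auto_unbox = TRUE,
      digits = NA, na = "null")
  }
  invisible(csvPath)
}

#' Read a simulator scenario from a YAML config
#'
#' Expects a \code{regime} block (culture_volume, transfer_volume, period,
#' carrying_capacity, n_transfers), a \code{genotypes} list (r_h, r_c, f,
#' t_c, count per entry) and an optional \code{mutation} block (rate,
#' onset_sd, frag_sd).
#'
#' @param path YAML file path.
#' @return list(state, regime, mutation) where mutation may be NULL.
#' @export
readScenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regime) || is.null(cfg$genotypes))
    stop("scenario config needs 'regime' and 'genotypes' blocks")
  rg <- cfg$regime
  regime <- transferRegime(
    cultureVolume = rg$culture_volume %||% 10,
    transferVolume = rg$transfer_volume %||% 0.1,
    period = rg$period %||% 24,
    carryingCapacity = rg$carrying_capacity %||% 1e9,
    nTransfers = rg$n_transfers %||% 85)
  gl <- cfg$genotypes
  traits <- data.frame(
    r_h = vapply(gl, function(x) x$r_h, 0),
    r_c = vapply(gl, function(x) x$r_c, 0),
    f = vapply(gl, function(x) x$f, 0),
    t_c = vapply(gl, function(x) x$t_c, 0))
  counts <- vapply(gl, function(x) x$count, 0)
  state <- populationState(traits, counts)
  mutation <- NULL
  if (!is.null(cfg$mutation))
    mutation <- mutationModel(rate = cfg$mutation$rate %||% 0,
                              onsetSd = cfg$mutation$onset_sd %||% 0,
                              fragSd = cfg$mutation$frag_sd %||% 0)
  list(state = state, regime = regime, mutation = mutation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
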