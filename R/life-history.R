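# Deterministic propagule-production model of one growth-and-transfer cycle.
#
# Hyphae grow exponentially from P0 founders at rate r_h until the
# conidiation onset t_c, giving H_T = P0 * exp(r_h * t_c) hyphal units at
# transfer; conidia then accumulate linearly, C_T = r_c * H_T * (T - t_c);
# a fraction f of the hyphae fragments into transferable particles, so the
# transferable total is P_T = f * H_T + C_T.

#' Total hyphal biomass at transfer
#'
#' @param p a \linkS4class{LifeHistory}.
#' @return \code{P0 * exp(r_h * t_c)}; equals \code{P0} when \code{r_h = 0}
#'   or \code{t_c = 0}.
#' @examples
#' hyphalTotal(lifeHistory(P0 = 1, r_h = 0.2, t_c = 20))  # exp(4)
#' @export
hyphalTotal <- function(p) {
  stopifnot(is(p, "LifeHistory"))
  validObject(p)
  p@P0 * exp(p@r_h * p@t_c)
}

## transferable total as a function of onset, vectorized over t_c
.totalAtOnset <- function(r_h, r_c, f, T, P0, t_c) {
  P0 * exp(r_h * t_c) * (f + r_c * (T - t_c))
}

#' End-of-cycle census of hyphae, fragments and conidia
#'
#' Evaluates one growth cycle of the propagule model. Conidia are zero
#' whenever \code{t_c = T} (no time to produce them) or \code{r_c = 0}.
#'
#' @param p a \linkS4class{LifeHistory}.
#' @return A \linkS4class{PropaguleCensus}.
#' @examples
#' census(lifeHistory(P0 = 1, r_h = 0, r_c = 2, f = 0, T = 24, t_c = 19))
#' @export
census <- function(p) {
  H <- hyphalTotal(p)
  frag <- p@f * H
  conidia <- p@r_c * H * (p@T - p@t_c)
  new("PropaguleCensus", hyphalTotal = H, fragments = frag,
      conidia = conidia, total = frag + conidia)
}

#' Optimal conidiation onset time
#'
#' Closed-form onset time maximizing the transferable propagule total
#' P_T(t_c) over [0, T]:
#' \deqn{t_c^* = T + f / r_c - 1 / r_h,}
#' clamped to [0, T]. The derivative of P_T with respect to t_c changes
#' sign from positive to negative exactly once (at the unclamped root), so
#' when the root falls outside [0, T] the nearer endpoint is the true
#' argmax: P_T is monotone increasing on the interval when the root exceeds
#' T, and monotone decreasing when the root is negative.
#'
#' Conventions for the degenerate corners: with \code{r_c = 0} and
#' \code{f > 0} fragments are the only propagules and delaying onset always
#' pays, so the optimum is \code{T}; with \code{r_h = 0} hyphal biomass
#' cannot grow, delaying onset only wastes production time, and the optimum
#' is \code{0}; with \code{r_c = 0} and \code{f = 0} there is no propagule
#' route at all (P_T is identically zero) and an error is signalled.
#'
#' @param p a \linkS4class{LifeHistory}; its \code{t_c} slot is ignored.
#' @return Onset time in hours, in [0, T].
#' @examples
#' optimalOnset(lifeHistory(r_h = 0.5, r_c = 1, f = 0, T = 24))  # 22
#' @export
optimalOnset <- function(p) {
  stopifnot(is(p, "LifeHistory"))
  validObject(p)
  if (p@r_c == 0 && p@f == 0)
    stop("no propagule route: r_c = 0 and f = 0 make P_T identically zero")
  if (p@r_h == 0) return(0)                     # no growth: switch at once
  if (p@r_c == 0) return(p@T)                   # fragments only: never switch
  root <- p@T + p@f / p@r_c - 1 / p@r_h
  min(max(root, 0), p@T)
}

#' Brute-force onset optimum on a regular grid
#'
#' Independent oracle for [optimalOnset()]: evaluates the census total on a
#' regular grid over [0, T] and returns the maximizing grid point. Ties are
#' broken toward the earliest onset.
#'
#' @param p a \linkS4class{LifeHistory}; \code{t_c} ignored.
#' @param gridStep grid spacing in hours (> 0).
#' @return The grid point (hours) maximizing the transferable total.
#' @export
optimalOnsetBruteforce <- function(p, gridStep = 1e-3) {
  stopifnot(is(p, "LifeHistory"))
  validObject(p)
  if (gridStep <= 0) stop("'gridStep' must be positive")
  grid <- seq(0, p@T, by = gridStep)
  if (grid[length(grid)] < p@T) grid <- c(grid, p@T)
  tot <- .totalAtOnset(p@r_h, p@r_c, p@f, p@T, p@P0, grid)
  grid[which.max(tot)]   # which.max returns the first (earliest) maximum
}

#' Optimal-onset surface over production rate and fragmentation
#'
#' Evaluates [optimalOnset()] on a rate x fragmentation grid under the
#' equal-rates assumption r_h = r_c = rate, for which the optimum reduces to
#' \code{T + (f - 1) / rate}. Entries are non-decreasing along both axes
#' (strictly increasing in rate for f < 1); the f = 1 column equals T for
#' every rate.
#'
#' @param rates per-hour growth/production rates (> 0).
#' @param fragmentations fragmentation fractions in [0, 1].
#' @param T transfer interval in hours.
#' @return Numeric matrix of onset times, rates in rows (named by rate) and
#'   fragmentation fractions in columns.
#' @examples
#' onsetSurface(c(0.25, 0.5, 1), c(0, 0.5, 1))
#' @export
onsetSurface <- function(rates, fragmentations, T = 24) {
  if (length(rates) == 0 || length(fragmentations) == 0)
    stop("'rates' and 'fragmentations' must be non-empty")
  if (any(rates <= 0)) stop("'rates' must be positive")
  if (any(fragmentations < 0 | fragmentations > 1))
    stop("'fragmentations' must lie in [0, 1]")
  out <- matrix(NA_real_, length(rates), length(fragmentations),
                dimnames = list(rate = as.character(rates),
                                f = as.character(fragmentations)))
  for (i in seq_along(rates))
    for (j in seq_along(fragmentations))
      out[i, j] <- optimalOnset(lifeHistory(
        r_h = rates[i], r_c = rates[i], f = fragmentations[j],
        T = T, t_c = 0))
  out
}

#' Write an onset surface as a CSV matrix
#'
#' First row carries the fragmentation axis, first column the rate axis,
#' cells the onset time in hours with 6 decimal places.
#'
#' @param surface matrix from [onsetSurface()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeOnsetSurface <- function(surface, path) {
  m <- cbind(rownames(surface), formatC(surface, format = "f", digits = 6))
  m <- rbind(c("rate\\f", colnames(surface)), m)
  utils::write.table(m, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read life-history parameters from a YAML config
#'
#' Flat key-value file with keys \code{r_h}, \code{r_c}, \code{f}, \code{T},
#' \code{t_c}, \code{P0} (hours and per-hour units). Missing keys fall back
#' to the [lifeHistory()] defaults; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A validated \linkS4class{LifeHistory}.
#' @export
readLifeHistory <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("r_h", "r_c", "f", "T", "t_c", "P0")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown life-history config keys: ", paste(extra, collapse = ", "))
  do.call(lifeHistory, cfg)
}
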