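# Independent oracles and small fixture builders shared across tests.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Discrete-time Euler integration of one growth cycle: exponential hyphal
# growth stepped at dt until onset, then linear conidia accumulation.
eulerCensus <- function(p, dt = 1e-3) {
  H <- p@P0
  nGrow <- round(p@t_c / dt)
  for (i in seq_len(nGrow)) H <- H * (1 + p@r_h * dt)
  conidia <- 0
  nProd <- round((p@T - p@t_c) / dt)
  for (i in seq_len(nProd)) conidia <- conidia + p@r_c * H * dt
  list(hyphalTotal = H, fragments = p@f * H, conidia = conidia,
       total = p@f * H + conidia)
}

# random valid parameter draw over a broad range
randomLifeHistory <- function() {
  lifeHistory(r_h = runif(1, 0.05, 1), r_c = runif(1, 0.05, 2),
              f = runif(1, 0, 1), T = 24, t_c = 0, P0 = 1)
}

# two-genotype, three-timepoint, two-replicate FPKM fixture built from a
# named list: values[[locus]] is a 2 x 3 matrix (ancestor/derived rows,
# 18/22/24 h columns), identical across replicates.
makeTinyExpression <- function(values, times = c(18, 22, 24)) {
  cells <- expand.grid(replicate = 1:2, time = times,
                       genotype = c("ancestor", "derived"),
                       stringsAsFactors = FALSE)
  m <- matrix(0, length(values), nrow(cells),
              dimnames = list(names(values), NULL))
  for (j in seq_len(nrow(cells))) {
    g <- match(cells$genotype[j], c("ancestor", "derived"))
    t <- match(cells$time[j], times)
    m[, j] <- vapply(values, function(v) v[g, t], 0)
  }
  fpkmExperiment(m, cells$genotype, cells$time, cells$replicate)
}
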