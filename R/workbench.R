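# Command-line workbench tying the modules together. The exported
# runWorkbench() takes an argv vector, dispatches to the model, simulator,
# synthetic-data and expression stages, and writes a JSON manifest (inputs,
# parameters, seed, output checksums) next to the outputs. A thin Rscript
# wrapper lives at inst/scripts/workbench.R.

.parseFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

.flagNum <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) {
    if (is.null(default)) stop("missing required flag --", key, call. = FALSE)
    return(default)
  }
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) stop("flag --", key, " must be numeric", call. = FALSE)
  v
}

.flagStr <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required flag --", key, call. = FALSE)
    return(default)
  }
  v
}

.writeManifest <- function(outDir, command, parameters, seed, inputs,
                           outputs) {
  sums <- as.list(tools::md5sum(outputs))
  names(sums) <- basename(outputs)
  jsonlite::write_json(list(command = command, parameters = parameters,
                            seed = seed, inputs = inputs,
                            output_checksums = sums),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
}

.cmdModel <- function(args) {
  sub <- args[1]
  flags <- .parseFlags(args[-1])
  if (identical(sub, "optimal-onset")) {
    p <- lifeHistory(r_h = .flagNum(flags, "r_h"),
                     r_c = .flagNum(flags, "r_c", 1),
                     f = .flagNum(flags, "f", 0),
                     T = .flagNum(flags, "T", 24), t_c = 0)
    cat(format(optimalOnset(p)), "\n", sep = "")
  } else if (identical(sub, "surface")) {
    rates <- as.numeric(strsplit(.flagStr(flags, "rates"), ",")[[1]])
    frags <- as.numeric(strsplit(.flagStr(flags, "fragmentations"),
                                 ",")[[1]])
    outDir <- .flagStr(flags, "out")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    s <- onsetSurface(rates, frags, T = .flagNum(flags, "T", 24))
    out <- file.path(outDir, "onset_surface.csv")
    writeOnsetSurface(s, out)
    .writeManifest(outDir, "model surface",
                   list(rates = rates, fragmentations = frags,
                        T = .flagNum(flags, "T", 24)),
                   NA, character(0), out)
  } else stop("unknown model subcommand '", sub, "'", call. = FALSE)
  0L
}

.cmdSimulate <- function(args, evolve = FALSE) {
  flags <- .parseFlags(args)
  scenarioPath <- .flagStr(flags, "scenario")
  outDir <- .flagStr(flags, "out")
  seed <- as.integer(.flagNum(flags, "seed", 1))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sc <- readScenario(scenarioPath)
  set.seed(seed)
  traj <- if (evolve) {
    if (is.null(sc$mutation))
      stop("evolve needs a 'mutation' block in the scenario", call. = FALSE)
    runEvolution(sc$state, sc$regime, sc$mutation)
  } else runSerial(sc$state, sc$regime)
  csv <- file.path(outDir, "trajectory.csv")
  js <- file.path(outDir, "summary.json")
  writeTrajectory(traj, csv, js)
  .writeManifest(outDir, if (evolve) "evolve" else "simulate",
                 list(scenario = basename(scenarioPath)), seed,
                 scenarioPath, c(csv, js))
  0L
}

.cmdSynth <- function(args) {
  sub <- args[1]
  flags <- .parseFlags(args[-1])
  outDir <- .flagStr(flags, "out")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (identical(sub, "expression")) {
    seed <- as.integer(.flagNum(flags, "seed", 1))
    gomap <- makeGOUniverse(nTerms = .flagNum(flags, "terms", 28),
                            lociPerTerm = .flagNum(flags, "loci-per-term", 25),
                            multiMembershipProb =
                              .flagNum(flags, "multi-membership", 0),
                            seed = seed)
    sim <- simulateExpression(gomap, seed = seed + 1L,
                              nBackgroundLoci =
                                .flagNum(flags, "background-loci", 9300))
    paths <- c(file.path(outDir, "expression.tsv"),
               file.path(outDir, "go_map.tsv"),
               file.path(outDir, "truth.json"))
    writeExpression(sim$expression, paths[1])
    writeGOMap(gomap, paths[2])
    writeTruth(sim$truth, paths[3])
    .writeManifest(outDir, "synth expression",
                   list(terms = .flagNum(flags, "terms", 28),
                        loci_per_term = .flagNum(flags, "loci-per-term", 25)),
                   seed, character(0), paths)
  } else if (identical(sub, "scenario")) {
    name <- .flagStr(flags, "name")
    fx <- makeScenarioFixture(name)
    out <- file.path(outDir, paste0(name, ".yaml"))
    writeScenario(fx, out)
    .writeManifest(outDir, "synth scenario", list(name = name), NA,
                   character(0), out)
  } else stop("unknown synth subcommand '", sub, "'", call. = FALSE)
  0L
}

.cmdExpr <- function(args) {
  sub <- args[1]
  flags <- .parseFlags(args[-1])
  exprPath <- .flagStr(flags, "expression")
  outDir <- .flagStr(flags, "out")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  x <- loadExpression(exprPath)
  seed <- as.integer(.flagNum(flags, "seed", 1))
  if (identical(sub, "filter")) {
    loci <- foldChangeLoci(x, .flagNum(flags, "threshold", 1),
                           .flagNum(flags, "pseudocount", 0.1))
    out <- file.path(outDir, "filtered_loci.txt")
    writeLines(loci, out)
    .writeManifest(outDir, "expr filter",
                   list(threshold = .flagNum(flags, "threshold", 1),
                        pseudocount = .flagNum(flags, "pseudocount", 0.1)),
                   seed, exprPath, out)
    return(0L)
  }
  norm <- normalizeExpression(x)
  if (identical(sub, "normalize")) {
    out <- file.path(outDir, "normalized_shares.tsv")
    d <- data.frame(locus_id = rownames(norm), assay(norm, "share"),
                    check.names = FALSE)
    utils::write.table(d, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .writeManifest(outDir, "expr normalize", list(), seed, exprPath, out)
    return(0L)
  }
  gomap <- loadGOMap(.flagStr(flags, "go-map"))
  if (identical(sub, "go-anova")) {
    alpha <- .flagNum(flags, "alpha", 0.05)
    correction <- .flagStr(flags, "correction", "BH")
    stats <- goGroupTests(norm, gomap, alpha = alpha,
                          correction = correction)
    fit <- globalFit(norm, gomap)
    p1 <- file.path(outDir, "go_group_stats.csv")
    p2 <- file.path(outDir, "global_fit.json")
    writeGroupStats(stats, p1)
    writeGlobalFit(fit, p2)
    .writeManifest(outDir, "expr go-anova",
                   list(alpha = alpha, correction = correction), seed,
                   c(exprPath, .flagStr(flags, "go-map")), c(p1, p2))
  } else if (identical(sub, "profile")) {
    prof <- deviationProfile(norm, gomap)
    out <- file.path(outDir, "deviation_profile.csv")
    writeDeviationProfile(prof, out)
    .writeManifest(outDir, "expr profile", list(), seed,
                   c(exprPath, .flagStr(flags, "go-map")), out)
  } else stop("unknown expr subcommand '", sub, "'", call. = FALSE)
  0L
}

#' Run the command-line workbench
#'
#' Dispatches the subcommands \code{model} (\code{optimal-onset},
#' \code{surface}), \code{simulate}, \code{evolve}, \code{synth}
#' (\code{expression}, \code{scenario}) and \code{expr} (\code{filter},
#' \code{normalize}, \code{go-anova}, \code{profile}). File-producing
#' commands write a \code{manifest.json} recording the command, its
#' parameters, the seed and md5 checksums of every output, so a run is
#' reproducible from its manifest alone. Diagnostics go to stderr; data go
#' to files only.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments when used from the wrapper script).
#' @return Integer exit status, invisibly: 0 on success, 2 on a validation
#'   error, 3 on a runtime error.
#' @examples
#' runWorkbench(c("model", "optimal-onset", "--r_h", "0.5", "--f", "0"))
#' @export
runWorkbench <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1) stop("usage: workbench <subcommand> ...",
                               call. = FALSE)
    cmd <- args[1]
    rest <- args[-1]
    switch(cmd,
      "model" = .cmdModel(rest),
      "simulate" = .cmdSimulate(rest, evolve = FALSE),
      "evolve" = .cmdSimulate(rest, evolve = TRUE),
      "synth" = .cmdSynth(rest),
      "expr" = .cmdExpr(rest),
      stop("unknown subcommand '", cmd, "'", call. = FALSE))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    # argument/config problems exit 2, anything deeper 3
    if (is.null(conditionCall(e))) 2L else 3L
  })
  invisible(as.integer(status))
}
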