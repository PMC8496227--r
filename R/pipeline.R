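# End-to-end orchestration: validated JSON config, staged execution
# (simulate -> scan -> census -> selection -> neutral null -> ddG), and a
# reproducibility manifest with input digests and per-stage timings.

.CONFIG_SCHEMA <- list(
  seed = "integer", outDir = "character",
  simulate = "list", scan = "list", selection = "list", mcnull = "list",
  ddg = "list")

#' Validate a pipeline configuration
#'
#' Checks the config (a list or a JSON file path) against the expected
#' schema; unknown or missing mandatory keys are reported together.
#'
#' @param config list or path to a JSON config.
#' @return the validated config list, with defaults filled in.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or JSON object")
  mandatory <- c("seed", "outDir")
  bad <- c(setdiff(names(config), names(.CONFIG_SCHEMA)),
           setdiff(mandatory, names(config)))
  if (length(bad))
    stop("config schema violation; offending key(s): ",
         paste(unique(bad), collapse = ", "))
  defaults <- list(simulate = list(), scan = list(), selection = list(),
                   mcnull = list(), ddg = list())
  modifyList(defaults, config)
}

#' Run the full synthetic pipeline
#'
#' Simulates a genome with planted retrocopies, scans it, runs the census,
#' evolves a codon alignment with a positively selected foreground class and
#' fits the branch-site models with their LRT, runs the Monte-Carlo neutral
#' null on a simulated pair, and classifies a synthetic free-energy table.
#' Stage failures for individual genes are collected, not fatal. All outputs
#' plus a manifest (tool version, config hash, seeds, input digests,
#' per-stage timings) are written under `outDir`.
#'
#' @param config list or JSON path accepted by [validateConfig()].
#' @return the manifest, invisibly; reports are files under `outDir`.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  manifest <- list(
    tool = "retroforge",
    version = as.character(utils::packageVersion("retroforge")),
    seed = seed, configHash = .digestConfig(cfg),
    stages = list(), errors = list())
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, fun) {
    t0 <- tic()
    res <- tryCatch(fun(), error = function(e) {
      manifest$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    manifest$stages[[name]] <<- list(seconds = round(tic() - t0, 2))
    res
  }

  sim <- stage("simulate", function() {
    args <- modifyList(list(nRetro = 3, targetLen = 3e5, seed = seed),
                       cfg$simulate)
    do.call(simulateRetrocopyGenome, args)
  })
  if (!is.null(sim)) {
    writeFasta(sim$genome, file.path(cfg$outDir, "genome.fa"))
    writeGff3(sim$annot, file.path(cfg$outDir, "parent.gff3"))
    write.table(sim$truth, file.path(cfg$outDir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  calls <- stage("scan", function() {
    tdb <- Biostrings::DNAStringSet(setNames(sim$mrna, geneId(sim$annot)))
    callRetrocopies(sim$annot, sim$mrna, sim$genome, tdb,
                    config = cfg$scan)
  })
  if (!is.null(calls))
    write.table(calls[, setdiff(names(calls), "blocks")],
                file.path(cfg$outDir, "calls.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  stage("census", function() {
    tdb <- Biostrings::DNAStringSet(setNames(sim$mrna, geneId(sim$annot)))
    retrocopyCensus(list(list(annot = sim$annot, mrna = sim$mrna)),
                    sim$genome, tdb, config = cfg$scan,
                    out = file.path(cfg$outDir, "census.tsv"))
  })

  sel <- stage("selection", function() {
    args <- modifyList(list(nCodons = 150, omega2 = 5, p2 = 0.1,
                            nStarts = 1), cfg$selection)
    tr <- ape::read.tree(
      text = "((fg1:0.25,fg2:0.25):0.25,bg1:0.35,bg2:0.35);")
    fgTips <- which(tr$tip.label %in% c("fg1", "fg2"))
    lt <- labeledTree(tr, tr$edge[, 2] %in%
                        c(fgTips, ape::getMRCA(tr, fgTips)))
    spec <- evolutionSpec(
      lt, kappa = 2,
      siteClasses = data.frame(proportion = c(0.45, 1 - 0.45 - args$p2,
                                              args$p2),
                               omega = c(0.1, 1, 1)),
      foregroundOmega = args$omega2, nCodons = args$nCodons, seed = seed)
    ev <- evolveCodons(spec)
    branchSiteTest(ev$alignment, lt, nStarts = max(2, args$nStarts),
                   seed = seed,
                   control = list(rel.tol = 1e-6, iter.max = 100))
  })
  if (!is.null(sel)) {
    rep <- list(
      ModelA = as.list(fitParams(sel$alt)), logL_ModelA = fitLogL(sel$alt),
      ModelA_null = as.list(fitParams(sel$null)),
      logL_null = fitLogL(sel$null),
      twoDeltaL = sel$lrt@twoDeltaL, p_value = sel$lrt@pValue)
    jsonlite::write_json(rep, file.path(cfg$outDir, "branch_site.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  mc <- stage("mcnull", function() {
    args <- modifyList(list(nReps = 1000), cfg$mcnull)
    tpl <- .demoTemplate(200, seed)
    mut <- decaySequence(tpl, subRate = 0.05, seed = seed + 1)$seq
    obs <- ng86(tpl, mut)
    k <- max(1, round(obs$Nd + obs$Sd))
    mcPvalue(obs, neutralNullConfig(tpl, K = k, nReps = args$nReps,
                                    seed = seed))
  })
  if (!is.null(mc))
    jsonlite::write_json(list(observed_omega = mc@observedOmega,
                              p_value = mc@pValue),
                         file.path(cfg$outDir, "mc_null.json"),
                         auto_unbox = TRUE, digits = NA)

  stage("ddg", function() {
    demo <- .demoDdg(seed)
    cls <- classifyDdgTable(demo$table, demo$chainA, demo$chainB)
    write.table(cls, file.path(cfg$outDir, "ddg_classified.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    summarizeDdg(cls, out = file.path(cfg$outDir, "ddg_summary.tsv"))
  })

  manifest$inputDigests <- .fileDigests(cfg$outDir,
                                        c("genome.fa", "parent.gff3"))
  manifest$outputs <- list.files(cfg$outDir)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.digestConfig <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.fileDigests <- function(dir, files) {
  paths <- file.path(dir, files)
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

# small in-frame template with no stops, for demo/report stages
.demoTemplate <- function(nCodons, seed) {
  set.seed(seed)
  .codonTables()
  paste(c("ATG", sample(.rf$codons[.rf$aa != "M"], nCodons - 1,
                        replace = TRUE)), collapse = "")
}

# synthetic free-energy table + two-chain coordinate set with a known
# interface: residues 1..10 of chain A sit within 5 A of chain B, the rest
# are translated away
.demoDdg <- function(seed) {
  set.seed(seed)
  mkChain <- function(n, offset) {
    data.frame(resno = rep(seq_len(n), each = 1), resid = "ALA",
               elety = "CA",
               x = seq_len(n) * 3 + offset, y = 0, z = 0)
  }
  chainA <- mkChain(20, 0)
  chainA$z <- ifelse(chainA$resno <= 10, 0, 50)
  chainB <- mkChain(20, 1.5)
  tab <- data.frame(
    site = 1:20, wt_aa = "A",
    mut_aa = rep(c("V", "L", "I", "T"), 5),
    ddg_bind = round(c(rep(2.5, 4), rep(0.5, 6), rnorm(10, 0.04, 0.17)), 3),
    ddg_fold = round(rnorm(20, 0, 0.8), 3))
  list(table = tab, chainA = chainA, chainB = chainB)
}
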