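stageOrder <- c("simulate", "thi", "fit", "params", "scan", "enrich",
                "report")
stageDeps <- list(simulate = character(0), thi = "simulate", fit = "thi",
                  params = "fit", scan = "fit", enrich = "scan",
                  report = c("params", "scan", "enrich"))

#' Pipeline run configuration
#'
#' @param sim a [simulationConfig()] (also carries the seed).
#' @param chain Gibbs protocol (default the desk-scale 20000/5000/10).
#' @param scanParity parity whose GEBV components are scanned (default 1).
#' @param windowBp scan window (default 2e6).
#' @param flank SNP-to-gene flank, bp (default 15000).
#' @param topFraction,minParities candidate-gene rule (defaults 0.05, 2).
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(sim = simulationConfig(),
                      chain = list(total = 20000, burnin = 5000, thin = 10),
                      scanParity = 1, windowBp = 2e6, flank = 15000,
                      topFraction = 0.05, minParities = 2) {
  structure(list(sim = sim, chain = chain, scanParity = scanParity,
                 windowBp = windowBp, flank = flank,
                 topFraction = topFraction, minParities = minParities),
            class = "runConfig")
}

readManifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE)
  else list(stages = list())
}

writeManifest <- function(dir, manifest) {
  # written atomically: temp file then rename at the stage boundary
  tmp <- file.path(dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(NULL)
}

#' Run one pipeline stage
#'
#' Stages (`simulate`, `thi`, `fit`, `params`, `scan`, `enrich`, `report`)
#' write their artifacts under `dir` and update `manifest.json` (config
#' snapshot, seed, input checksums, timing, completion flags). Upstream
#' stages are enforced; re-running a completed stage is a no-op unless
#' `force = TRUE`. Deterministic stages reproduce byte-identical outputs
#' given the same config and seed.
#'
#' @param name stage name.
#' @param cfg a [runConfig()].
#' @param dir run directory (created).
#' @param force re-run even if the stage is already complete.
#' @return the manifest, invisibly.
#' @export
runStage <- function(name, cfg, dir, force = FALSE) {
  name <- match.arg(name, stageOrder)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- readManifest(dir)
  done <- names(Filter(function(s) isTRUE(s$complete), manifest$stages))
  missing <- setdiff(stageDeps[[name]], done)
  if (length(missing))
    stop("stage '", name, "' requires completed stage(s): ",
         paste(missing, collapse = ", "))
  if (name %in% done && !force) {
    message("stage '", name, "' already complete; skipping (use force=TRUE)")
    return(invisible(manifest))
  }
  t0 <- Sys.time()
  files <- stageImpl[[name]](cfg, dir)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$package_version <- as.character(utils::packageVersion("thermoRRM"))
  manifest$seed <- cfg$sim$seed
  if (is.null(manifest$config))
    manifest$config <- list(chain = cfg$chain, scanParity = cfg$scanParity,
                            windowBp = cfg$windowBp, flank = cfg$flank,
                            nCows = cfg$sim$nCowsPhenotyped,
                            trait = cfg$sim$trait)
  manifest$stages[[name]] <- list(
    complete = TRUE, elapsed_s = round(elapsed, 3),
    files = as.list(files),
    checksums = as.list(tools::md5sum(unname(files))))
  writeManifest(dir, manifest)
  message(sprintf("[%s] stage complete in %.1fs (seed %s)", name, elapsed,
                  as.character(cfg$sim$seed)))
  invisible(manifest)
}

#' Run the pipeline end to end
#'
#' @param cfg a [runConfig()].
#' @param dir run directory.
#' @param stages stages to run in order (default all).
#' @param force passed to [runStage()].
#' @return the final manifest, invisibly.
#' @export
runPipeline <- function(cfg, dir, stages = stageOrder, force = FALSE) {
  for (s in stages) runStage(s, cfg, dir, force = force)
  invisible(readManifest(dir))
}

stagePath <- function(dir, x) file.path(dir, x)

stageImpl <- list(
  simulate = function(cfg, dir) {
    study <- simulateStudy(cfg$sim)
    files <- writeStudyFiles(study, dir)
    saveRDS(study, stagePath(dir, "state_study.rds"))
    files
  },
  thi = function(cfg, dir) {
    ph <- utils::read.table(stagePath(dir, "phenotypes.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    daily <- utils::read.table(stagePath(dir, "daily_thi.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    daily$date <- as.Date(daily$date)
    ph$thi <- assignTestDayTHI(daily, as.Date(ph$test_date))
    ph$heat_load <- heatLoad(ph$thi, cfg$sim$thiThreshold)
    out <- stagePath(dir, "phenotypes_thi.tsv")
    utils::write.table(ph, out, sep = "\t", quote = FALSE, row.names = FALSE)
    c(phenotypes_thi = out)
  },
  fit = function(cfg, dir) {
    ph <- utils::read.table(stagePath(dir, "phenotypes_thi.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ped <- readPedigree(stagePath(dir, "pedigree.tsv"))
    spec <- modelSpec(thiThreshold = cfg$sim$thiThreshold,
                      parities = cfg$sim$parities)
    val <- validateTestDayRecords(ph, spec)
    design <- buildDesign(val$records, ped, spec)
    Ainv <- buildAInverse(ped)
    init <- VarianceComponents(cfg$sim$Phi, cfg$sim$Psi, cfg$sim$Rdiag)
    chain <- gibbsSampler(design, Ainv, init, chain = cfg$chain,
                          seed = cfg$sim$seed)
    writeChain(chain, stagePath(dir, "chain.tsv"))
    vc <- vcFromChain(chain)
    sol <- solveMME(assembleMME(design, vc, Ainv))
    saveRDS(list(design = design, chain = chain, vc = vc, sol = sol,
                 edits = val$report), stagePath(dir, "state_fit.rds"))
    utils::write.table(posteriorSummary(chain),
                       stagePath(dir, "vc_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(chain = stagePath(dir, "chain.tsv"),
      vc_summary = stagePath(dir, "vc_summary.tsv"))
  },
  params = function(cfg, dir) {
    st <- readRDS(stagePath(dir, "state_fit.rds"))
    par <- chainGeneticParameters(st$chain)
    out <- posteriorSummary(par)
    f <- stagePath(dir, "genetic_parameters.tsv")
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    c(genetic_parameters = f)
  },
  scan = function(cfg, dir) {
    st <- readRDS(stagePath(dir, "state_fit.rds"))
    geno <- readGenotypes(stagePath(dir, "genotypes.tsv"),
                          stagePath(dir, "snp_map.tsv"))
    qc <- qcSnps(geno)
    ped <- st$design$ped
    gids <- intersect(sampleIds(qc$geno), st$design$cowIds)
    sub <- GenotypeData(genoCodes(qc$geno)[gids, , drop = FALSE],
                        snpMap(qc$geno), gids)
    A22 <- extractA22(ped, gids)
    G <- buildG(sub, A22 = A22)
    Hinv <- buildHInverse(buildAInverse(ped), invertRelationship(G$G),
                          invertRelationship(A22))
    sol <- solveMME(assembleMME(st$design, st$vc, Hinv))
    tracks <- list()
    for (comp in c("a", "v")) {
      gebv <- ebvComponent(sol, gids, comp, cfg$scanParity)
      tr <- backsolveSnpEffects(gebv, sub, alleleFreq = G$alleleFreq)
      wv <- windowVariance(tr, sub, windowBp = cfg$windowBp,
                           alleleFreq = G$alleleFreq)
      tracks[[paste0(comp, "_p", cfg$scanParity)]] <- wv
      writeTrack(tr, stagePath(dir, sprintf("snp_effects_%s_p%d.tsv", comp,
                                            cfg$scanParity)))
      writeTrack(wv, stagePath(dir, sprintf("windows_%s_p%d.tsv", comp,
                                            cfg$scanParity)))
    }
    saveRDS(list(sol = sol, geno = sub, freq = G$alleleFreq,
                 tracks = tracks), stagePath(dir, "state_scan.rds"))
    stats::setNames(
      stagePath(dir, sprintf("windows_%s_p%d.tsv", c("a", "v"),
                             cfg$scanParity)),
      paste0("windows_", c("a", "v")))
  },
  enrich = function(cfg, dir) {
    st <- readRDS(stagePath(dir, "state_scan.rds"))
    fit <- readRDS(stagePath(dir, "state_fit.rds"))
    ann <- readGeneAnnotation(stagePath(dir, "genes.tsv"))
    sets <- readGmt(stagePath(dir, "gene_sets.gmt"))
    asg <- assignSnpsToGenes(snpMap(st$geno), ann, flank = cfg$flank)
    P <- fit$design$nParities
    tracks <- lapply(seq_len(P), function(l)
      backsolveSnpEffects(
        ebvComponent(st$sol, sampleIds(st$geno), "v", l),
        st$geno, alleleFreq = st$freq))
    fc <- flagCandidateGenes(tracks, asg$assignments,
                             topFraction = cfg$topFraction,
                             minParities = min(cfg$minParities, P))
    enr <- fisherEnrichment(fc$candidates, sets, universe = asg$genes)
    f <- stagePath(dir, "enrichment.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(fc$candidates, stagePath(dir, "candidate_genes.txt"))
    c(enrichment = f, candidates = stagePath(dir, "candidate_genes.txt"))
  },
  report = function(cfg, dir) {
    st <- readRDS(stagePath(dir, "state_scan.rds"))
    mt <- manhattanTable(st$tracks, topK = 5)
    f <- stagePath(dir, "top_windows.tsv")
    utils::write.table(mt$top, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(top_windows = f)
  }
)
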