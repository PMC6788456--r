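#' Default additive (co)variance matrix for simulation
#'
#' Builds the 2P x 2P additive matrix Phi for a trait from the published
#' reference components: published within-parity variances/covariances on the
#' diagonal blocks and published across-parity intercept/slope correlations on
#' the off-diagonal blocks. The unpublished across-parity intercept-slope
#' correlations are filled by a symmetrised path rule,
#' `corr(a_i, v_j) = (cor_gen[i,j] * r_j + cor_ht[i,j] * r_i) / 2` with
#' `r_l` the within-parity intercept-slope correlation; the resulting milk
#' matrix is positive definite (checked at construction).
#'
#' @param trait `"milk"`, `"fat"` or `"protein"`.
#' @param parities subset of 1:3 (default all three).
#' @return numeric matrix, coefficient order (a1, v1, a2, v2, ...).
#' @export
defaultPhi <- function(trait = "milk", parities = 1:3) {
  rv <- referenceVarianceComponents()
  rv <- rv[rv$trait == trait, ]
  pc <- referenceParityCorrelations()[[trait]]
  sa <- rv$sigma_a2
  sv <- rv$sigma_v2_x100 / 100
  sav <- rv$sigma_av_x10 / 10
  r <- sav / sqrt(sa * sv)
  C <- matrix(0, 6, 6)
  for (i in 1:3) for (j in 1:3) {
    C[2 * i - 1, 2 * j - 1] <- pc$cor_gen[i, j]
    C[2 * i, 2 * j] <- pc$cor_ht[i, j]
    C[2 * i - 1, 2 * j] <- if (i == j) r[i] else
      (pc$cor_gen[i, j] * r[j] + pc$cor_ht[i, j] * r[i]) / 2
    C[2 * i, 2 * j - 1] <- C[2 * i - 1, 2 * j]
  }
  C <- (C + t(C)) / 2
  sd6 <- sqrt(as.vector(rbind(sa, sv)))
  Phi <- diag(sd6) %*% C %*% diag(sd6)
  idx <- as.vector(rbind(2 * parities - 1, 2 * parities))
  Phi <- Phi[idx, idx, drop = FALSE]
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("constructed Phi is not positive definite")
  cf <- coefNames(length(parities))
  dimnames(Phi) <- list(cf, cf)
  Phi
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions: milk-yield variance components from the published
#' reference estimates (permanent-environment components, which are
#' unpublished, default to half the corresponding additive components,
#' `Psi = 0.5 * Phi`), a subtropical THI series whose mean daily THI exceeds
#' the threshold 68 on roughly two-thirds of days, monthly test days with
#' about ten tests per lactation, and a three-generation random-mating
#' pedigree whose final generation supplies the phenotyped cows.
#'
#' @param seed integer seed for all generator stages.
#' @param nCowsPhenotyped phenotyped cows (final generation; default 500).
#' @param nFounders founder animals, half male (default 80).
#' @param nGenerations offspring generations (default 3).
#' @param nPerGeneration animals in intermediate generations (default
#'   `max(nFounders, nCowsPhenotyped %/% 2)`).
#' @param parities parities simulated and analysed (default 1:3).
#' @param trait `"milk"`, `"fat"` or `"protein"` (selects default variance
#'   components).
#' @param Phi,Psi,Rdiag variance components; defaults from [defaultPhi()]
#'   and the reference residuals.
#' @param nSnps,nChromosomes,chromosomeLengthBp marker panel (default 600
#'   SNPs on 3 chromosomes of 20 Mb).
#' @param mafRange founder allele-frequency range (default c(0.05, 0.5)).
#' @param qtl optional data.frame (`chr`, `pos`, `component` in
#'   \{"a","v"\}, `effect` per allele) of planted QTL added on top of the
#'   polygenic term (Phi is not re-normalised; the induced variance
#'   inflation is reported in the truth object). An optional `var_share`
#'   column (with `effect = NA`) instead sizes each effect so the QTL
#'   explains that fraction of the component's polygenic variance at the
#'   realised marker variance.
#' @param weather list: `mean` (72), `amplitude` (7), `noiseSd` (2.5),
#'   `startDate`, `years` — a sinusoidal annual THI cycle plus Gaussian
#'   noise.
#' @param nHerds contemporary herds (default 15).
#' @param testIntervalDays days between herd test dates (default 30).
#' @param baseMean overall yield mean (default 25, milk kg).
#' @param htdSd SD of herd-test-day effects (default 1.5).
#' @param thiThreshold heat-load threshold (default 68).
#' @return a list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(seed = 1, nCowsPhenotyped = 500, nFounders = 80,
                             nGenerations = 3, nPerGeneration = NULL,
                             parities = 1:3, trait = "milk",
                             Phi = NULL, Psi = NULL, Rdiag = NULL,
                             nSnps = 600, nChromosomes = 3,
                             chromosomeLengthBp = 2e7,
                             mafRange = c(0.05, 0.5), qtl = NULL,
                             weather = list(), nHerds = 15,
                             testIntervalDays = 30, baseMean = 25,
                             htdSd = 1.5, thiThreshold = 68) {
  parities <- as.integer(parities)
  P <- length(parities)
  if (is.null(Phi)) Phi <- defaultPhi(trait, parities)
  if (is.null(Psi)) Psi <- 0.5 * Phi
  if (is.null(Rdiag)) {
    rv <- referenceVarianceComponents()
    Rdiag <- rv$sigma_e2[rv$trait == trait][parities]
  }
  w <- utils::modifyList(
    list(mean = 72, amplitude = 7, noiseSd = 2.5,
         startDate = as.Date("2010-01-01"), years = P + 1),
    weather)
  if (is.null(nPerGeneration))
    nPerGeneration <- max(nFounders, nCowsPhenotyped %/% 2)
  stopifnot(nFounders >= 2, nCowsPhenotyped > 0, nSnps > 0,
            length(Rdiag) == P, all(dim(Phi) == 2 * P))
  structure(list(seed = seed, nCowsPhenotyped = nCowsPhenotyped,
                 nFounders = nFounders, nGenerations = nGenerations,
                 nPerGeneration = nPerGeneration, parities = parities,
                 trait = trait, Phi = Phi, Psi = Psi, Rdiag = Rdiag,
                 nSnps = nSnps, nChromosomes = nChromosomes,
                 chromosomeLengthBp = chromosomeLengthBp,
                 mafRange = mafRange, qtl = qtl, weather = w,
                 nHerds = nHerds, testIntervalDays = testIntervalDays,
                 baseMean = baseMean, htdSd = htdSd,
                 thiThreshold = thiThreshold),
            class = "simulationConfig")
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Discrete generations: founders (half male), intermediate generations with
#' sires and dams drawn at random from the previous generation, and a final
#' all-female generation of the phenotyped cows. Acyclic and topologically
#' ordered by construction.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `ped` (a [Pedigree-class]), `sex` (per animal,
#'   `"M"`/`"F"`), `generation` (integer per animal) and `cows` (ids of the
#'   final generation).
#' @export
simulatePedigree <- function(cfg) {
  set.seed(cfg$seed)
  id <- function(g, i) sprintf("G%d_%04d", g, i)
  animal <- id(0, seq_len(cfg$nFounders))
  sire <- dam <- rep(NA_character_, cfg$nFounders)
  sex <- rep(c("M", "F"), length.out = cfg$nFounders)
  gen <- rep(0L, cfg$nFounders)
  prev <- animal; prevSex <- sex
  if (cfg$nGenerations > 0) for (g in seq_len(cfg$nGenerations)) {
    last <- g == cfg$nGenerations
    n <- if (last) cfg$nCowsPhenotyped else cfg$nPerGeneration
    males <- prev[prevSex == "M"]; females <- prev[prevSex == "F"]
    if (!length(males) || !length(females))
      stop("a generation ran out of one sex; increase nFounders")
    a <- id(g, seq_len(n))
    s <- sample(males, n, replace = TRUE)
    d <- sample(females, n, replace = TRUE)
    sx <- if (last) rep("F", n) else rep(c("M", "F"), length.out = n)
    animal <- c(animal, a); sire <- c(sire, s); dam <- c(dam, d)
    sex <- c(sex, sx); gen <- c(gen, rep(g, n))
    prev <- a; prevSex <- sx
  }
  ped <- Pedigree(animal, sire, dam)
  ord <- match(animalIds(ped), animal)
  list(ped = ped, sex = sex[ord], generation = gen[ord],
       cows = animal[gen == cfg$nGenerations])
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn at allele frequencies uniform on
#' `cfg$mafRange`; descendants inherit one allele per SNP from each parent
#' by Mendelian sampling (unlinked drop). Map positions are uniform within
#' each chromosome and sorted.
#'
#' @param ped a [Pedigree-class] (typically from [simulatePedigree()]).
#' @param cfg a [simulationConfig()].
#' @return list with `geno` (a [GenotypeData-class] over all pedigree
#'   animals) and `founderFreq` (the founder allele frequencies).
#' @export
simulateGenotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nAnimals(ped)
  m <- cfg$nSnps
  p <- stats::runif(m, cfg$mafRange[1], cfg$mafRange[2])
  perChr <- rep(m %/% cfg$nChromosomes, cfg$nChromosomes)
  perChr[seq_len(m - sum(perChr))] <- perChr[seq_len(m - sum(perChr))] + 1L
  chr <- rep(as.character(seq_len(cfg$nChromosomes)), perChr)
  pos <- unlist(lapply(perChr, function(k)
    sort(sample.int(cfg$chromosomeLengthBp, k))))
  map <- data.frame(snp = sprintf("snp%05d", seq_len(m)), chr = chr,
                    pos = pos, allele = "B", stringsAsFactors = FALSE)
  H1 <- H2 <- matrix(0L, n, m)
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(n)) {
    H1[i, ] <- if (s[i] > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, H1[s[i], ], H2[s[i], ])
    } else as.integer(stats::runif(m) < p)
    H2[i, ] <- if (d[i] > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, H1[d[i], ], H2[d[i], ])
    } else as.integer(stats::runif(m) < p)
  }
  list(geno = GenotypeData(H1 + H2, map, animalIds(ped)), founderFreq = p)
}

#' Simulate a seasonal daily THI series
#'
#' Sinusoidal annual cycle plus Gaussian noise:
#' `thi(t) = mean + amplitude * sin(2 pi (doy - 105) / 365) + N(0, noiseSd)`
#' (peak around mid-July). Under the defaults the series crosses the
#' heat-stress threshold 68 on roughly two-thirds of days, emulating a
#' subtropical location.
#'
#' @param cfg a [simulationConfig()].
#' @return data.frame (`date`, `thi`), one row per day.
#' @export
simulateWeather <- function(cfg) {
  set.seed(cfg$seed + 2L)
  w <- cfg$weather
  nd <- ceiling(365.25 * w$years)
  dates <- w$startDate + seq_len(nd) - 1L
  doy <- as.integer(format(dates, "%j"))
  thi <- w$mean + w$amplitude * sin(2 * pi * (doy - 105) / 365) +
    stats::rnorm(nd, 0, w$noiseSd)
  if (!any(thi > cfg$thiThreshold))
    warning("simulated THI never exceeds the threshold ", cfg$thiThreshold)
  data.frame(date = dates, thi = thi)
}

#' Simulate test-day phenotypes under the reaction-norm model
#'
#' True breeding-value coefficient vectors are generated by the
#' pedigree-recursive rule (child = half the parent average plus a
#' Mendelian-sampling deviation scaled by `0.5 - 0.25(F_s + F_d)`), which
#' realises covariance `A (x) Phi` without a dense Cholesky; optional QTL
#' effects are added from centred genotype codes on top of the polygenic
#' draw. Permanent-environment pairs are drawn iid from Psi; residuals per
#' parity from Rdiag. Records follow herd-synchronised monthly test dates
#' with DIM in \[5, 305\] and heat loads from the supplied daily THI series
#' (mean of the three days before each test).
#'
#' @param sim output of [simulatePedigree()].
#' @param geno a [GenotypeData-class] (required only when `cfg$qtl` is set).
#' @param weather daily THI series from [simulateWeather()].
#' @param cfg a [simulationConfig()].
#' @return list with `records` (test-day data.frame: `cow`, `herd`,
#'   `test_date`, `parity`, `dim`, `yield`, `thi`, `heat_load`) and `truth`
#'   (`u` true additive coefficients per animal, `w` true permanent
#'   coefficients per cow, `qtl` the planted QTL with realised variance
#'   contribution, `htd`/`dimEffects` the fixed effects used).
#' @export
simulatePhenotypes <- function(sim, geno = NULL, weather, cfg) {
  set.seed(cfg$seed + 3L)
  ped <- sim$ped
  n <- nAnimals(ped)
  P <- length(cfg$parities)
  p2 <- 2L * P
  cholPhi <- chol(cfg$Phi)
  f <- unname(inbreeding(ped))
  s <- ped@sire; d <- ped@dam
  U <- matrix(0, n, p2, dimnames = list(animalIds(ped), coefNames(P)))
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else -1
    fd <- if (d[i] > 0L) f[d[i]] else -1
    di <- 0.5 - 0.25 * (fs + fd)
    pa <- (if (s[i] > 0L) U[s[i], ] else 0) / 2 +
          (if (d[i] > 0L) U[d[i], ] else 0) / 2
    U[i, ] <- pa + sqrt(di) * as.numeric(crossprod(cholPhi, stats::rnorm(p2)))
  }
  qtlTruth <- NULL
  if (!is.null(cfg$qtl)) {
    if (is.null(geno)) stop("geno required when QTL are planted")
    map <- snpMap(geno)
    codes <- genoCodes(geno)[animalIds(ped), , drop = FALSE]
    qtlTruth <- cfg$qtl
    qtlTruth$snp <- NA_character_
    qtlTruth$var_contrib <- NA_real_
    qtlTruth$effect_realised <- NA_real_
    for (k in seq_len(nrow(cfg$qtl))) {
      onchr <- which(map$chr == as.character(cfg$qtl$chr[k]))
      j <- onchr[which.min(abs(map$pos[onchr] - cfg$qtl$pos[k]))]
      z <- codes[, j] - mean(codes[, j])
      cols <- if (cfg$qtl$component[k] == "a") 2 * seq_len(P) - 1
              else 2 * seq_len(P)
      eff <- cfg$qtl$effect[k]
      if (!is.null(cfg$qtl$var_share) && !is.na(cfg$qtl$var_share[k])) {
        # size the effect so the QTL explains the stated share of the
        # component's polygenic variance at the realised marker variance
        comp <- mean(diag(cfg$Phi)[cols])
        eff <- sqrt(cfg$qtl$var_share[k] * comp / stats::var(z))
      }
      U[, cols] <- U[, cols] + eff * z
      qtlTruth$snp[k] <- map$snp[j]
      qtlTruth$effect_realised[k] <- eff
      qtlTruth$var_contrib[k] <- stats::var(z) * eff^2
    }
  }
  cows <- sim$cows
  nc <- length(cows)
  W <- matrix(stats::rnorm(nc * p2), nc, p2) %*% chol(cfg$Psi)
  dimnames(W) <- list(cows, coefNames(P))

  herd <- sample.int(cfg$nHerds, nc, replace = TRUE)
  # smooth lactation-curve fixed effects by DIM class
  spec <- modelSpec(thiThreshold = cfg$thiThreshold, parities = cfg$parities)
  nCls <- dimClass(spec$dimRange[2], spec)
  mid <- spec$dimRange[1] + (seq_len(nCls) - 0.5) * spec$dimClassWidth
  dimEffects <- 4 * exp(-(mid - 60)^2 / 2e4) - 0.01 * mid
  htdKey <- new.env()
  recs <- vector("list", 2000)
  nr <- 0L
  w0 <- min(weather$date)
  calving <- sample.int(60, nc, replace = TRUE)      # day-of-year of calving
  for (ci in seq_len(nc)) {
    for (li in seq_len(P)) {
      calve <- w0 + 365L * (li - 1L) + calving[ci]
      tests <- seq(4L, 364L, by = cfg$testIntervalDays)  # herd-synchronised
      for (td in tests) {
        date <- w0 + 365L * (li - 1L) + td
        dim <- as.integer(date - calve)
        if (dim < spec$dimRange[1] || dim > spec$dimRange[2]) next
        if (date - 3L < w0 || date > max(weather$date)) next
        nr <- nr + 1L
        recs[[nr]] <- list(cow = cows[ci], herd = herd[ci], date = date,
                           parity = cfg$parities[li], dim = dim, ci = ci,
                           li = li)
      }
    }
  }
  recs <- recs[seq_len(nr)]
  rdf <- data.frame(
    cow = vapply(recs, `[[`, character(1), "cow"),
    herd = vapply(recs, `[[`, integer(1), "herd"),
    test_date = as.Date(vapply(recs, function(r) as.character(r$date),
                               character(1))),
    parity = vapply(recs, `[[`, integer(1), "parity"),
    dim = vapply(recs, `[[`, integer(1), "dim"),
    stringsAsFactors = FALSE)
  thi <- assignTestDayTHI(weather, rdf$test_date)
  fl <- heatLoad(thi, cfg$thiThreshold)
  htdLab <- paste0(rdf$herd, ":", rdf$test_date, ":", rdf$parity)
  htdLev <- unique(htdLab)
  htdEff <- stats::setNames(stats::rnorm(length(htdLev), 0, cfg$htdSd),
                            htdLev)
  li <- vapply(recs, `[[`, integer(1), "li")
  ci <- vapply(recs, `[[`, integer(1), "ci")
  ui <- match(rdf$cow, animalIds(ped))
  acol <- 2L * li - 1L
  e <- stats::rnorm(nr, 0, sqrt(cfg$Rdiag[li]))
  yield <- cfg$baseMean + htdEff[htdLab] + dimEffects[dimClass(rdf$dim, spec)] +
    U[cbind(ui, acol)] + fl * U[cbind(ui, acol + 1L)] +
    W[cbind(ci, acol)] + fl * W[cbind(ci, acol + 1L)] + e
  rdf$yield <- as.numeric(yield)
  rdf$thi <- thi
  rdf$heat_load <- fl
  list(records = rdf,
       truth = list(u = U, w = W, qtl = qtlTruth,
                    htd = htdEff, dimEffects = dimEffects))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: pedigree, genotypes, weather and phenotypes from one
#' config, seed-deterministic end to end.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `ped`, `sex`, `cows`, `geno`, `founderFreq`, `weather`,
#'   `records`, `truth`, `cfg`.
#' @export
simulateStudy <- function(cfg = simulationConfig()) {
  sim <- simulatePedigree(cfg)
  g <- simulateGenotypes(sim$ped, cfg)
  weather <- simulateWeather(cfg)
  ph <- simulatePhenotypes(sim, g$geno, weather, cfg)
  c(sim[c("ped", "sex", "cows")], g, list(weather = weather),
    ph, list(cfg = cfg))
}

#' Write every pipeline input format for a simulated study
#'
#' Emits pedigree, phenotype, genotype + map, daily-THI, gene-annotation and
#' GMT files under a directory so the pipeline stages can run from files
#' alone. Gene intervals are synthetic: non-overlapping windows tiled along
#' each simulated chromosome; gene sets are random draws over those genes.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created).
#' @param nGenes synthetic genes to tile (default 60).
#' @param nSets synthetic gene sets (default 10).
#' @return named character vector of file paths.
#' @export
writeStudyFiles <- function(study, dir, nGenes = 60, nSets = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(x) file.path(dir, x)
  utils::write.table(parents(study$ped), path("pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "0")
  utils::write.table(study$records, path("phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- data.frame(id = sampleIds(study$geno),
                  as.data.frame(genoCodes(study$geno)),
                  check.names = FALSE)
  utils::write.table(g, path("genotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(snpMap(study$geno), path("snp_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$weather, path("daily_thi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  set.seed(study$cfg$seed + 4L)
  chrs <- as.character(seq_len(study$cfg$nChromosomes))
  perChr <- rep(nGenes %/% length(chrs), length(chrs))
  perChr[seq_len(nGenes - sum(perChr))] <-
    perChr[seq_len(nGenes - sum(perChr))] + 1L
  L <- study$cfg$chromosomeLengthBp
  ann <- do.call(rbind, lapply(seq_along(chrs), function(k) {
    w <- L %/% perChr[k]
    start <- (seq_len(perChr[k]) - 1L) * w + w %/% 4L
    data.frame(gene = sprintf("gene_%s_%02d", chrs[k], seq_len(perChr[k])),
               chr = chrs[k], start = start, end = start + w %/% 2L,
               strand = "+", stringsAsFactors = FALSE)
  }))
  utils::write.table(ann, path("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sets <- lapply(seq_len(nSets), function(i)
    sample(ann$gene, max(3, stats::rpois(1, 8))))
  lines <- vapply(seq_len(nSets), function(i)
    paste(c(sprintf("set%02d", i), "synthetic", sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path("gene_sets.gmt"))
  c(pedigree = path("pedigree.tsv"), phenotypes = path("phenotypes.tsv"),
    genotypes = path("genotypes.tsv"), snp_map = path("snp_map.tsv"),
    daily_thi = path("daily_thi.tsv"), genes = path("genes.tsv"),
    gene_sets = path("gene_sets.gmt"))
}
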