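#' Model specification for the reaction-norm test-day model
#'
#' @param dimClassWidth width of the days-in-milk fixed classes, days
#'   (default 20; classes anchored at DIM 5, i.e. \[5,24\], \[25,44\], ...,
#'   with the last class absorbing the remainder up to 305).
#' @param thiThreshold THI threshold of the heat-load covariate (default 68).
#' @param parities parities analysed (default 1:3).
#' @param minTestsPerLactation minimum test-day records per lactation
#'   (default 6).
#' @param dimRange admissible days-in-milk range (default c(5, 305)).
#' @return a list of class `"modelSpec"`.
#' @export
modelSpec <- function(dimClassWidth = 20, thiThreshold = 68, parities = 1:3,
                      minTestsPerLactation = 6, dimRange = c(5, 305)) {
  stopifnot(dimClassWidth > 0, length(dimRange) == 2, dimRange[1] < dimRange[2])
  structure(list(dimClassWidth = dimClassWidth, thiThreshold = thiThreshold,
                 parities = as.integer(parities),
                 minTestsPerLactation = minTestsPerLactation,
                 dimRange = dimRange),
            class = "modelSpec")
}

#' Apply test-day record edits
#'
#' Standard edits before model fitting: records outside the admissible DIM
#' range are dropped; parities beyond those modelled are dropped; lactations
#' (cow x parity) left with fewer than the minimum number of tests are
#' dropped entirely. Counts per rule are reported.
#'
#' @param records data.frame with at least columns `cow`, `parity`, `dim`.
#' @param spec a [modelSpec()].
#' @return list with `records` (the surviving rows) and `report` (named
#'   integer vector: `dim`, `parity`, `min_tests`, `retained`).
#' @export
validateTestDayRecords <- function(records, spec = modelSpec()) {
  need <- c("cow", "parity", "dim")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  n0 <- nrow(records)
  okDim <- records$dim >= spec$dimRange[1] & records$dim <= spec$dimRange[2]
  nDim <- sum(!okDim)
  records <- records[okDim, , drop = FALSE]
  okPar <- records$parity %in% spec$parities
  nPar <- sum(!okPar)
  records <- records[okPar, , drop = FALSE]
  lact <- interaction(records$cow, records$parity, drop = TRUE)
  cnt <- table(lact)
  keepLact <- names(cnt)[cnt >= spec$minTestsPerLactation]
  nMin <- sum(!(lact %in% keepLact))
  records <- records[lact %in% keepLact, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       report = c(dim = nDim, parity = nPar, min_tests = nMin,
                  retained = nrow(records)))
}

#' Days-in-milk fixed-effect class
#'
#' Classes of `width` days anchored at the lower DIM bound: with defaults,
#' class 1 is DIM 5-24, class 2 is 25-44, ..., and the last class absorbs
#' the remainder up to DIM 305.
#'
#' @param dim days in milk (vectorised).
#' @param spec a [modelSpec()].
#' @return integer class index (1-based).
#' @export
dimClass <- function(dim, spec = modelSpec()) {
  lo <- spec$dimRange[1]; hi <- spec$dimRange[2]; w <- spec$dimClassWidth
  if (any(dim < lo | dim > hi)) stop("dim outside admissible range")
  k <- pmin((dim - lo) %/% w + 1, (hi - lo) %/% w)
  as.integer(k)
}

#' Build the design of the reaction-norm test-day model
#'
#' Maps each record to its herd-test-day level (fixed; herd x test date
#' within parity), its DIM class (fixed, first class per parity dropped for
#' identifiability), its (animal, parity) additive coefficient pair with
#' covariates (1, f) and its (cow, parity) permanent-environment pair with
#' the same covariates. The heat load f is taken from the `heat_load` column
#' if present, otherwise computed from a supplied daily THI series.
#'
#' @param records data.frame with columns `cow`, `herd`, `test_date`,
#'   `parity`, `dim`, `yield`, and either `heat_load` or nothing (then
#'   `daily` must be given).
#' @param ped a [Pedigree-class] covering every cow in `records`.
#' @param spec a [modelSpec()].
#' @param daily optional daily THI series (see [dailyMeanTHI()]) used to
#'   assign heat loads when `records$heat_load` is absent.
#' @return a list of class `"rrmDesign"` with the incidence indexing used by
#'   [assembleMME()] and [gibbsSampler()]: record vectors `y`, `parity`
#'   (re-indexed 1..P), `f`, `htd`, `dimcl` (0 = dropped baseline class),
#'   `animal` (pedigree code), `cow` (phenotyped-cow index), plus level
#'   tables and the pedigree.
#' @export
buildDesign <- function(records, ped, spec = modelSpec(), daily = NULL) {
  need <- c("cow", "herd", "test_date", "parity", "dim", "yield")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records$cow <- as.character(records$cow)
  miss <- setdiff(unique(records$cow), animalIds(ped))
  if (length(miss))
    stop("cows missing from pedigree: ", paste(miss, collapse = ", "))
  if (is.null(records$heat_load)) {
    if (is.null(daily))
      stop("records carry no heat_load and no daily THI series was supplied")
    thi <- assignTestDayTHI(daily, records$test_date)
    records$heat_load <- heatLoad(thi, spec$thiThreshold)
  }
  if (any(records$heat_load < 0)) stop("heat_load must be >= 0")
  if (!all(records$parity %in% spec$parities))
    stop("records contain parities outside the model spec; run ",
         "validateTestDayRecords() first")

  P <- length(spec$parities)
  par <- match(records$parity, spec$parities)        # 1..P
  htdLab <- interaction(records$herd, records$test_date, records$parity,
                        drop = TRUE, sep = ":")
  htd <- as.integer(htdLab)
  dcl <- dimClass(records$dim, spec)
  # drop first observed class per parity (baseline -> 0)
  dimLab <- if (length(par)) paste0("p", par, ":c", dcl) else character(0)
  base <- if (length(dimLab))
    vapply(split(dimLab, par), function(x) sort(unique(x))[1], character(1))
  else character(0)
  dimLab[dimLab %in% base] <- NA
  dimLev <- sort(unique(stats::na.omit(dimLab)))
  dimcl <- ifelse(is.na(dimLab), 0L, match(dimLab, dimLev))

  cows <- sort(unique(records$cow))
  structure(list(
    y = as.numeric(records$yield),
    parity = as.integer(par),
    f = as.numeric(records$heat_load),
    htd = htd, htdLevels = levels(htdLab),
    dimcl = as.integer(dimcl), dimLevels = dimLev, dimBaseline = unname(base),
    animal = match(records$cow, animalIds(ped)),
    cow = match(records$cow, cows), cowIds = cows,
    nParities = P, ped = ped, spec = spec,
    records = records
  ), class = "rrmDesign")
}
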