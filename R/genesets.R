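#' Read gene annotation intervals
#'
#' Accepts either a native 1-based inclusive TSV (columns `gene`, `chr`,
#' `start`, `end`, optional `strand`) or 0-based half-open BED (`dialect =
#' "bed"`, converted to 1-based inclusive on ingest).
#'
#' @param path file path.
#' @param dialect `"native"` (1-based inclusive) or `"bed"` (0-based
#'   half-open, first four columns chrom/start/end/name).
#' @return data.frame with columns `gene`, `chr`, `start`, `end`, `strand`.
#' @export
readGeneAnnotation <- function(path, dialect = c("native", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    b <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    ann <- data.frame(gene = as.character(b[[4]]), chr = as.character(b[[1]]),
                      start = b[[2]] + 1L, end = b[[3]],
                      strand = if (ncol(b) >= 6) b[[6]] else "*",
                      stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (is.null(ann$strand)) ann$strand <- "*"
    ann <- ann[, c("gene", "chr", "start", "end", "strand")]
  }
  if (any(ann$start > ann$end)) stop("gene intervals with start > end")
  if (any(ann$start <= 0)) stop("coordinates must be positive (1-based)")
  ann
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Assign SNPs to genes within a flanking distance
#'
#' A SNP is assigned to every gene whose interval, extended by `flank` bp on
#' both sides (strand-agnostic, boundaries inclusive), contains its
#' position; one SNP may map to several genes. Overlap is computed with
#' GenomicRanges.
#'
#' @param map SNP map data.frame (`snp`, `chr`, `pos`).
#' @param ann gene annotation data.frame from [readGeneAnnotation()].
#' @param flank flanking distance in bp (default 15000).
#' @return list with `assignments` (data.frame `snp`, `gene`), `unassigned`
#'   (SNP ids hitting no gene) and `genes` (genes with >= 1 assigned SNP).
#' @export
assignSnpsToGenes <- function(map, ann, flank = 15000) {
  snps <- GenomicRanges::GRanges(map$chr,
                                 IRanges::IRanges(map$pos, width = 1))
  genes <- GenomicRanges::GRanges(
    ann$chr, IRanges::IRanges(pmax(1L, ann$start - flank), ann$end + flank))
  hits <- GenomicRanges::findOverlaps(snps, genes, ignore.strand = TRUE)
  assignments <- data.frame(
    snp = map$snp[S4Vectors::queryHits(hits)],
    gene = ann$gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  list(assignments = assignments,
       unassigned = setdiff(map$snp, assignments$snp),
       genes = unique(assignments$gene))
}

#' Flag candidate thermotolerance genes from SNP-effect tracks
#'
#' Per parity, the relevant SNPs are those whose absolute effect reaches the
#' top `topFraction` of that parity's effect distribution (empirical order
#' statistic; ties at the boundary are included, so equal-magnitude effects
#' are never silently dropped). A gene is a candidate when it contains at
#' least one relevant SNP in at least `minParities` parities.
#'
#' @param tracks list of `snpEffectTrack`s (one per parity, shared SNP map);
#'   conventionally the thermotolerance (slope) tracks.
#' @param assignments SNP-to-gene data.frame from [assignSnpsToGenes()].
#' @param topFraction fraction of the distribution flagged (default 0.05).
#' @param minParities minimum parities in which a gene must be hit
#'   (default 2).
#' @return list with `candidates` (gene ids), `relevantSnps` (list per
#'   parity) and `threshold` (per-parity cutoffs).
#' @export
flagCandidateGenes <- function(tracks, assignments, topFraction = 0.05,
                               minParities = 2) {
  if (!length(tracks)) stop("no effect tracks supplied")
  for (t in tracks) if (!nrow(t)) stop("empty effect track")
  thr <- numeric(length(tracks))
  rel <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    a <- abs(tracks[[k]]$effect)
    nTop <- max(1L, ceiling(topFraction * length(a)))
    thr[k] <- sort(a, decreasing = TRUE)[nTop]
    rel[[k]] <- tracks[[k]]$snp[a >= thr[k]]
  }
  hitGenes <- lapply(rel, function(snps)
    unique(assignments$gene[assignments$snp %in% snps]))
  cnt <- table(unlist(hitGenes))
  list(candidates = sort(names(cnt)[cnt >= minParities]),
       relevantSnps = rel, threshold = thr)
}

#' Gene-set enrichment by Fisher's exact (hypergeometric) test
#'
#' For each set: upper-tail hypergeometric probability of observing at least
#' the seen overlap between the candidate genes and the set, within the gene
#' universe. The universe defaults to all genes carrying at least one
#' assigned SNP. Results are sorted by p; a Benjamini-Hochberg FDR column is
#' appended for reference but the headline significance call is the
#' uncorrected `p <= 0.05`.
#'
#' @param candidates character vector of candidate gene ids.
#' @param collection named list of gene sets (see [readGmt()]).
#' @param universe gene universe; candidate genes and all set members are
#'   required to be inside it (strays are an error for candidates; set
#'   members outside the universe are dropped with a count).
#' @return data.frame: `set`, `overlap`, `set_size`, `n_candidates`,
#'   `universe_size`, `p`, `fdr`, `dropped_outside_universe`.
#' @export
fisherEnrichment <- function(candidates, collection, universe) {
  candidates <- unique(as.character(candidates))
  universe <- unique(as.character(universe))
  stray <- setdiff(candidates, universe)
  if (length(stray))
    stop("candidates outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "))
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(names(collection), function(nm) {
    full <- unique(as.character(collection[[nm]]))
    set <- intersect(full, universe)
    K <- length(set)
    k <- length(intersect(set, candidates))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, n_candidates = n,
               universe_size = N, p = p,
               dropped_outside_universe = length(full) - K,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out[, c("set", "overlap", "set_size", "n_candidates", "universe_size",
          "p", "fdr", "dropped_outside_universe")]
}
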