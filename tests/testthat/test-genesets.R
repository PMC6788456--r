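test_that("SNP-to-gene assignment is inclusive at the 15 kb flank", {
  ann <- data.frame(gene = "g1", chr = "1", start = 100000, end = 120000,
                    strand = "+", stringsAsFactors = FALSE)
  map <- data.frame(snp = c("in", "edgeL", "outL", "edgeR", "outR"),
                    chr = "1",
                    pos = c(110000, 85000, 84999, 135000, 135001),
                    stringsAsFactors = FALSE)
  asg <- assignSnpsToGenes(map, ann, flank = 15000)
  expect_setequal(asg$assignments$snp, c("in", "edgeL", "edgeR"))
  expect_setequal(asg$unassigned, c("outL", "outR"))
})

test_that("assignment equals an exhaustive interval scan, multi-gene", {
  set.seed(17)
  ann <- data.frame(gene = paste0("g", 1:5), chr = sample(c("1", "2"), 5, TRUE),
                    start = sample.int(9e5, 5), stringsAsFactors = FALSE)
  ann$end <- ann$start + sample.int(2e5, 5)
  ann$strand <- "+"
  map <- data.frame(snp = paste0("s", 1:50),
                    chr = sample(c("1", "2"), 50, TRUE),
                    pos = sample.int(1.2e6, 50), stringsAsFactors = FALSE)
  asg <- assignSnpsToGenes(map, ann, flank = 15000)
  got <- asg$assignments[order(asg$assignments$snp, asg$assignments$gene), ]
  brute <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    hit <- which(ann$chr == map$chr[i] &
                 map$pos[i] >= ann$start - 15000 &
                 map$pos[i] <= ann$end + 15000)
    if (length(hit))
      data.frame(snp = map$snp[i], gene = ann$gene[hit],
                 stringsAsFactors = FALSE)
  }))
  brute <- brute[order(brute$snp, brute$gene), ]
  expect_equal(got$snp, brute$snp)
  expect_equal(got$gene, brute$gene)
})

test_that("BED ingest converts 0-based half-open to 1-based inclusive", {
  f <- tempfile(fileext = ".bed")
  writeLines("1\t99\t200\tgeneA\t0\t+", f)
  ann <- readGeneAnnotation(f, dialect = "bed")
  expect_equal(ann$start, 100)
  expect_equal(ann$end, 200)
  expect_equal(ann$gene, "geneA")
})

mkTrack <- function(effects) {
  structure(data.frame(snp = paste0("s", seq_along(effects)), chr = "1",
                       pos = seq_along(effects) * 1000, effect = effects),
            class = c("snpEffectTrack", "data.frame"))
}

test_that("top-5 percent flagging picks exactly the largest effects", {
  set.seed(27)
  eff <- sample(seq(0.01, 1, length.out = 100))   # distinct magnitudes
  tracks <- list(mkTrack(eff), mkTrack(sample(eff)), mkTrack(sample(eff)))
  asg <- data.frame(snp = paste0("s", 1:100),
                    gene = rep(paste0("g", 1:20), each = 5),
                    stringsAsFactors = FALSE)
  fc <- flagCandidateGenes(tracks, asg, topFraction = 0.05, minParities = 2)
  for (k in 1:3) {
    expect_length(fc$relevantSnps[[k]], 5L)
    expect_setequal(fc$relevantSnps[[k]],
                    tracks[[k]]$snp[order(-abs(tracks[[k]]$effect))[1:5]])
  }
})

test_that("a gene needs relevant SNPs in at least two parities", {
  # 20 SNPs, 4 genes of 5 SNPs; parity k flags s1 (gene g1) and s<k+5>
  base <- rep(0.01, 20)
  t1 <- base; t1[1] <- 1; t1[6] <- 0.9    # flags g1, g2
  t2 <- base; t2[1] <- 1; t2[11] <- 0.9   # flags g1, g3
  t3 <- base; t3[16] <- 1; t3[17] <- 0.9  # flags g4 only
  asg <- data.frame(snp = paste0("s", 1:20),
                    gene = rep(paste0("g", 1:4), each = 5),
                    stringsAsFactors = FALSE)
  fc <- flagCandidateGenes(list(mkTrack(t1), mkTrack(t2), mkTrack(t3)),
                           asg, topFraction = 0.1, minParities = 2)
  expect_equal(fc$candidates, "g1")
  # brute-force rule application over all genes and parities agrees
  rel <- lapply(list(t1, t2, t3), function(tt) {
    thr <- sort(abs(tt), decreasing = TRUE)[2]
    paste0("s", which(abs(tt) >= thr))
  })
  hits <- sapply(paste0("g", 1:4), function(g) {
    snps <- asg$snp[asg$gene == g]
    sum(vapply(rel, function(r) any(r %in% snps), logical(1)))
  })
  expect_equal(fc$candidates, names(hits)[hits >= 2])
})

test_that("flagging is monotone in the top fraction", {
  set.seed(29)
  tracks <- lapply(1:3, function(i) mkTrack(rnorm(60)))
  asg <- data.frame(snp = paste0("s", 1:60),
                    gene = rep(paste0("g", 1:12), each = 5),
                    stringsAsFactors = FALSE)
  prev <- character(0)
  for (tf in c(0.02, 0.05, 0.1, 0.25)) {
    cur <- flagCandidateGenes(tracks, asg, topFraction = tf,
                              minParities = 2)$candidates
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("enrichment p-values match hypergeometric enumeration", {
  universe <- paste0("g", 1:20)
  sets <- list(small = paste0("g", 1:5))
  cand <- paste0("g", c(1, 2, 3, 9, 12, 18))   # overlap 3 of 6
  res <- fisherEnrichment(cand, sets, universe)
  expect_equal(res$p, 5090 / 38760, tolerance = 1e-12)
  expect_equal(res$p, oracleHyperTail(3, 5, 20, 6), tolerance = 1e-12)

  u4 <- paste0("g", 1:4)
  res2 <- fisherEnrichment(c("g1", "g2"), list(s = c("g1", "g2")), u4)
  expect_equal(res2$p, 1 / 6, tolerance = 1e-12)

  # degenerate: no candidates
  res3 <- fisherEnrichment(character(0), list(s = c("g1", "g2")), u4)
  expect_equal(res3$p, 1)
})

test_that("enrichment is invariant to relabelling genes", {
  set.seed(35)
  universe <- paste0("g", 1:50)
  sets <- list(a = sample(universe, 10), b = sample(universe, 20))
  cand <- sample(universe, 12)
  res1 <- fisherEnrichment(cand, sets, universe)
  perm <- stats::setNames(sample(universe), universe)
  res2 <- fisherEnrichment(unname(perm[cand]),
                           lapply(sets, function(s) unname(perm[s])),
                           unname(perm[universe]))
  expect_equal(res1$p, res2$p)
})

test_that("candidates outside the universe are an error; GMT round-trips", {
  expect_error(fisherEnrichment("zz", list(s = "g1"), paste0("g", 1:3)),
               "zz")
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), f)
  sets <- readGmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("g2", "g4"))
})
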