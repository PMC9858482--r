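test_that("binarization collapses multi-hit genes and is idempotent", {
  mt <- data.frame(
    sample_id = c("s1", "s1", "s2", "s3"),
    gene_id = c("TP53", "TP53", "TP53", "PIK3CA"),
    variant_classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Silent", "Missense_Mutation"))
  m <- binarizeMutations(mt, samples = paste0("s", 1:4))
  expect_equal(m["TP53", ], c(s1 = 1L, s2 = 0L, s3 = 0L, s4 = 0L))
  expect_equal(m["PIK3CA", "s3"], 1L)
  expect_true(all(m %in% 0:1))
  expect_equal((m > 0) * 1L, m)   # binarize . binarize = binarize

  expect_warning(z <- binarizeMutations(mt[0, ], samples = paste0("s", 1:3)),
                 "all-zero")
  expect_equal(dim(z), c(0L, 3L))
})

test_that("binarization matches a direct counting oracle on random tables", {
  set.seed(71)
  samples <- sprintf("s%02d", 1:15)
  genes <- sprintf("G%02d", 1:10)
  mt <- data.frame(
    sample_id = sample(samples, 120, replace = TRUE),
    gene_id = sample(genes, 120, replace = TRUE),
    variant_classification = sample(c("Missense_Mutation", "Silent"), 120,
                                    replace = TRUE))
  m <- binarizeMutations(mt, samples = samples)
  for (g in rownames(m)) {
    for (s in samples) {
      hit <- any(mt$gene_id == g & mt$sample_id == s &
                   mt$variant_classification == "Missense_Mutation")
      expect_identical(m[g, s] == 1L, hit)
    }
  }
})

test_that("frequency filter is strictly greater-than", {
  m <- matrix(0L, 3, 100, dimnames = list(c("gA", "gB", "gC"),
                                          sprintf("s%03d", 1:100)))
  m["gA", 1:2] <- 1L   # 2%
  m["gB", 1] <- 1L     # exactly 1%
  expect_identical(filterByFrequency(m, 0.01), "gA")
  expect_error(filterByFrequency(m, 0), "in \\(0, 1\\)")
})

test_that("chi-square specificity matches the closed-form 2x2 oracle", {
  st <- stats::setNames(factor(rep(c("A", "B"), each = 10)),
                        sprintf("s%02d", 1:20))
  m <- matrix(0L, 2, 20, dimnames = list(c("biased", "uniform"), names(st)))
  m["biased", st == "A"] <- 1L            # 10/10 in A, 0/10 in B
  m["uniform", c(1:5, 11:15)] <- 1L       # identical rate in both subtypes
  res <- subtypeSpecificMutations(m, st, fdrThreshold = 0.01)
  rb <- res[res$gene == "biased", ]
  expect_equal(rb$chi2, 20)               # no continuity correction
  expect_equal(rb$p, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(rb$p, 1e-5)
  ru <- res[res$gene == "uniform", ]
  expect_equal(ru$chi2, 0)
  expect_equal(ru$p, 1)
  expect_true(rb$specific && !ru$specific)
})

test_that("degenerate genes are excluded and order does not matter", {
  st <- stats::setNames(factor(rep(c("A", "B", "C"), each = 8)),
                        sprintf("s%02d", 1:24))
  set.seed(72)
  m <- matrix(stats::rbinom(5 * 24, 1, 0.3), 5, 24,
              dimnames = list(paste0("g", 1:5), names(st)))
  m["g4", ] <- 0L
  m["g5", ] <- 1L
  res <- subtypeSpecificMutations(m, st)
  expect_false(any(c("g4", "g5") %in% res$gene))

  shuffled <- subtypeSpecificMutations(
    m[sample(nrow(m)), sample(ncol(m))], st)
  expect_equal(shuffled[order(shuffled$gene),
                        c("gene", "chi2", "p", "fdr")],
               res[order(res$gene), c("gene", "chi2", "p", "fdr")],
               tolerance = 1e-12)
  # FDR is monotone in p
  expect_true(all(diff(res$fdr[order(res$p)]) >= -1e-12))
})

test_that("CNV amp and del analyses are directional and independent", {
  st <- stats::setNames(factor(rep(c("A", "B"), each = 12)),
                        sprintf("s%02d", 1:24))
  cnv <- matrix(0L, 2, 24, dimnames = list(c("ampGene", "quiet"), names(st)))
  cnv["ampGene", st == "A"] <- rep(c(1L, 2L), 6)  # amplified only in A
  res <- subtypeSpecificCnv(cnv, st, fdrThreshold = 0.01)
  expect_true("ampGene" %in% res$amp$gene[res$amp$specific])
  expect_false("ampGene" %in% res$del$gene)

  allNeutral <- matrix(0L, 2, 24,
                       dimnames = list(c("x", "y"), names(st)))
  res0 <- subtypeSpecificCnv(allNeutral, st)
  expect_equal(nrow(res0$amp), 0)
  expect_equal(nrow(res0$del), 0)

  # high-level restriction drops single-copy events
  cnv2 <- cnv
  cnv2["ampGene", st == "A"] <- 1L
  res2 <- subtypeSpecificCnv(cnv2, st, highLevelOnly = TRUE)
  expect_equal(nrow(res2$amp), 0)
})

test_that("mixed planted amp and del genes agree with a contingency oracle", {
  set.seed(73)
  st <- stats::setNames(factor(rep(c("A", "B", "C"), times = c(20, 30, 25))),
                        sprintf("s%03d", 1:75))
  genes <- paste0("g", 1:6)
  amp <- matrix(0.05, 6, 3, dimnames = list(genes, levels(st)))
  del <- matrix(0.05, 6, 3, dimnames = list(genes, levels(st)))
  amp["g1", "A"] <- 0.8
  del["g2", "B"] <- 0.8
  syn <- generateCohort(cohortConfig(
    nPerSubtype = c(A = 20, B = 30, C = 25), nGenes = 150,
    cells = data.frame(name = "c1", n_markers = 10, lineage = "other"),
    cnvSpec = list(amp = amp, del = del), seed = 74))
  cnv <- cnvMatrix(syn$cohort)
  res <- subtypeSpecificCnv(cnv, subtypes(syn$cohort))
  expect_true("g1" %in% res$amp$gene[res$amp$specific])
  expect_true("g2" %in% res$del$gene[res$del$specific])
  # brute-force chi-square recomputation for one gene
  g1amp <- (cnv["g1", ] > 0) * 1L
  tab <- table(factor(g1amp, levels = c(1, 0)), subtypes(syn$cohort))
  oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  r1 <- res$amp[res$amp$gene == "g1", ]
  expect_equal(r1$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(r1$p, oracle$p.value, tolerance = 1e-10)
})
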