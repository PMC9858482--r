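test_that("MHC score is zero for identical samples and matches hand centering", {
  m <- matrix(rep(c(4, 7, 2), 3), 3, 3,
              dimnames = list(c("HLA-A", "HLA-B", "B2M"), paste0("p", 1:3)))
  expect_equal(unname(mhcScore(m, coreSet = rownames(m))), c(0, 0, 0))

  # post-log values geneA = (1,2,3), geneB = (0,2,4) -> scores (-1.5, 0, 1.5)
  v <- rbind(geneA = c(1, 2, 3), geneB = c(0, 2, 4))
  colnames(v) <- paste0("p", 1:3)
  sc <- mhcScore(2^v - 1, coreSet = c("geneA", "geneB"))
  expect_equal(unname(sc), c(-1.5, 0, 1.5), tolerance = 1e-12)
  # per-gene centered medians are exactly zero
  centered <- log2((2^v - 1) + 1) - apply(v, 1, stats::median)
  expect_equal(unname(apply(centered, 1, stats::median)), c(0, 0))
})

test_that("MHC score enforces its expected FPKM input scale", {
  m <- randExpr(12, 4, seed = 21)
  rownames(m)[1:2] <- c("HLA-A", "B2M")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = abs(m)), metadata = list(scale = "log2p1"))
  expect_error(mhcScore(se, coreSet = c("HLA-A", "B2M")), "FPKM")
  expect_silent(mhcScore(se, coreSet = c("HLA-A", "B2M"),
                         logTransform = FALSE))
  expect_error(mhcScore(m[, 1, drop = FALSE], coreSet = "HLA-A"), "2 samples")
})

test_that("bundled core MHC set carries the nine class I genes", {
  gs <- bundledGeneSets("mhc_core")
  expect_setequal(gs[[1]], c("HLA-A", "HLA-B", "HLA-C", "TAP1", "TAP2",
                             "NLRC5", "PSMB9", "PSMB8", "B2M"))
})

test_that("GEP score responds to planted inflammation and is reproducible", {
  gep <- bundledGeneSets("gep18")[[1]]
  expect_length(gep, 18)
  set.seed(22)
  genes <- c(gep, sprintf("bg%03d", 1:150))
  m <- matrix(stats::rnorm(length(genes) * 10, 5), length(genes), 10,
              dimnames = list(genes, paste0("s", 1:10)))
  m[gep, "s4"] <- m[gep, "s4"] + 6   # strongly inflame one sample
  sc <- gepScore(m)
  expect_identical(names(which.max(sc)), "s4")

  m2 <- cbind(m, s11 = m[, "s1"])    # identical sample, identical score
  sc2 <- gepScore(m2)
  expect_equal(unname(sc2["s11"]), unname(sc2["s1"]))
})

test_that("TMB counts non-silent variants per megabase", {
  mt <- data.frame(
    sample_id = c("s1", "s1", "s1", "s1", "s1", "s2"),
    gene_id = paste0("g", 1:6),
    variant_classification = c("Silent", "Silent", "Silent",
                               "Missense_Mutation", "Missense_Mutation",
                               "Nonsense_Mutation"))
  tmb <- tmbScore(mt, codingMb = 1)
  expect_equal(unname(tmb["s1"]), 2)          # 3 silent + 2 missense -> 2
  tmb38 <- tmbScore(data.frame(
    sample_id = "s1", gene_id = paste0("g", 1:38),
    variant_classification = "Missense_Mutation"), codingMb = 38)
  expect_equal(unname(tmb38), 1)
  # samples with no variants are zero within a declared universe
  expect_equal(unname(tmbScore(mt, codingMb = 1,
                               samples = c("s1", "s2", "s3"))["s3"]), 0)
  # invariant to row order
  expect_equal(tmbScore(mt[sample(nrow(mt)), ], codingMb = 1), tmb)
})

test_that("unknown variant classes error unless lenient", {
  mt <- data.frame(sample_id = "s1", gene_id = "g1",
                   variant_classification = "Weird_Class")
  expect_error(tmbScore(mt), "Weird_Class")
  expect_message(tmb <- tmbScore(mt, lenient = TRUE), "dropped")
  expect_equal(unname(tmb), 0)
})

test_that("ESTIMATE-style scores are additive with a monotone purity transform", {
  set.seed(23)
  std <- bundledGeneSets("estimate_synthetic")
  genes <- c(std[["immune_signature"]], std[["stromal_signature"]],
             sprintf("bg%03d", 1:100))
  m <- matrix(stats::rnorm(length(genes) * 12, 5), length(genes), 12,
              dimnames = list(genes, sprintf("s%02d", 1:12)))
  hot <- sprintf("s%02d", 1:4)
  m[std[["immune_signature"]], hot] <- m[std[["immune_signature"]], hot] + 4
  es <- suppressMessages(estimateScores(m))
  expect_equal(es$estimate_score, es$immune_score + es$stromal_score)
  expect_true(all(es$tumor_purity >= 0 & es$tumor_purity <= 1))
  # planted immune expression raises the immune ranking of those samples
  expect_true(all(rank(-es$immune_score)[es$sample_id %in% hot] <= 4))
  # purity decreases with the estimate score over the calibrated range
  ord <- order(es$estimate_score)
  inRange <- !es$purity_out_of_range[ord]
  expect_true(all(diff(es$tumor_purity[ord][inRange]) <= 1e-12))
})

test_that("signature panel has 8 sets and composes from per-set scoring", {
  panel <- bundledGeneSets("tme_panel")
  expect_length(panel, 8)
  set.seed(24)
  genes <- unique(c(unlist(as.list(panel)), sprintf("bg%03d", 1:80)))
  m <- matrix(stats::rnorm(length(genes) * 6, 5), length(genes), 6,
              dimnames = list(genes, paste0("s", 1:6)))
  sc <- signaturePanel(m)
  expect_identical(rownames(sc), names(panel))
  for (nm in names(panel)) {
    single <- ssgseaScores(m, panel[nm])
    expect_equal(sc[nm, ], single[1, ], tolerance = 1e-12)
  }
  mConst <- matrix(rep(m[, 1], 3), nrow(m), 3,
                   dimnames = list(rownames(m), paste0("c", 1:3)))
  scc <- signaturePanel(mConst)
  expect_true(all(scc == scc[, 1]))
})
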