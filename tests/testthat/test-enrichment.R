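test_that("median-of-ratios size factors match hand computations", {
  # identical samples
  m <- matrix(c(5L, 10L, 20L, 5L, 10L, 20L), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(compute_size_factors(m), c(a = 1, b = 1))
  # sample b = 2 x sample a: ratios to the geometric mean are 1/sqrt(2)
  # and sqrt(2), already geometric-mean-1
  m2 <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
               dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(compute_size_factors(m2),
               c(a = 1 / sqrt(2), b = sqrt(2)))
  # genes containing any zero are excluded from the median: g3's wild
  # ratio is ignored because g4 has a zero... construct explicitly
  m3 <- matrix(c(10L, 10L, 0L, 10L, 10L, 1000L), ncol = 2,
               dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(compute_size_factors(m3), c(a = 1, b = 1))
})

test_that("size factors agree with DESeq2's median-of-ratios estimator", {
  set.seed(7)
  m <- matrix(rnbinom(600, mu = 200, size = 10), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:100), letters[1:6]))
  sf <- compute_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(sf), unname(ref), tolerance = 1e-12)
})

test_that("degenerate matrices error with a pseudo-reference escape hatch", {
  m <- matrix(c(0L, 5L, 3L, 0L), ncol = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(compute_size_factors(m), "pseudo_reference")
  sf <- compute_size_factors(m, pseudo_reference = TRUE)
  expect_length(sf, 2L)
  expect_true(all(sf > 0))
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("normalization invariances hold", {
  set.seed(11)
  m <- matrix(rpois(300, 500), ncol = 3,
              dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  sf <- compute_size_factors(m)
  norm <- normalize_counts(m, sf)
  # s = (1,1,...) is the identity
  expect_equal(normalize_counts(m, rep(1, 3)), m + 0)
  # scaling one sample by c scales its factor by c (up to the global
  # geometric-mean rescale) and leaves normalized counts unchanged
  m2 <- m
  m2[, 2] <- m2[, 2] * 5L
  sf2 <- compute_size_factors(m2)
  rescale <- 5^(1 / 3)  # geometric-mean renormalization constant
  expect_equal(sf2, sf * c(1, 5, 1) / rescale, tolerance = 1e-9)
  expect_equal(normalize_counts(m2, sf2) / rescale, norm,
               tolerance = 1e-9)
  # mean read count
  mm <- matrix(c(100, 300), ncol = 2,
               dimnames = list("g1", c("a", "b")))
  expect_equal(unname(mean_read_count(normalize_counts(mm, c(1, 1)))),
               200)
})

test_that("enrichment score follows its ratio definition with pseudocount", {
  es <- function(pd, inp, eps = 0.5) (pd + eps) / (inp + eps)
  expect_equal(es(1000, 1000), 1.0)
  expect_equal(es(4000, 1000), 4000.5 / 1000.5)
  expect_equal(es(10, 0), 21.0)
  # through the full object path
  x <- make_toy_counts()
  x$counts[1, ] <- 0L
  x$counts[1, "untreated_G4RP_1"] <- 10L
  x$counts[1, "untreated_G4RP_2"] <- 10L
  out <- enrichment_score(x, "untreated", size_factors = rep(1, 9))
  expect_equal(unname(out["g01"]), 21.0)
  expect_equal(unname(out["g02"]), 1.0)
  expect_error(enrichment_score(x, "missing-condition"), "input")
})

test_that("dES boundary is strict and NA propagates", {
  expect_equal(enrichment_score_change(3.5, 2.0), 1.75)
  expect_equal(enrichment_score_change(4.0, 2.0), 2.0)
  expect_true(is.na(enrichment_score_change(1, 0)))
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    mean_read_count = c(600, 600, 600),
                    es.untreated = c(2, 2, 2),
                    `des.BRACO-19` = c(1.75, 2.0, NA),
                    check.names = FALSE)
  out <- filter_and_rank(tab)
  expect_equal(out[["induced.BRACO-19"]], c(FALSE, TRUE, FALSE))
})

test_that("filters and ranks follow the landscape rules", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    mean_read_count = c(600, 40, 900, 50),
                    es.untreated = c(3, 2, 3, 1),
                    `des.BRACO-19` = c(2.0, 1.8, 1.2, 2.0),
                    check.names = FALSE)
  out <- filter_and_rank(tab)
  # mean read count exactly 50 is NOT expressed (strict >)
  expect_equal(out$expressed, c(TRUE, FALSE, TRUE, FALSE))
  # abundance defaults to >= 500
  expect_equal(out$abundant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(filter_and_rank(tab, strict_abundance = TRUE)$abundant,
               c(TRUE, FALSE, TRUE, FALSE))
  # induced: expressed and dES > 1.75; g2 fails expression, g3 fails dES
  expect_equal(out[["induced.BRACO-19"]], c(TRUE, FALSE, FALSE, FALSE))
  # ES ties broken by gene id; non-expressed genes carry NA ranks
  expect_equal(out$rank_es.untreated, c(1L, NA, 2L, NA))
  expect_equal(out[["rank_des.BRACO-19"]], c(1L, NA, 2L, NA))
  # ranks are a permutation of the expressed genes
  r <- out$rank_es.untreated
  expect_setequal(r[!is.na(r)], seq_len(sum(out$expressed)))
})

test_that("abundance boundary: >= 500 by default, > 500 when strict", {
  tab <- data.frame(gene_id = "g1", mean_read_count = 500,
                    es.untreated = 1)
  expect_true(filter_and_rank(tab)$abundant)
  expect_false(filter_and_rank(tab, strict_abundance = TRUE)$abundant)
})

test_that("enrichment_table computes ES/dES per condition on a known matrix", {
  x <- make_toy_counts()
  # g01: pulldown doubled under BRACO-19 only
  x$counts[1, "BRACO-19_G4RP_1"] <- 200L
  x$counts[1, "BRACO-19_G4RP_2"] <- 200L
  tab <- enrichment_table(x, size_factors = rep(1, 9))
  g1 <- tab[tab$gene_id == "g01", ]
  expect_equal(g1$es.untreated, 1.0)
  expect_equal(g1[["es.BRACO-19"]], 200.5 / 100.5)
  expect_equal(g1[["des.BRACO-19"]], 200.5 / 100.5)
  expect_equal(g1[["des.RHPS4"]], 1.0)
  # pulldown_ratio variant ignores inputs
  tab2 <- enrichment_table(x, size_factors = rep(1, 9),
                           des_mode = "pulldown_ratio")
  expect_equal(tab2[tab2$gene_id == "g01", "des.BRACO-19"], 200.5 / 100.5)
  # missing input for a condition aborts
  keep <- x$samples$sample_id != "RHPS4_input_1"
  expect_error(
    g4rp_counts(x$counts[, x$samples$sample_id[keep]],
                x$samples[keep, ]),
    "RHPS4")
})

test_that("ES is invariant to rescaling one library (scale invariance)", {
  cfg <- simulation_config(n_transcripts = 300L,
                           length_range = c(300L, 800L),
                           expression_log_mean = 7, seed = 23L)
  sim <- simulate_g4rp_counts(simulate_transcriptome(cfg))
  x <- sim$counts
  tab <- enrichment_table(x)
  x2 <- x
  x2$counts[, "untreated_G4RP_1"] <- x2$counts[, "untreated_G4RP_1"] * 4L
  tab2 <- enrichment_table(x2)
  hi <- tab$mean_read_count >= 500
  rel <- abs(tab2$es.untreated[hi] - tab$es.untreated[hi]) /
    tab$es.untreated[hi]
  expect_lt(max(rel), 1e-3)
})

test_that("top_genes returns rank-ordered abundant genes", {
  tab <- data.frame(gene_id = paste0("g", 1:6),
                    mean_read_count = c(600, 600, 600, 600, 100, 600),
                    es.untreated = c(5, 4, 3, 2, 10, 1))
  out <- filter_and_rank(tab)
  class(out) <- c("g4rp_enrichment", "data.frame")
  expect_equal(top_genes(out, "rank_es.untreated", k = 3),
               c("g1", "g2", "g3"))
  expect_equal(top_genes(out, "rank_es.untreated", k = 3,
                         abundant_only = FALSE),
               c("g5", "g1", "g2"))
})
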