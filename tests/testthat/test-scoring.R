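test_that("log-normalization implements ln(1 + scale * proportion)", {
  counts <- matrix(c(1, 1, 2), 3, 1,
                   dimnames = list(c("A", "B", "C"), "u1"))
  out <- logNormalize(counts, scale = 1e4)
  expect_equal(as.numeric(out),
               c(log(2501), log(2501), log(5001)))
  # proportions only: doubling counts changes nothing
  expect_equal(logNormalize(2 * counts), out)
  z <- cbind(counts, u2 = c(0, 0, 0))
  expect_warning(out2 <- logNormalize(z), "zero total")
  expect_equal(unname(out2[, "u2"]), c(0, 0, 0))
  expect_error(logNormalize(counts - 5), "negative")
})

test_that("bulk normalization z-scores per gene after log2", {
  expr <- matrix(c(1, 3, 7, 5, 5, 5), 2, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  z <- bulkNormalize(expr)
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 0))  # constant gene -> 0
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_error(bulkNormalize(expr[, 1, drop = FALSE]), "two samples")
})

test_that("the 4-gene hand example scores +2 / -2", {
  expr <- matrix(c(4, 3, 2, 1), 4, 1,
                 dimnames = list(paste0("G", 1:4), "u"))
  coll <- GeneSetCollection(list(GeneSet("top", "G1"),
                                 GeneSet("bottom", "G4")))
  es <- ssgseaScore(expr, coll, alpha = 0.25)
  expect_equal(es["top", "u"], 2.0)
  expect_equal(es["bottom", "u"], -2.0)
})

test_that("scores match the brute-force walk oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    genes <- paste0("G", seq_len(50))
    expr <- matrix(rnorm(50 * 8), 50, 8,
                   dimnames = list(genes, paste0("u", 1:8)))
    size <- sample(3:10, 1)
    set_genes <- sample(genes, size)
    coll <- GeneSetCollection(GeneSet("S", set_genes))
    es <- ssgseaScore(expr, coll, alpha = 0.25)
    for (u in 1:8)
      expect_lt(abs(es["S", u] -
                    oracle_ssgsea_unit(expr[, u], set_genes)), 1e-10)
  }
})

test_that("scores are rank-invariant and gene-order invariant", {
  set.seed(7)
  genes <- paste0("G", 1:40)
  expr <- matrix(rexp(40 * 5), 40, 5,
                 dimnames = list(genes, paste0("u", 1:5)))
  coll <- GeneSetCollection(GeneSet("S", sample(genes, 6)))
  es <- ssgseaScore(expr, coll)
  cubed <- expr
  cubed[, 2] <- cubed[, 2]^3   # strictly increasing transform
  expect_equal(ssgseaScore(cubed, coll), es)
  perm <- sample(nrow(expr))
  expect_equal(ssgseaScore(expr[perm, ], coll), es)
})

test_that("random-set null: unweighted walk is centred, weighted bias is real", {
  set.seed(3)
  genes <- paste0("G", 1:60)
  expr <- matrix(sample(60), 60, 1, dimnames = list(genes, "u"))
  n_sets <- 1000
  set_list <- lapply(seq_len(n_sets), function(i) sample(genes, 10))
  coll <- GeneSetCollection(lapply(seq_len(n_sets), function(i)
    GeneSet(paste0("R", i), set_list[[i]])))
  # alpha = 0 (uniform in-set weights): mean ES within 3 SE of 0
  es0 <- ssgseaScore(expr, coll, alpha = 0)
  expect_lt(abs(mean(es0)), 3 * sd(es0) / sqrt(n_sets))
  # the default rank-weighted walk has a positive null bias; it is a
  # property of the statistic, reproduced exactly by the oracle
  es <- ssgseaScore(expr, coll, alpha = 0.25)
  oracle_mean <- mean(vapply(set_list[1:50], function(g)
    oracle_ssgsea_unit(expr[, 1], g), numeric(1)))
  expect_equal(mean(es[1:50]), oracle_mean, tolerance = 1e-10)
})

test_that("degenerate inputs follow the documented conventions", {
  genes <- paste0("G", 1:5)
  tied <- matrix(1, 5, 2, dimnames = list(genes, c("u1", "u2")))
  coll <- GeneSetCollection(GeneSet("S", genes[1:2]))
  expect_equal(unname(ssgseaScore(tied, coll)), matrix(0, 1, 2))
  # set covering all genes: walk undefined
  expect_error(ssgseaScore(matrix(rnorm(10), 5, 2,
                                  dimnames = list(genes, NULL)),
                           GeneSetCollection(GeneSet("all", genes))),
               "every gene")
})

test_that("matrix-range normalization rescales by max - min", {
  set.seed(5)
  genes <- paste0("G", 1:30)
  expr <- matrix(rnorm(90), 30, 3, dimnames = list(genes, NULL))
  coll <- GeneSetCollection(list(GeneSet("a", genes[1:4]),
                                 GeneSet("b", genes[5:10])))
  raw <- ssgseaScore(expr, coll, normalize = FALSE)
  nrm <- ssgseaScore(expr, coll, normalize = TRUE)
  expect_equal(nrm, raw / (max(raw) - min(raw)))
})

test_that("derived indices follow their formulas with the S_In guard", {
  sc <- rbind(put_biosynthesis = c(u1 = 0.2, u2 = 0.5, u3 = 0),
              put_loss = c(0.1, 0.3, 0.2),
              put_transport = c(0.4, 0.6, 0.3))
  out <- derivePutIndices(sc)
  expect_equal(unname(out["S_extracellular", "u1"]), 0.4 / 0.2)
  expect_equal(unname(out["S_accumulation", "u2"]), 0.5 - 0.3)
  expect_true(is.na(out["S_extracellular", "u3"]))  # S_In <= 0 flagged
  expect_equal(unname(attr(out, "invalid_extracellular")),
               c(FALSE, FALSE, TRUE))
  expect_error(derivePutIndices(sc[1:2, ]), "must contain rows")
})
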