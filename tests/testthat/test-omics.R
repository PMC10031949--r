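test_that("planted effects are called with high recall and controlled FDR", {
  fdp <- recall <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_expression_matrix(1000, 8, 50, effect = 2, sigma = 0.5,
                                      seed = s)
    hits <- call_differential(sim, config = differential_call_config("bh_fdr",
                                                                     0.005))
    called <- attr(hits, "table")$called
    recall[s] <- mean(called[sim$truth])
    fdp[s] <- if (sum(called) == 0) 0 else sum(called & !sim$truth) / sum(called)
  }
  expect_gt(mean(recall), 0.9)
  expect_lte(mean(fdp), 0.05)
})

test_that("null matrices yield almost no BH calls", {
  false_calls <- vapply(1:50, function(s) {
    sim <- simulate_expression_matrix(500, 8, 0, effect = 0, sigma = 1, seed = s)
    nrow(call_differential(sim, config = differential_call_config("bh_fdr", 0.005)))
  }, numeric(1))
  expect_lte(mean(false_calls), 0.005 * 500)
})

test_that("an infinite fold-change floor empties the hit list", {
  sim <- simulate_expression_matrix(200, 6, 50, effect = 3, sigma = 0.5, seed = 1)
  cfg <- differential_call_config("bh_fdr", 0.01, lfc_threshold = Inf)
  expect_equal(nrow(call_differential(sim, config = cfg)), 0L)
})

test_that("zero-variance features are flagged and excluded from the family", {
  sim <- simulate_expression_matrix(100, 4, 10, effect = 2, sigma = 0.5, seed = 2)
  sim$x[7, ] <- 3  # constant feature
  hits <- call_differential(sim, config = differential_call_config("bh_fdr", 0.01))
  tabf <- attr(hits, "table")
  expect_true(tabf$degenerate[7])
  expect_true(is.na(tabf$p_adj[7]))
  expect_false(tabf$called[7])
})

test_that("exhaustive permutation p-values match brute-force enumeration", {
  sim <- simulate_expression_matrix(40, 3, 5, effect = 3, sigma = 0.5, seed = 4)
  padj <- permutation_fdr(sim$x, sim$group, seed = 1)
  p_perm <- attr(padj, "p_perm")
  # oracle: enumerate all choose(6,3) = 20 label assignments directly
  combos <- combn(6, 3)
  expect_equal(ncol(combos), 20L)
  welch_t <- function(x2, x1) {
    n1 <- ncol(x1); n2 <- ncol(x2)
    (rowMeans(x2) - rowMeans(x1)) /
      sqrt(apply(x1, 1, var) / n1 + apply(x2, 1, var) / n2)
  }
  obs <- abs(welch_t(sim$x[, 4:6], sim$x[, 1:3]))
  pool <- abs(as.vector(apply(combos, 2, function(ii)
    welch_t(sim$x[, ii, drop = FALSE], sim$x[, -ii, drop = FALSE]))))
  pool <- pool[is.finite(pool)]
  p_oracle <- unname(vapply(obs, function(t0) mean(pool >= t0), numeric(1)))
  expect_equal(unname(p_perm), p_oracle, tolerance = 1e-12)
})

test_that("a statistic equal to every permuted statistic gets p = 1", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)  # every relabeling, same spread
  # build a flat case: identical values in both groups
  x <- rbind(rep(c(1, 2), 3))
  g <- rep(c("a", "b"), each = 3)
  # symmetric data: observed |t| is the minimum of the pooled null
  padj <- permutation_fdr(rbind(c(1, 2, 1, 2, 1, 2)), rep(c("a", "b"), each = 3))
  expect_equal(attr(padj, "p_perm"), 1)
})

test_that("sampled permutation p-values are roughly uniform under the null", {
  sim <- simulate_expression_matrix(200, 8, 0, effect = 0, sigma = 1, seed = 6)
  padj <- permutation_fdr(sim$x, sim$group, n_perm = 200, seed = 3)
  expect_gte(mean(attr(padj, "p_perm")), 0.4)
  expect_gte(mean(padj, na.rm = TRUE), mean(attr(padj, "p_perm")))
  expect_error(permutation_fdr(sim$x, sim$group, n_perm = 50), ">= 100")
})

test_that("list intersection is exact set algebra", {
  mk <- function(ids) data.frame(molecule = ids, day = 1, modality = "mrna",
                                 log2fc = 1, direction = "up")
  disjoint <- list(mk(c("a", "b")), mk(c("c", "d", "e")))
  ov <- intersect_lists(disjoint)
  expect_equal(ov$intersection_size, 0L)
  expect_equal(ov$union_size, 5L)
  single <- intersect_lists(list(mk(c("a", "b", "b"))))
  expect_equal(single$union_size, 2L)  # duplicates count once
  expect_equal(single$intersection_size, 2L)
})

test_that("set algebra matches brute-force operations on random instances", {
  set.seed(99)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    idsets <- lapply(seq_len(k), function(j) sample(pool, sample(1:15, 1)))
    lists <- lapply(idsets, function(ids)
      data.frame(molecule = ids, day = 1, modality = "m", log2fc = 1,
                 direction = "up"))
    ov <- intersect_lists(lists)
    expect_equal(ov$union_size, length(unique(unlist(idsets))))
    expect_equal(sort(ov$members), sort(Reduce(intersect, idsets)))
    expect_lte(ov$intersection_size, min(lengths(idsets)))
    expect_true(isSymmetric(ov$pairwise))
    expect_equal(unname(diag(ov$pairwise)), lengths(idsets))
  }
})

test_that("cross-modality overlap harmonizes IDs and honors the map", {
  m <- data.frame(molecule = c("Tp53", "GADD45A", "CDKN1A"), day = 3,
                  modality = "mrna", log2fc = c(1, 2, -1))
  p <- data.frame(molecule = c("TP53", "XRCC4"), day = 3,
                  modality = "protein", log2fc = c(0.8, 1.2))
  ov <- cross_modality_overlap(m, p)
  expect_equal(ov$molecule, "TP53")  # case-folded symbol equality
  map <- data.frame(from = "XRCC4", to = "GADD45A")
  ov2 <- cross_modality_overlap(m, p, id_map = map)
  expect_setequal(ov2$molecule, c("TP53", "GADD45A"))
  # concordance restriction
  m2 <- data.frame(molecule = c("A", "B"), day = 3, modality = "mrna",
                   log2fc = c(1, -1))
  p2 <- data.frame(molecule = c("A", "B"), day = 3, modality = "protein",
                   log2fc = c(1, 1))
  expect_equal(cross_modality_overlap(m2, p2, concordant = TRUE)$molecule, "A")
  expect_error(cross_modality_overlap(m, transform(p, day = 7)), "same single day")
  # empty protein list gives an empty overlap
  expect_equal(nrow(cross_modality_overlap(m, p[0, ])), 0L)
})

test_that("the time-correlation filter applies the Pearson cutoff per modality", {
  mk <- function(mol, mod, days, lfc)
    data.frame(molecule = mol, modality = mod, day = days, log2fc = lfc)
  s <- rbind(
    mk("M1", "mrna", c(1, 3, 5, 7), c(4, 3, 2, 1)),      # r = -1
    mk("M1", "protein", c(1, 3, 6, 7), c(2, 1.5, 1, .5)),
    mk("M2", "mrna", c(1, 3, 5, 7), c(2, 1, 3, 2)),      # r = 0.316, fails
    mk("M2", "protein", c(1, 3, 6, 7), c(4, 3, 2, 1)),
    mk("M3", "mrna", c(1, 3, 5, 7), c(1, 1, 1, 1)),      # constant, excluded
    mk("M3", "protein", c(1, 3, 6, 7), c(4, 3, 2, 1)))
  out <- time_correlation_filter(s, threshold = -0.5)
  expect_equal(as.character(out), "M1")
  recs <- attr(out, "records")
  r_m2 <- recs$r[recs$molecule == "M2" & recs$modality == "mrna"]
  expect_equal(r_m2, 2 / sqrt(40), tolerance = 1e-10)  # hand Pearson value
  expect_equal(recs$status[recs$molecule == "M3" & recs$modality == "mrna"],
               "constant")
  # days beyond the window are ignored
  s2 <- rbind(mk("M1", "mrna", c(1, 3, 5, 7, 28), c(4, 3, 2, 1, 50)),
              mk("M1", "protein", c(1, 3, 6), c(3, 2, 1)))
  expect_equal(as.character(time_correlation_filter(s2)), "M1")
})

test_that("Pearson r responds to affine transforms as expected", {
  mk <- function(lfc, mod) data.frame(molecule = "M", modality = mod,
                                      day = c(1, 3, 5, 7), log2fc = lfc)
  base <- c(3.1, 2.5, 1.2, 0.4)
  r0 <- attr(time_correlation_filter(rbind(mk(base, "a"), mk(base, "b"))),
             "records")$r[1]
  r_aff <- attr(time_correlation_filter(rbind(mk(2 * base + 1, "a"),
                                              mk(base, "b"))), "records")$r[1]
  r_neg <- attr(time_correlation_filter(rbind(mk(-base, "a"), mk(base, "b"))),
                "records")$r[1]
  expect_equal(r0, r_aff, tolerance = 1e-12)
  expect_equal(r0, -r_neg, tolerance = 1e-12)
})
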