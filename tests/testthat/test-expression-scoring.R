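test_that("rpkm follows the count-density formula", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 500, 1e6), 0)
  set.seed(404)
  counts <- rpois(20, 500); len <- sample(200:5000, 20)
  expect_equal(rpkm(counts, len, 2e7) * 2, rpkm(counts, len, 1e7))
  expect_equal(rpkm(counts, len, 1e7),
               counts / ((len / 1000) * 10), tolerance = 1e-12)
  expect_error(rpkm(10, 0, 1e6), "gene_lengths")
})

test_that("bh_adjust equals the literal step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37) # single test: adjusted = raw
  set.seed(405)
  for (m in c(2, 3, 5, 8, 12)) {
    for (i in 1:6) {
      p <- round(runif(m), 3)
      got <- bh_adjust(p)
      expect_equal(got, bh_bruteforce(p), tolerance = 1e-12)
      expect_equal(got, p.adjust(p, "BH"), tolerance = 1e-12)
      # monotone non-decreasing in raw-p rank
      expect_true(all(diff(got[order(p)]) >= -1e-12))
    }
  }
})

test_that("differential_expression handles signal and degeneracy", {
  a <- matrix(c(10, 10, 10, 10), 2, 2,
              dimnames = list(c("g1", "g2"), NULL))
  b <- matrix(c(10, 10, 40, 40), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  de <- differential_expression(a, b)
  expect_equal(de$log2_fc, c(0, 2))
  expect_equal(de$p[1], 1)  # constant, equal: p = 1 convention
  expect_equal(de$p[2], 0)  # constant, different: perfect separation
  # replicated noisy gene: p matches a direct Student's t-test
  set.seed(406)
  a2 <- matrix(rnorm(40, 10), 10, 4)
  b2 <- matrix(rnorm(40, 12), 10, 4)
  de2 <- differential_expression(a2, b2)
  expect_equal(de2$p[3],
               t.test(a2[3, ], b2[3, ], var.equal = TRUE)$p.value)
  expect_equal(de2$p_adj, bh_bruteforce(de2$p), tolerance = 1e-12)
})

test_that("reference_filter applies a strict 1.5-fold floor", {
  expr <- matrix(c(1.5, 1.6, 0.9, 4), 4, 1,
                 dimnames = list(sprintf("g%d", 1:4), "Tg"))
  expect_equal(reference_filter(expr, sprintf("g%d", 1:4)),
               c("g2", "g4"))
  expect_equal(length(reference_filter(expr, "g1")), 0)
  expect_error(reference_filter(expr, "g1", reference = "missing"),
               "not in expression")
})

test_that("tg_normalized_induction is a log-ratio percent, base-invariant", {
  expect_equal(tg_normalized_induction(4, 4), 100)
  expect_equal(tg_normalized_induction(1, 4), 0)
  expect_equal(tg_normalized_induction(2, 4), 50)
  set.seed(407)
  fc_c <- runif(20, 0.2, 10); fc_r <- runif(20, 1.6, 12)
  # independent recomputation in a different log base
  expect_equal(tg_normalized_induction(fc_c, fc_r),
               100 * log2(fc_c) / log2(fc_r), tolerance = 1e-9)
  expect_equal(tg_normalized_induction(fc_c, fc_r),
               100 * log10(fc_c) / log10(fc_r), tolerance = 1e-9)
  expect_error(tg_normalized_induction(-1, 4), "> 0")
  expect_error(tg_normalized_induction(2, 1), "reference")
  expect_error(tg_normalized_induction(2, 0.9), "reference")
  # linear alternative
  expect_equal(tg_normalized_induction(2, 3, scale = "linear"), 50)
})

test_that("geneset_score summarises filtered per-gene percents", {
  sets <- default_geneset_catalog()
  out <- generate_expression_profiles("global", genesets = sets,
                                      sd_log = 0, seed = 9L)
  # reference scored against itself: 100 for every UPR geneset
  for (s in c("ATF6", "XBP1s", "PERK")) {
    sc <- geneset_score(out$expr, sets, s, "Tg")
    expect_equal(sc$median, 100)
    expect_equal(sc$mean, 100)
    expect_true(sc$usable)
    expect_equal(sc$n, 16)
  }
  # noise-free global compound also scores 100 everywhere
  sc <- geneset_score(out$expr, sets, "ATF6", "cmpd_00001")
  expect_equal(unname(sc$values), rep(100, sc$n))
  # off-pathway set fails the reference filter and is unusable
  sc_off <- geneset_score(out$expr, sets, "HSR", "cmpd_00001")
  expect_false(sc_off$usable)
  expect_equal(sc_off$n, 0)
})

test_that("planted ATF6-preferential effects are recovered in scores", {
  out <- generate_expression_profiles("atf6_preferential", sd_log = 0.05,
                                      seed = 10L)
  sc <- lapply(c(ATF6 = "ATF6", XBP1s = "XBP1s", PERK = "PERK"),
               function(s) geneset_score(out$expr, out$genesets, s,
                                         "cmpd_00001"))
  expect_equal(sc$ATF6$median, 50, tolerance = 0.15)
  expect_lt(abs(sc$XBP1s$median - 5), 6)
  expect_lt(abs(sc$PERK$median - 5), 6)
  cl <- classify_upr_profile(sc)
  expect_equal(cl$call, "preferential_ATF6")
})

test_that("classify_upr_profile applies the documented decision rule", {
  mk <- function(v, set, cmp = "x") {
    structure(list(compound = cmp, geneset = set, genes = seq_along(v),
                   values = v, median = median(v), mean = mean(v),
                   n = length(v), usable = TRUE),
              class = "geneset_score")
  }
  tight <- function(m) m + c(-1, -0.5, 0, 0.5, 1)
  # forced separation -> preferential
  cl <- classify_upr_profile(list(ATF6 = mk(tight(50), "ATF6"),
                                  XBP1s = mk(tight(2), "XBP1s"),
                                  PERK = mk(tight(3), "PERK")))
  expect_equal(cl$call, "preferential_ATF6")
  expect_lt(cl$anova_p, 0.05)
  # constructed overlap at high activation -> global
  set.seed(408)
  ov <- function(m) m + rnorm(8, 0, 6)
  cl2 <- classify_upr_profile(list(ATF6 = mk(ov(75), "ATF6"),
                                   XBP1s = mk(ov(70), "XBP1s"),
                                   PERK = mk(ov(72), "PERK")))
  expect_equal(cl2$call, "global")
  # all near zero -> weak_none
  cl3 <- classify_upr_profile(list(ATF6 = mk(tight(1), "ATF6"),
                                   XBP1s = mk(tight(0), "XBP1s"),
                                   PERK = mk(tight(1), "PERK")))
  expect_equal(cl3$call, "weak_none")
  # degenerate all-identical scores warn and fall back to weak_none
  expect_warning(
    cl4 <- classify_upr_profile(list(ATF6 = mk(rep(5, 5), "ATF6"),
                                     XBP1s = mk(rep(5, 5), "XBP1s"),
                                     PERK = mk(rep(5, 5), "PERK"))),
    "degenerate")
  expect_equal(cl4$call, "weak_none")
})

test_that("planted classes are recovered at high rate and the reference is
           global", {
  classes <- rep(c("global", "atf6_preferential", "inactive"), each = 60)
  out <- generate_expression_profiles(classes, seed = 12L)
  calls <- classify_all_profiles(out$expr, out$genesets)
  planted <- out$truth$class[match(calls$compound, out$truth$condition)]
  map <- c(global = "global", atf6_preferential = "preferential_ATF6",
           inactive = "weak_none")
  acc <- tapply(calls$call == map[planted], planted, mean)
  expect_true(all(acc >= 0.95))
  # the reference condition itself always classifies as global
  ref_call <- classify_all_profiles(out$expr, out$genesets,
                                    compounds = "Tg")
  expect_equal(ref_call$call, "global")
})

test_that("Ward/Euclidean clustering recovers planted structure", {
  # two identical profiles merge first at height 0
  m <- cbind(a = c(1, 2, 4, 8), b = c(1, 2, 4, 8), c = c(9, 1, 2, 2))
  rownames(m) <- sprintf("g%d", 1:4)
  cp <- cluster_profiles(m)
  expect_equal(cp$hclust$height[1], 0)
  expect_equal(sort(cp$hclust$merge[1, ]), c(-2, -1))
  # planted three-class profiles: flat 3-cut matches classes exactly
  classes <- rep(c("global", "atf6_preferential", "inactive"), each = 8)
  out <- generate_expression_profiles(classes, sd_log = 0.05, seed = 13L)
  expr <- out$expr[, out$truth$condition]
  cp3 <- cluster_profiles(expr, k = 3)
  expect_equal(adjusted_rand_index(cp3$labels, classes), 1)
  # permuting input order leaves the multiset of merge heights unchanged
  set.seed(409)
  perm <- sample(ncol(expr))
  cp_perm <- cluster_profiles(expr[, perm], k = 3)
  expect_equal(sort(cp_perm$hclust$height), sort(cp3$hclust$height),
               tolerance = 1e-9)
  expect_equal(adjusted_rand_index(cp_perm$labels, classes[perm]), 1)
})
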