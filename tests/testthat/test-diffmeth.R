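test_that("complete separation gives difference -100 and the exact G deviance", {
  g1 <- rbind(c(20, 0), c(20, 0))   # two samples fully methylated
  g2 <- rbind(c(0, 20), c(0, 20))   # two samples fully unmethylated
  r <- dm_test_site(g1, g2)
  expect_equal(r$difference, -100)
  expect_lt(r$p_value, 1e-10)
  # pooled 2x2 table 40/0 vs 0/40: G = 2 * (40 ln 2 + 40 ln 2)
  expect_equal(r$statistic, 160 * log(2), tolerance = 1e-12)
})

test_that("identical pooled proportions give difference 0 and p = 1", {
  r <- dm_test_site(rbind(c(5, 5), c(10, 10)), rbind(c(12, 12)))
  expect_equal(r$difference, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
})

test_that("the LRT statistic equals the pooled-table G-statistic", {
  # independent oracle: G = 2 sum O log(O/E) computed from scratch
  g_oracle <- function(m1, u1, m2, u2) {
    O <- c(m1, u1, m2, u2)
    N <- sum(O)
    E <- c((m1 + u1) * (m1 + m2), (m1 + u1) * (u1 + u2),
           (m2 + u2) * (m1 + m2), (m2 + u2) * (u1 + u2)) / N
    2 * sum(ifelse(O > 0, O * log(O / E), 0))
  }
  r <- dm_test_site(rbind(c(24, 6)), rbind(c(6, 24)))
  expect_equal(r$difference, -60)
  expect_equal(r$statistic, g_oracle(24, 6, 6, 24), tolerance = 1e-9)
  set.seed(10)
  for (i in 1:25) {
    m1 <- rpois(1, 20); u1 <- rpois(1, 20) + 1
    m2 <- rpois(1, 10); u2 <- rpois(1, 30) + 1
    r <- dm_test_site(rbind(c(m1, u1)), rbind(c(m2, u2)))
    expect_equal(r$statistic, g_oracle(m1, u1, m2, u2), tolerance = 1e-9)
  }
})

test_that("the LRT matches a per-sample binomial glm deviance difference", {
  # dual route: logistic regression with per-sample binomial totals via glm
  set.seed(11)
  for (i in 1:10) {
    c1 <- cbind(rbinom(4, 25, 0.5), 25 - rbinom(4, 25, 0.5))
    c2 <- cbind(rbinom(5, 25, 0.3), 25 - rbinom(5, 25, 0.3))
    c1[, 2] <- pmax(c1[, 2], 1); c2[, 2] <- pmax(c2[, 2], 1)
    grp <- factor(rep(c("a", "b"), c(4, 5)))
    y <- rbind(c1, c2)
    m0 <- glm(y ~ 1, family = binomial)
    m1 <- glm(y ~ grp, family = binomial)
    r <- dm_test_site(c1, c2)
    expect_equal(r$statistic, m0$deviance - m1$deviance, tolerance = 1e-8)
    expect_equal(r$p_value,
                 pchisq(m0$deviance - m1$deviance, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("the test is symmetric under group exchange", {
  set.seed(12)
  c1 <- cbind(rpois(3, 15), rpois(3, 5))
  c2 <- cbind(rpois(3, 5), rpois(3, 15))
  a <- dm_test_site(c1, c2); b <- dm_test_site(c2, c1)
  expect_equal(a$difference, -b$difference)
  expect_equal(a$p_value, b$p_value)
})

test_that("BH q-values match an independent step-up implementation", {
  expect_equal(adjust_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_qvalues(0.2), 0.2)
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(13)
  p <- runif(200)^2
  expect_equal(adjust_qvalues(p), bh_oracle(p), tolerance = 1e-12)
  # invariance under permutation of input order
  i <- sample(200)
  expect_equal(adjust_qvalues(p)[i], adjust_qvalues(p[i]), tolerance = 1e-12)
})

test_that("call_dmcs flags planted differences and respects thresholds", {
  lay <- build_genome(n_chrom = 1, chrom_length = 3000,
                      cytosine_density = 25, genes_per_chrom = 0, seed = 6)
  eff <- list(effect_spec("bg", 0.1, 0.1,
                          region = list(chrom = "Chr1", start = 0, end = 2000)),
              effect_spec("sig", 0.1, 0.7,
                          region = list(chrom = "Chr1", start = 2000, end = 3000)))
  co <- cohort_spec(n_female = 5, n_male = 5, sites = c("A", "B"),
                    genotype_sd = 0.2, seed = 21)
  smp <- lapply(simulate_cohort(lay, co, effects = eff), filter_coverage)
  dm <- call_dmcs(smp)
  expect_s3_class(dm, "dm_result")
  expect_true(all(dm$q >= 0 & dm$q <= 1))
  expect_true(all(abs(dm$diff) <= 100))
  planted <- dm$pos >= 2000
  expect_gt(mean(dm$significant[planted]), 0.8)
  expect_lt(mean(dm$significant[!planted]), 0.02)
  # significance implies both thresholds
  expect_true(all(dm$q[dm$significant] < 0.001))
  expect_true(all(abs(dm$diff[dm$significant]) >= 25))
  # a vacuous difference threshold kills every call
  dm101 <- call_dmcs(smp, diff_threshold = 101)
  expect_equal(sum(dm101$significant), 0L)
  # a single-sex cohort is a configuration error
  expect_error(call_dmcs(smp[vapply(smp, `[[`, "", "sex") == "M"]), "both sexes")
})

test_that("sites need the minimum covered samples per group", {
  s1 <- make_sample("f1", "c", 0:1, c(5, 5), c(5, 5), sex = "F")
  s2 <- make_sample("f2", "c", 0L, 5L, 5L, sex = "F")
  s3 <- make_sample("m1", "c", 0:1, c(5, 5), c(5, 5), sex = "M")
  s4 <- make_sample("m2", "c", 0:1, c(5, 5), c(5, 5), sex = "M")
  dm <- call_dmcs(list(s1, s2, s3, s4), min_samples = 2)
  expect_equal(dm$pos, 0L)  # position 1 has a single covered female
})

test_that("gene-feature profiles recover planted feature levels", {
  lay <- build_genome(n_chrom = 1, chrom_length = 40000,
                      cytosine_density = 40, genes_per_chrom = 3, seed = 8)
  co <- cohort_spec(n_female = 6, n_male = 6, genotype_sd = 0.1, seed = 31)
  smp <- lapply(simulate_cohort(lay, co), filter_coverage)
  dm <- call_dmcs(smp)
  prof <- profile_gene_features(smp, lay$annotation, lay$sdr_gene, dm)
  i1 <- prof[prof$feature == "intron_1", ]
  expect_lt(abs((i1$mean_m - i1$mean_f) - 0.5), 0.08)
  expect_gt(i1$n_dmc, 0)
  i4 <- prof[prof$feature == "intron_4", ]
  expect_gt(i4$mean_m, 0.8); expect_gt(i4$mean_f, 0.8)
  expect_equal(i4$n_dmc, 0L)
  i5 <- prof[prof$feature == "intron_5", ]
  expect_lt(i5$mean_m, 0.1); expect_lt(i5$mean_f, 0.1)
  # all-zero feature means 0 in both sexes
  z1 <- make_sample("a", "c1", c(150L, 160L), c(0L, 0L), c(20L, 20L), sex = "F")
  z2 <- make_sample("b", "c1", c(150L, 160L), c(0L, 0L), c(20L, 20L), sex = "M")
  gz <- gene_annotation(list(gene_model("gz", "c1", "+",
                                        matrix(c(100, 300, 200, 400), ncol = 2),
                                        promoter_width = 50)))
  pz <- profile_gene_features(list(z1, z2), gz, "gz")
  e1 <- pz[pz$feature == "exon_1", ]
  expect_equal(e1$mean_f, 0); expect_equal(e1$mean_m, 0)
  expect_equal(e1$n_sites, 2L)
  # gene with no covered sites: undefined means, zero counts
  expect_true(all(is.na(pz[pz$feature == "promoter", c("mean_f", "mean_m")])))
})

test_that("gene ranking puts the planted gene first and breaks ties by id", {
  lay <- build_genome(n_chrom = 1, chrom_length = 40000,
                      cytosine_density = 40, genes_per_chrom = 3, seed = 8)
  co <- cohort_spec(n_female = 6, n_male = 6, genotype_sd = 0.1, seed = 31)
  smp <- lapply(simulate_cohort(lay, co), filter_coverage)
  dm <- call_dmcs(smp)
  rk <- rank_sdr_genes(names(lay$annotation$genes), dm, lay$annotation)
  expect_equal(rk$gene_id[1], lay$sdr_gene)
  expect_gt(rk$n_dmc[1], 0)
  # no significant DMCs anywhere: all zero counts, ordered by id
  none <- dm; none$significant <- FALSE
  rk0 <- rank_sdr_genes(names(lay$annotation$genes), none, lay$annotation)
  expect_equal(rk0$gene_id, sort(names(lay$annotation$genes)))
  expect_true(all(rk0$n_dmc == 0))
  # single gene list returns that gene; unknown ids are an error
  expect_equal(nrow(rank_sdr_genes(lay$sdr_gene, dm, lay$annotation)), 1L)
  expect_error(rank_sdr_genes("nope", dm, lay$annotation), "unknown gene")
})
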