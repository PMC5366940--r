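# small feature matrix with planted sex signal for CV-level tests
cv_fixture <- function(seed = 1, n_geno = 10, p = 30, effect = 2.5) {
  set.seed(seed)
  md <- data.frame(sample = paste0("g", rep(1:n_geno, each = 2),
                                   "_", c("A", "B")),
                   sex = rep(rep(c("F", "M"), length.out = n_geno), each = 2),
                   genotype = paste0("g", rep(1:n_geno, each = 2)),
                   site = rep(c("A", "B"), n_geno))
  n <- nrow(md)
  vals <- matrix(rnorm(n * p), n, p,
                 dimnames = list(md$sample, sprintf("chr%d:%d-%d",
                                                    rep(1:3, length.out = p),
                                                    seq_len(p) * 500,
                                                    seq_len(p) * 500 + 500)))
  vals[, 1] <- vals[, 1] + ifelse(md$sex == "M", effect, 0)
  tiles <- data.frame(tile_id = colnames(vals),
                      chrom = rep(paste0("chr", 1:3), length.out = p),
                      start = seq_len(p) * 500, end = seq_len(p) * 500 + 500)
  structure(list(values = vals, tiles = tiles, samples = md),
            class = "feature_matrix")
}

test_that("folds partition samples, balance sizes and respect genotypes", {
  md <- data.frame(sample = paste0("s", 1:30),
                   sex = rep(c("F", "M"), 15),
                   genotype = paste0("s", 1:30))   # one sample per genotype
  folds <- make_folds(md, cv_plan(K = 5, R = 2, seed = 3))
  expect_length(folds, 10L)
  for (r in 1:2) {
    it <- Filter(function(f) f$iteration == r, folds)
    vals <- sort(unlist(lapply(it, `[[`, "validation")))
    expect_equal(vals, sort(md$sample))              # partition
    expect_true(all(lengths(lapply(it, `[[`, "validation")) == 6L))
  }
  # identical seeds give identical fold sequences
  folds2 <- make_folds(md, cv_plan(K = 5, R = 2, seed = 3))
  expect_identical(folds, folds2)
})

test_that("by-genotype folding keeps clonal replicates together", {
  fm <- cv_fixture()
  folds <- make_folds(fm$samples, cv_plan(K = 3, R = 5, seed = 2))
  for (f in folds) {
    g_val <- unique(fm$samples$genotype[fm$samples$sample %in% f$validation])
    g_tr <- unique(fm$samples$genotype[fm$samples$sample %in% f$train])
    expect_length(intersect(g_val, g_tr), 0L)
  }
})

test_that("run_cv produces K x R records and near-zero error on signal", {
  fm <- cv_fixture()
  cv <- run_cv(fm, cv_plan(K = 2, R = 1, seed = 1), n_clusters = 2)
  expect_equal(cv$n_fits, 2L)
  cv5 <- run_cv(fm, cv_plan(K = 5, R = 2, seed = 1), n_clusters = 2)
  expect_equal(cv5$n_fits, 10L)
  expect_lte(cv5$misclassification, 0.05)
  expect_lte(cv5$misclassification_pooled, 0.05)
})

test_that("recurrence counts fits once per feature and bins correctly", {
  fm <- cv_fixture()
  cv <- run_cv(fm, cv_plan(K = 5, R = 2, seed = 4), n_clusters = 2)
  rec <- recurrence(cv)
  expect_true(all(rec$frequency >= 0 & rec$frequency <= 1))
  expect_true(all(rec$count <= cv$n_fits))
  # the planted tile is the most recurrent
  expect_equal(rec$feature[1], colnames(fm$values)[1])
  expect_equal(rec$bin[1], "F4")
  # bin boundaries: > 0.8 is F4, 0.2 exactly is F2, 0.1 exactly is F1
  fake <- cv
  fake$n_fits <- 250L
  fake$records <- c(
    replicate(210, list(features = "chr1:500-1000", clusters = list()),
              simplify = FALSE),
    replicate(40, list(features = "chr2:1000-1500", clusters = list()),
              simplify = FALSE))
  # feature 1: 210/250 = 0.84 -> F4 ; feature 2 in 250 fits count 50 -> 0.2
  fake$records <- c(fake$records,
                    replicate(10, list(features = "chr2:1000-1500",
                                       clusters = list()), simplify = FALSE))
  r2 <- recurrence(fake)
  expect_equal(r2$bin[r2$feature == "chr1:500-1000"], "F4")
  expect_equal(r2$frequency[r2$feature == "chr2:1000-1500"], 0.2)
  expect_equal(r2$bin[r2$feature == "chr2:1000-1500"], "F2")
  # never-selected features do not appear
  expect_false(any(!r2$feature %in% c("chr1:500-1000", "chr2:1000-1500")))
})

test_that("chromosome prevalence follows the share-ratio definition", {
  fm <- cv_fixture(p = 30)   # 10 tiles per chromosome
  cv <- run_cv(fm, cv_plan(K = 5, R = 2, seed = 5), n_clusters = 2)
  cs <- chromosome_summary(cv)
  # shares sum to one => prevalence weighted by input share sums to 1
  input_share <- cs$n_input / sum(cs$n_input)
  expect_equal(sum(cs$prevalence * input_share), 1, tolerance = 1e-12)
  expect_true(all(cs$mean_unique <= cs$mean_features + 1e-12))
  # hand check: a chromosome with 10% of inputs and 37% of selections
  fake <- list(records = list(
    list(clusters = list(data.frame(feature = c("a", "a", "a", "b"),
                                    sign = 1)),
         features = c("a", "b"))),
    n_fits = 1L,
    tiles = data.frame(tile_id = c("a", "b", letters[3:12]),
                       chrom = c("chrS", rep("chrO", 11)),
                       start = 0, end = 1))
  class(fake) <- "plr_cv"
  # chrS holds 1/12 of inputs and 3/4 of selections -> prevalence 9
  cs2 <- chromosome_summary(fake)
  expect_equal(cs2$prevalence[cs2$chrom == "chrS"], (3 / 4) / (1 / 12))
  expect_equal(cs2$prevalence[cs2$chrom == "chrO"], (1 / 4) / (11 / 12))
})

test_that("uniform random selection gives prevalence near one everywhere", {
  set.seed(6)
  tiles <- data.frame(tile_id = paste0("t", 1:100),
                      chrom = rep(paste0("chr", 1:4), each = 25),
                      start = 0, end = 1)
  records <- replicate(400, {
    f <- sample(tiles$tile_id, 6)
    list(clusters = list(data.frame(feature = f, sign = 1)), features = f)
  }, simplify = FALSE)
  fake <- structure(list(records = records, n_fits = 400L, tiles = tiles),
                    class = "plr_cv")
  cs <- chromosome_summary(fake)
  expect_true(all(abs(cs$prevalence - 1) < 0.3))
})

test_that("the train/test split is disjoint and genotype-coherent", {
  fm <- cv_fixture()
  sp <- train_test_split(fm$samples, 0.7, seed = 9)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), fm$samples$sample)
  g_tr <- fm$samples$genotype[fm$samples$sample %in% sp$train]
  g_te <- fm$samples$genotype[fm$samples$sample %in% sp$test]
  expect_length(intersect(g_tr, g_te), 0L)
})

test_that("test-set evaluation validates inputs and returns projections", {
  fm <- cv_fixture()
  sp <- train_test_split(fm$samples, 0.7, seed = 10)
  ev <- evaluate_test_set(fm, sp$train, sp$test, n_clusters = 2)
  expect_equal(ev$misclassification, 0)
  expect_equal(nrow(ev$projection), length(sp$test))
  expect_equal(ev$calls$sample, sp$test)
  expect_error(evaluate_test_set(fm, sp$train, character(0)), "empty")
  expect_error(evaluate_test_set(fm, sp$train, sp$train[1]), "overlap")
})
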