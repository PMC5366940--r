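# Repeated K-fold cross-validation of the classifier, feature-recurrence
# mapping (F1-F4 bins) and per-chromosome predictor composition.

#' Cross-validation plan
#'
#' @param K number of folds (default 5).
#' @param R number of repeat iterations (default 50).
#' @param strategy `"by_genotype"` keeps all samples of a genotype in one
#'   fold (clonal replicates must never straddle the train/validation
#'   boundary); `"random"` folds samples freely.
#' @param seed master seed; iteration r reshuffles with a seed derived
#'   deterministically from `(seed, r)`.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(K = 5L, R = 50L, strategy = c("by_genotype", "random"),
                    seed = 1L) {
  stopifnot(K >= 2, R >= 1)
  structure(list(K = as.integer(K), R = as.integer(R),
                 strategy = match.arg(strategy), seed = as.integer(seed)),
            class = "cv_plan")
}

derive_seed <- function(seed, r) as.integer((seed + 7919 * r) %% 2147483629)

#' Build cross-validation folds
#'
#' Folds are stratified by sex where possible. A draw in which some
#' training complement would contain a single class is rejected and redrawn
#' (at most 100 attempts).
#'
#' @param metadata `data.frame` with columns sample, sex, and (for the
#'   by-genotype strategy) genotype.
#' @param plan a [cv_plan()].
#' @return List of `K * R` records, each
#'   `list(iteration, fold, train, validation)` with sample-id vectors;
#'   within an iteration the K validation sets partition the samples.
#' @export
make_folds <- function(metadata, plan = cv_plan()) {
  K <- plan$K
  if (nrow(metadata) < K) stop("fewer samples than folds")
  unit_col <- if (plan$strategy == "by_genotype") "genotype" else "sample"
  units <- unique(metadata[, c(unit_col, "sex")])
  names(units) <- c("unit", "sex")
  if (anyDuplicated(units$unit))
    stop("a genotype carries two sex labels; cannot stratify")
  if (nrow(units) < K) stop("fewer ", unit_col, " units than folds")
  records <- list()
  for (r in seq_len(plan$R)) {
    set.seed(derive_seed(plan$seed, r))
    for (attempt in seq_len(100L)) {
      fold_of <- rep(NA_integer_, nrow(units))
      for (sx in unique(units$sex)) {
        idx <- which(units$sex == sx)
        idx <- idx[sample.int(length(idx))]
        # round-robin with a random starting fold keeps fold sizes balanced
        fold_of[idx] <- ((sample.int(K, 1) + seq_along(idx) - 2L) %% K) + 1L
      }
      sample_fold <- fold_of[match(metadata[[unit_col]], units$unit)]
      ok <- all(vapply(seq_len(K), function(k)
        length(unique(metadata$sex[sample_fold != k])) == 2 &&
          any(sample_fold == k), logical(1)))
      if (ok) break
      if (attempt == 100L)
        stop("could not build folds with two classes in every training set")
    }
    for (k in seq_len(K)) {
      records[[length(records) + 1L]] <- list(
        iteration = r, fold = k,
        train = metadata$sample[sample_fold != k],
        validation = metadata$sample[sample_fold == k])
    }
  }
  records
}

#' Run repeated cross-validation of the classifier
#'
#' Fits the [plr()] classifier on each fold's training portion and scores
#' the held-out fold. Per-fit feature selections (with cluster membership)
#' are retained for recurrence and chromosome-composition analysis. A fit
#' failure is recorded, the fit skipped, and the error denominator adjusted.
#'
#' @param fm a filtered, imputed [build_feature_matrix()] result.
#' @param plan a [cv_plan()].
#' @param labels optional response vector (default: the samples' sex).
#' @param ... passed to [plr()] (lambda, n_clusters, ...).
#' @return An object of class `plr_cv`: list with `records` (per-fit
#'   selected clusters, validation errors), `misclassification` (mean of
#'   per-fold error rates), `misclassification_pooled` (all CV predictions
#'   pooled), `n_fits`, `n_failed`, `tiles`, `plan`.
#' @export
run_cv <- function(fm, plan = cv_plan(), labels = NULL, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (anyNA(fm$values)) stop("feature matrix has missing values; impute first")
  md <- fm$samples
  if (!is.null(labels)) md$sex <- as.character(labels)
  folds <- make_folds(md, plan)
  records <- list()
  n_failed <- 0L
  for (fd in folds) {
    tr <- match(fd$train, md$sample)
    va <- match(fd$validation, md$sample)
    rec <- tryCatch({
      fit <- plr(fm$values[tr, , drop = FALSE], md$sex[tr], ...)
      prob <- predict(fit, fm$values[va, , drop = FALSE])
      pred <- fit$levels[(prob >= 0.5) + 1L]
      list(iteration = fd$iteration, fold = fd$fold,
           clusters = fit$clusters,
           features = unique(unlist(lapply(fit$clusters, `[[`, "feature"))),
           n_validation = length(va),
           n_errors = sum(pred != md$sex[va]),
           validation = fd$validation, predicted = pred)
    }, error = function(e) {
      warning("fold ", fd$fold, " of iteration ", fd$iteration,
              " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) n_failed <- n_failed + 1L else
      records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L) stop("all cross-validation fits failed")
  err_rates <- vapply(records, function(r) r$n_errors / r$n_validation, 0)
  structure(list(records = records,
                 misclassification = mean(err_rates),
                 misclassification_pooled =
                   sum(vapply(records, `[[`, 0L, "n_errors")) /
                   sum(vapply(records, `[[`, 0L, "n_validation")),
                 n_fits = length(records), n_failed = n_failed,
                 tiles = fm$tiles, plan = plan),
            class = "plr_cv")
}

#' @export
print.plr_cv <- function(x, ...) {
  cat("<plr_cv>", x$n_fits, "fits",
      sprintf("(K=%d, R=%d, %s)\n", x$plan$K, x$plan$R, x$plan$strategy))
  cat(sprintf("  misclassification: %.3f (mean over folds), %.3f (pooled)\n",
              x$misclassification, x$misclassification_pooled))
  invisible(x)
}

#' Feature-recurrence table
#'
#' How often each feature was selected into the model across the K x R
#' cross-validation fits (counted once per fit even if it joined several
#' clusters), with frequency bins F4 (> 80% of fits), F3 (> 20% and <= 80%),
#' F2 (> 10% and <= 20%), F1 (<= 10%). Never-selected features are absent.
#'
#' @param cv a [run_cv()] result.
#' @return `data.frame`: feature, chrom, count, frequency, bin; most
#'   recurrent first.
#' @export
recurrence <- function(cv) {
  stopifnot(inherits(cv, "plr_cv"))
  tab <- table(unlist(lapply(cv$records, `[[`, "features")))
  if (length(tab) == 0L)
    return(data.frame(feature = character(0), chrom = character(0),
                      count = integer(0), frequency = numeric(0),
                      bin = character(0)))
  freq <- as.vector(tab) / cv$n_fits
  bin <- cut(freq, breaks = c(0, 0.10, 0.20, 0.80, 1),
             labels = c("F1", "F2", "F3", "F4"), include.lowest = TRUE)
  out <- data.frame(feature = names(tab),
                    chrom = cv$tiles$chrom[match(names(tab),
                                                 cv$tiles$tile_id)],
                    count = as.vector(tab), frequency = freq,
                    bin = as.character(bin), stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Per-chromosome predictor composition
#'
#' For every chromosome: the mean and SD over fits of the number of
#' selected features located there (total, counting a feature once per
#' cluster it joins, and unique), and the *relative cluster prevalence* -
#' the chromosome's share of all selections across fits divided by its
#' share of the input features, i.e. enrichment over the expectation under
#' uniform selection. Values far above 1 mark chromosomes whose methylation
#' carries concentrated predictive signal.
#'
#' @param cv a [run_cv()] result.
#' @return `data.frame`: chrom, n_input, mean_features, sd_features,
#'   mean_unique, sd_unique, prevalence.
#' @export
chromosome_summary <- function(cv) {
  stopifnot(inherits(cv, "plr_cv"))
  tiles <- cv$tiles
  chroms <- unique(tiles$chrom)
  chrom_of <- function(f) {
    cc <- tiles$chrom[match(f, tiles$tile_id)]
    if (anyNA(cc)) stop("selected feature(s) missing from the tile map")
    cc
  }
  per_fit_tot <- vapply(cv$records, function(r) {
    cc <- chrom_of(unlist(lapply(r$clusters, `[[`, "feature")))
    as.vector(table(factor(cc, levels = chroms)))
  }, numeric(length(chroms)))
  per_fit_uni <- vapply(cv$records, function(r) {
    cc <- chrom_of(r$features)
    as.vector(table(factor(cc, levels = chroms)))
  }, numeric(length(chroms)))
  per_fit_tot <- matrix(per_fit_tot, nrow = length(chroms))
  per_fit_uni <- matrix(per_fit_uni, nrow = length(chroms))
  n_input <- as.vector(table(factor(tiles$chrom, levels = chroms)))
  sel_share <- rowSums(per_fit_tot) / sum(per_fit_tot)
  input_share <- n_input / sum(n_input)
  out <- data.frame(chrom = chroms, n_input = n_input,
                    mean_features = rowMeans(per_fit_tot),
                    sd_features = apply(per_fit_tot, 1, sd),
                    mean_unique = rowMeans(per_fit_uni),
                    sd_unique = apply(per_fit_uni, 1, sd),
                    prevalence = ifelse(input_share > 0,
                                        sel_share / input_share, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Train/test split of a cohort
#'
#' Reserves a fraction of the cohort for final model evaluation, splitting
#' by genotype (clones stay together) and stratifying by sex.
#'
#' @param metadata `data.frame` with sample, sex, genotype columns.
#' @param train_fraction fraction of genotypes per sex used for training.
#' @param seed RNG seed.
#' @return List with `train` and `test` sample-id vectors (disjoint).
#' @export
train_test_split <- function(metadata, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  units <- unique(metadata[, c("genotype", "sex")])
  train_units <- unlist(lapply(split(units$genotype, units$sex), function(g) {
    g <- g[sample.int(length(g))]
    g[seq_len(max(1L, round(train_fraction * length(g))))]
  }))
  list(train = metadata$sample[metadata$genotype %in% train_units],
       test = metadata$sample[!metadata$genotype %in% train_units])
}

#' Evaluate the final model on held-out test samples
#'
#' Refits the classifier on all training samples and scores the disjoint
#' test set, returning per-sample calls and the 2-D centroid projection.
#'
#' @param fm a complete (filtered, imputed) `feature_matrix` holding both
#'   training and test samples.
#' @param train,test disjoint sample-id vectors.
#' @param ... passed to [plr()].
#' @return List: `model`, `misclassification`, `calls` (sample, truth,
#'   predicted, probability), `projection` (test-sample coordinates).
#' @export
evaluate_test_set <- function(fm, train, test, ...) {
  if (length(test) == 0L) stop("empty test set")
  if (length(intersect(train, test)) > 0)
    stop("train and test sample ids overlap")
  md <- fm$samples
  tr <- match(train, md$sample); te <- match(test, md$sample)
  if (anyNA(tr) || anyNA(te)) stop("unknown sample id in train/test")
  model <- plr(fm$values[tr, , drop = FALSE], md$sex[tr], ...)
  prob <- predict(model, fm$values[te, , drop = FALSE])
  pred <- model$levels[(prob >= 0.5) + 1L]
  list(model = model,
       misclassification = mean(pred != md$sex[te]),
       calls = data.frame(sample = test, truth = md$sex[te],
                          predicted = pred, probability = as.vector(prob),
                          stringsAsFactors = FALSE),
       projection = project_centroids(model, fm$values[te, , drop = FALSE]))
}
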