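# End-to-end orchestration: simulate -> differential methylation ->
# classification. These wrappers tie the modules together with one config
# list, log the thresholds actually used, and write all artifacts to an
# output directory; they are the programmatic equivalent of a command-line
# pipeline.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its conventional default:
#' coverage > 10x, difference >= 25 percentage points at q < 0.001, 500 bp
#' tiles, 80% detection, lambda = 1/32, q = 10 clusters, K = 5 folds,
#' R = 50 iterations, 70% of genotypes for training.
#'
#' @param seed master seed for all randomness.
#' @param context methylation context analysed by the classifier.
#' @param min_coverage,diff_threshold,q_threshold DM-calling thresholds.
#' @param tile_length,detection_rate,min_sites tile-feature settings.
#' @param lambda,n_clusters,max_cluster_size classifier settings.
#' @param K,R,cv_strategy cross-validation settings.
#' @param train_fraction train/test genotype split.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, context = "CG", min_coverage = 10L,
                            diff_threshold = 25, q_threshold = 0.001,
                            tile_length = 500L, detection_rate = 0.80,
                            min_sites = 1L, lambda = 1 / 32,
                            n_clusters = 10L, max_cluster_size = 15L,
                            K = 5L, R = 50L, cv_strategy = "by_genotype",
                            train_fraction = 0.7) {
  structure(as.list(environment()), class = "pipeline_config")
}

log_msg <- function(...) message("[methylsex] ", ...)

#' Simulate a cohort fixture on disk
#'
#' @param dir output directory.
#' @param config a [pipeline_config()].
#' @param layout optional [build_genome()] layout (default: 19-chromosome
#'   layout with the 13-gene SDR panel, built from `config$seed`).
#' @param cohort optional [cohort_spec()] (default cohort, `config$seed`).
#' @param force overwrite an existing fixture.
#' @return The file manifest, invisibly.
#' @export
pipeline_simulate <- function(dir, config = pipeline_config(),
                              layout = NULL, cohort = NULL, force = FALSE) {
  if (is.null(layout)) layout <- build_genome(seed = config$seed)
  if (is.null(cohort)) cohort <- cohort_spec(seed = config$seed)
  samples <- simulate_cohort(layout, cohort)
  manifest <- write_fixture(samples, layout, dir, force = force)
  log_msg("wrote ", length(manifest), " fixture files to ", dir)
  invisible(manifest)
}

#' Read a fixture directory
#'
#' @param dir directory produced by [pipeline_simulate()] /
#'   [write_fixture()].
#' @param promoter_width promoter window for the gene models.
#' @return List: `samples` (methylome samples with metadata attached),
#'   `annotation`, `metadata`.
#' @export
read_fixture <- function(dir, promoter_width = 2000L) {
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  ann <- read_gff3(file.path(dir, "genes.gff3"),
                   promoter_width = promoter_width)
  files <- list.files(dir, pattern = "\\.(cx|cov)\\.tsv(\\.gz)?$",
                      full.names = TRUE)
  samples <- lapply(files, function(f) {
    sid <- sub("\\.(cx|cov)\\.tsv(\\.gz)?$", "", basename(f))
    i <- match(sid, md$sample)
    if (is.na(i)) stop("call file ", basename(f), " not in metadata")
    read_coverage_file(f, sample_id = sid, sex = md$sex[i],
                       genotype = md$genotype[i], site = md$site[i])
  })
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  list(samples = samples, annotation = ann, metadata = md)
}

#' Differential methylation step of the pipeline
#'
#' Coverage-filters all samples, tests every context separately, writes
#' per-context DMC tables (TSV + BED), ranks the annotated genes by
#' overlapping DMCs, and profiles the top-ranked gene's features.
#'
#' @param fixture_dir fixture directory.
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @return List with per-context `dm` tables, the gene `ranking`, and the
#'   top gene's feature `profile`, invisibly.
#' @export
pipeline_dmc <- function(fixture_dir, out_dir, config = pipeline_config()) {
  fx <- read_fixture(fixture_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  filtered <- lapply(fx$samples, filter_coverage,
                     min_coverage = config$min_coverage)
  log_msg("DM thresholds: coverage > ", config$min_coverage,
          "x, |diff| >= ", config$diff_threshold, ", q < ",
          config$q_threshold)
  dms <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    ctx_samples <- lapply(filtered, function(s) split_by_context(s)[[ctx]])
    dm <- call_dmcs(ctx_samples, q_threshold = config$q_threshold,
                    diff_threshold = config$diff_threshold)
    write_dm_result(dm, tsv = file.path(out_dir, paste0("dmc_", ctx, ".tsv")),
                    bed = file.path(out_dir, paste0("dmc_", ctx, ".bed")))
    log_msg(ctx, ": ", nrow(dm), " testable sites, ",
            sum(dm$significant), " DMCs")
    dms[[ctx]] <- dm
  }
  gene_ids <- names(fx$annotation$genes)
  ranking <- rank_sdr_genes(gene_ids, dms[[config$context]], fx$annotation)
  write.table(ranking, file.path(out_dir, "gene_ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prof <- profile_gene_features(lapply(filtered, function(s)
    split_by_context(s)[[config$context]]),
    fx$annotation, ranking$gene_id[1], dm = dms[[config$context]])
  write.table(prof, file.path(out_dir, "top_gene_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(dm = dms, ranking = ranking, profile = prof))
}

#' Classification step of the pipeline
#'
#' Builds the tile feature matrix for the configured context, filters and
#' imputes it, holds out a test set of genotypes, runs repeated K-fold
#' cross-validation on the training samples, maps feature recurrence and
#' chromosome composition, and evaluates the final model on the test set.
#' All artifacts (recurrence table + BED, chromosome summary, projection
#' coordinates, JSON report) are written to `out_dir`.
#'
#' @param fixture_dir fixture directory.
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @return List: `cv`, `recurrence`, `chromosomes`, `evaluation`,
#'   `feature_matrix`, `split`, invisibly.
#' @export
pipeline_classify <- function(fixture_dir, out_dir,
                              config = pipeline_config()) {
  fx <- read_fixture(fixture_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  filtered <- lapply(fx$samples, function(s)
    split_by_context(filter_coverage(s, config$min_coverage))[[config$context]])
  chrom_len <- local({
    mx <- tapply(unlist(lapply(fx$samples, function(s) s$calls$pos)),
                 unlist(lapply(fx$samples, function(s) s$calls$chrom)), max)
    setNames(as.integer(mx + config$tile_length), names(mx))
  })
  tiles <- tile_genome(chrom_len, tile_length = config$tile_length)
  fm <- build_feature_matrix(filtered, tiles,
                             tile_length = config$tile_length,
                             min_sites = config$min_sites)
  fm <- impute_missing(filter_features(fm,
                                       detection_rate = config$detection_rate))
  log_msg(ncol(fm$values), " features retained (", config$context,
          " context) across ", nrow(fm$values), " samples")
  split <- train_test_split(fm$samples, config$train_fraction,
                            seed = config$seed)
  fm_train <- fm
  keep <- fm$samples$sample %in% split$train
  fm_train$values <- fm$values[keep, , drop = FALSE]
  fm_train$samples <- fm$samples[keep, , drop = FALSE]
  plan <- cv_plan(K = config$K, R = config$R, strategy = config$cv_strategy,
                  seed = config$seed)
  cv <- run_cv(fm_train, plan, lambda = config$lambda,
               n_clusters = config$n_clusters,
               max_cluster_size = config$max_cluster_size)
  rec <- recurrence(cv)
  chrs <- chromosome_summary(cv)
  ev <- evaluate_test_set(fm, split$train, split$test,
                          lambda = config$lambda,
                          n_clusters = config$n_clusters,
                          max_cluster_size = config$max_cluster_size)
  log_msg(sprintf("CV misclassification %.3f; test misclassification %.3f",
                  cv$misclassification, ev$misclassification))

  write.table(rec, file.path(out_dir, "recurrence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(rec) > 0) {
    co <- fm$tiles[match(rec$feature, fm$tiles$tile_id), ]
    shade <- c(F1 = 250, F2 = 500, F3 = 750, F4 = 1000)[rec$bin]
    write.table(data.frame(co$chrom, co$start, co$end, rec$feature, shade),
                file.path(out_dir, "recurrence.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(chrs, file.path(out_dir, "chromosome_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = rownames(ev$projection), ev$projection),
              file.path(out_dir, "projection.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_features = ncol(fm$values),
         n_train = length(split$train), n_test = length(split$test),
         cv_misclassification = cv$misclassification,
         cv_misclassification_pooled = cv$misclassification_pooled,
         test_misclassification = ev$misclassification,
         n_fits = cv$n_fits, n_failed = cv$n_failed,
         config = unclass(config)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(cv = cv, recurrence = rec, chromosomes = chrs,
                 evaluation = ev, feature_matrix = fm, split = split))
}
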