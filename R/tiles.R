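# Fixed 500 bp genomic tiles and the samples x tiles feature matrix used
# for sex classification.

#' Tile a genome into fixed windows
#'
#' Consecutive non-overlapping `[0,500), [500,1000), ...` windows per
#' chromosome; the terminal tile is truncated at the chromosome end. Tile
#' ids are `"chrom:start-end"` (0-based half-open).
#'
#' @param chrom_lengths named integer vector of chromosome lengths, or a
#'   `genome_layout` (its `chromosomes` table is used).
#' @param tile_length window width in bp (default 500).
#' @return `data.frame`: tile_id, chrom, start, end.
#' @export
tile_genome <- function(chrom_lengths, tile_length = 500L) {
  stopifnot(tile_length > 0)
  if (inherits(chrom_lengths, "genome_layout"))
    chrom_lengths <- setNames(chrom_lengths$chromosomes$length,
                              chrom_lengths$chromosomes$name)
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    start <- seq.int(0L, len - 1L, by = tile_length)
    end <- pmin(start + tile_length, len)
    data.frame(tile_id = sprintf("%s:%d-%d", cn, start, end),
               chrom = cn, start = start, end = end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize a sample's methylation over tiles
#'
#' A tile's value is the coverage-weighted methylation fraction
#' sum(#Cs)/sum(#Cs + #Ts) over the covered cytosine sites falling in the
#' tile. A tile with fewer than `min_sites` covered sites is *missing*
#' (`NA`), never 0. The sample should already be coverage-filtered.
#'
#' @param sample a [methylome_sample()].
#' @param tiles tile table from [tile_genome()].
#' @param tile_length tile width used to map positions to tiles (must match
#'   `tiles`).
#' @param min_sites minimum covered sites for a tile to count as detected.
#' @return Named numeric vector over `tiles$tile_id` (`NA` = undetected).
#' @export
summarize_tiles <- function(sample, tiles, tile_length = 500L,
                            min_sites = 1L) {
  calls <- sample$calls
  vals <- setNames(rep(NA_real_, nrow(tiles)), tiles$tile_id)
  if (nrow(calls) == 0) return(vals)
  cov <- calls$meth + calls$unmeth
  calls <- calls[cov > 0, , drop = FALSE]
  if (nrow(calls) == 0) return(vals)
  tstart <- (calls$pos %/% tile_length) * tile_length
  key <- sprintf("%s:%d", calls$chrom, tstart)
  tile_key <- sprintf("%s:%d", tiles$chrom, tiles$start)
  m <- rowsum(calls$meth, key)
  tot <- rowsum(calls$meth + calls$unmeth, key)
  ns <- rowsum(rep(1L, nrow(calls)), key)
  idx <- match(rownames(m), tile_key)
  keep <- !is.na(idx) & as.vector(ns) >= min_sites
  vals[idx[keep]] <- as.vector(m)[keep] / as.vector(tot)[keep]
  vals
}

#' Build the samples x tiles feature matrix
#'
#' @param samples list of [methylome_sample()]s (coverage-filtered; usually
#'   one context, see [split_by_context()]).
#' @param tiles tile table from [tile_genome()].
#' @param tile_length,min_sites passed to [summarize_tiles()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (samples x tiles numeric matrix, `NA` = undetected), `tiles`, and
#'   `samples` (metadata data.frame).
#' @export
build_feature_matrix <- function(samples, tiles, tile_length = 500L,
                                 min_sites = 1L) {
  vals <- t(vapply(samples, summarize_tiles, numeric(nrow(tiles)),
                   tiles = tiles, tile_length = tile_length,
                   min_sites = min_sites))
  rownames(vals) <- vapply(samples, `[[`, "", "sample_id")
  md <- data.frame(sample = rownames(vals),
                   sex = vapply(samples, `[[`, "", "sex"),
                   genotype = vapply(samples, `[[`, "", "genotype"),
                   site = vapply(samples, `[[`, "", "site"),
                   stringsAsFactors = FALSE)
  rownames(md) <- NULL
  structure(list(values = vals, tiles = tiles, samples = md),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "samples x", ncol(x$values),
      "tiles;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Filter features for classification
#'
#' Two filters, applied in order: (1) detection - keep tiles detected
#' (non-missing) in at least `detection_rate` of the samples; (2)
#' variability - among the detection-passing tiles, keep those whose
#' across-sample inter-quartile range is strictly greater than the median
#' IQR of the detection-passing tiles. Constant tiles carry no
#' discriminative signal and are dropped.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param detection_rate minimum fraction of samples with a value.
#' @param iqr_rule `"above_median"` (default) applies filter (2); `"none"`
#'   keeps all detection-passing tiles.
#' @return A `feature_matrix` restricted to the retained tiles.
#' @export
filter_features <- function(fm, detection_rate = 0.80,
                            iqr_rule = c("above_median", "none")) {
  iqr_rule <- match.arg(iqr_rule)
  v <- fm$values
  det <- colMeans(!is.na(v)) >= detection_rate
  keep <- det
  if (iqr_rule == "above_median" && any(det)) {
    iqrs <- apply(v[, det, drop = FALSE], 2, IQR, na.rm = TRUE)
    keep[det] <- iqrs > median(iqrs)
  }
  if (!any(keep))
    stop("no features pass the detection/IQR filters; classifier cannot run")
  fm$values <- v[, keep, drop = FALSE]
  fm$tiles <- fm$tiles[match(colnames(fm$values), fm$tiles$tile_id), ]
  rownames(fm$tiles) <- NULL
  fm
}

#' Impute residual missing values
#'
#' Replaces each missing entry by the feature's across-sample median. The
#' pre-imputation missingness mask is kept in `fm$imputed` for audit.
#' Imputed values never leave the feature's observed range.
#'
#' @param fm a filtered `feature_matrix` (every feature mostly detected).
#' @return A complete `feature_matrix` (no `NA`).
#' @export
impute_missing <- function(fm) {
  v <- fm$values
  fm$imputed <- is.na(v)
  if (any(fm$imputed)) {
    med <- apply(v, 2, median, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 2]]
  }
  fm$values <- v
  fm
}

#' Write a feature matrix as TSV (tiles x samples) plus a BED of tiles
#'
#' @param fm a `feature_matrix`.
#' @param tsv,bed output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_feature_matrix <- function(fm, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    tab <- data.frame(tile_id = colnames(fm$values), t(fm$values),
                      check.names = FALSE)
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed))
    write.table(fm$tiles[, c("chrom", "start", "end", "tile_id")], bed,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(c(tsv, bed))
}
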