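# Per-cytosine differential methylation between two groups of samples.
# The test is a logistic regression of methylation proportion on group
# membership with per-sample binomial totals, assessed by the likelihood
# ratio (deviance difference between the null and the group model) against
# chi-square with 1 df. Because group membership is the only covariate, the
# group-model MLE is the pooled per-group proportion, and the LRT statistic
# equals the G-statistic of the pooled 2x2 (meth/unmeth x group) table;
# that closed form is what the vectorised implementation computes.

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# vectorised LRT over pooled 2x2 tables
dm_lrt <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1; n2 <- m2 + u2
  M <- m1 + m2; U <- u1 + u2; N <- n1 + n2
  G <- 2 * (xlogx(m1) + xlogx(u1) + xlogx(m2) + xlogx(u2) + xlogx(N)
            - xlogx(n1) - xlogx(n2) - xlogx(M) - xlogx(U))
  G <- pmax(G, 0)  # guard against tiny negative rounding
  data.frame(statistic = G,
             p = pchisq(G, df = 1, lower.tail = FALSE),
             diff = 100 * (m2 / n2 - m1 / n1))
}

#' Differential methylation test at one site
#'
#' Likelihood-ratio test of a logistic regression of per-sample methylation
#' proportions (binomial totals) on group membership. The reported
#' difference is pooled ratio(group 2) minus pooled ratio(group 1), in
#' percentage points. Swapping the groups negates the difference and leaves
#' the p-value unchanged.
#'
#' @param counts1,counts2 two-column matrices (meth, unmeth), one row per
#'   covered sample of the group.
#' @return List with `difference` (percentage points), `p_value`, and the
#'   LRT `statistic`.
#' @export
dm_test_site <- function(counts1, counts2) {
  counts1 <- rbind(counts1); counts2 <- rbind(counts2)
  if (sum(counts1) == 0 || sum(counts2) == 0)
    stop("a group has zero total coverage at this site")
  r <- dm_lrt(sum(counts1[, 1]), sum(counts1[, 2]),
              sum(counts2[, 1]), sum(counts2[, 2]))
  list(difference = r$diff, p_value = r$p, statistic = r$statistic)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; output is invariant under
#' permutation of the input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
adjust_qvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Significance threshold presets
#'
#' "methods": differential methylation of at least 25 percentage points at
#' q < 0.001; "figure1": difference > 20 points at q < 0.001.
#'
#' @param name preset name.
#' @return List with `diff_threshold` and `q_threshold`.
#' @export
dm_preset <- function(name = c("methods", "figure1")) {
  switch(match.arg(name),
         methods = list(diff_threshold = 25, q_threshold = 0.001),
         figure1 = list(diff_threshold = 20, q_threshold = 0.001))
}

# pool calls of a sample list into per-site (chrom, pos, strand) totals
pool_group <- function(samples) {
  calls <- do.call(rbind, lapply(samples, `[[`, "calls"))
  key <- paste(calls$chrom, calls$pos, calls$strand, sep = "\r")
  m <- rowsum(calls$meth, key)
  u <- rowsum(calls$unmeth, key)
  n <- rowsum(rep(1L, nrow(calls)), key)
  first <- calls[!duplicated(key), c("chrom", "pos", "strand", "context")]
  first <- first[match(rownames(m), key[!duplicated(key)]), ]
  cbind(first, data.frame(meth = as.vector(m), unmeth = as.vector(u),
                          n_samples = as.vector(n)))
}

#' Call differentially methylated cytosines between the sexes
#'
#' Runs the per-site likelihood-ratio test over all sites covered in at
#' least `min_samples` samples of each sex, applies Benjamini-Hochberg
#' correction across the testable sites, and flags sites passing both the
#' q-value and the absolute-difference thresholds. The difference is male
#' minus female, in percentage points. Samples should already be
#' coverage-filtered (see [filter_coverage()]).
#'
#' @param samples list of [methylome_sample()]s with sex labels "F"/"M".
#' @param q_threshold,diff_threshold significance thresholds (defaults
#'   q < 0.001 and at least 25 points; see [dm_preset()]).
#' @param min_samples minimum covered samples required per group at a site.
#' @return A `data.frame` of class `dm_result`, one row per testable site:
#'   chrom, pos, strand, context, pooled counts per sex, covered-sample
#'   counts, `diff` (percentage points, M - F), `p`, `q`, `significant`.
#' @export
call_dmcs <- function(samples, q_threshold = 0.001, diff_threshold = 25,
                      min_samples = 2L) {
  sex <- vapply(samples, `[[`, "", "sex")
  f <- samples[sex == "F"]; m <- samples[sex == "M"]
  if (length(f) == 0 || length(m) == 0)
    stop("need samples of both sexes; got ", length(f), " F and ",
         length(m), " M")
  pf <- pool_group(f); pm <- pool_group(m)
  keyf <- paste(pf$chrom, pf$pos, pf$strand, sep = "\r")
  keym <- paste(pm$chrom, pm$pos, pm$strand, sep = "\r")
  common <- intersect(keyf, keym)
  pf <- pf[match(common, keyf), ]; pm <- pm[match(common, keym), ]
  ok <- pf$n_samples >= min_samples & pm$n_samples >= min_samples &
    (pf$meth + pf$unmeth) > 0 & (pm$meth + pm$unmeth) > 0
  pf <- pf[ok, ]; pm <- pm[ok, ]
  if (nrow(pf) == 0) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), context = character(0),
                        meth_f = integer(0), total_f = integer(0),
                        meth_m = integer(0), total_m = integer(0),
                        n_f = integer(0), n_m = integer(0),
                        diff = numeric(0), p = numeric(0), q = numeric(0),
                        significant = logical(0))
    return(structure(empty, class = c("dm_result", "data.frame")))
  }
  r <- dm_lrt(pf$meth, pf$unmeth, pm$meth, pm$unmeth)
  out <- data.frame(chrom = pf$chrom, pos = pf$pos, strand = pf$strand,
                    context = pf$context,
                    meth_f = pf$meth, total_f = pf$meth + pf$unmeth,
                    meth_m = pm$meth, total_m = pm$meth + pm$unmeth,
                    n_f = pf$n_samples, n_m = pm$n_samples,
                    diff = r$diff, p = r$p, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  out$q <- adjust_qvalues(out$p)
  out$significant <- out$q < q_threshold & abs(out$diff) >= diff_threshold
  class(out) <- c("dm_result", "data.frame")
  out
}

#' Gene-feature methylation profile
#'
#' For each feature of a gene (promoter, exons, introns in transcription
#' order), computes the coverage-weighted mean methylation per sex
#' (sum of #Cs over sum of coverage across all covered sites of all samples
#' of that sex), the number of distinct covered sites, and the number of
#' overlapping significant DMCs.
#'
#' @param samples list of [methylome_sample()]s (coverage-filtered).
#' @param annotation a [gene_annotation()].
#' @param gene_id gene to profile.
#' @param dm optional `dm_result` from [call_dmcs()] for the DMC counts.
#' @return `data.frame`: gene_id, feature, start, end, mean_f, mean_m
#'   (`NA` when no covered site), n_sites, n_dmc.
#' @export
profile_gene_features <- function(samples, annotation, gene_id, dm = NULL) {
  g <- annotation$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene id: ", gene_id)
  feats <- gene_features(g)
  sex <- vapply(samples, `[[`, "", "sex")
  pools <- list(F = if (any(sex == "F")) pool_group(samples[sex == "F"]),
                M = if (any(sex == "M")) pool_group(samples[sex == "M"]))
  out <- feats
  out$gene_id <- gene_id
  for (sx in c("F", "M")) {
    col <- paste0("mean_", tolower(sx))
    out[[col]] <- NA_real_
    pl <- pools[[sx]]
    if (is.null(pl)) next
    for (i in seq_len(nrow(feats))) {
      sel <- pl$chrom == feats$chrom[i] & pl$pos >= feats$start[i] &
        pl$pos < feats$end[i]
      tot <- sum(pl$meth[sel] + pl$unmeth[sel])
      if (tot > 0) out[[col]][i] <- sum(pl$meth[sel]) / tot
    }
  }
  all_sites <- unique(do.call(rbind, lapply(pools[!vapply(pools, is.null, TRUE)],
                                            function(p) p[c("chrom", "pos", "strand")])))
  out$n_sites <- vapply(seq_len(nrow(feats)), function(i)
    sum(all_sites$chrom == feats$chrom[i] & all_sites$pos >= feats$start[i] &
          all_sites$pos < feats$end[i]), integer(1))
  out$n_dmc <- 0L
  if (!is.null(dm) && nrow(dm) > 0) {
    sig <- dm[dm$significant, , drop = FALSE]
    out$n_dmc <- vapply(seq_len(nrow(feats)), function(i)
      sum(sig$chrom == feats$chrom[i] & sig$pos >= feats$start[i] &
            sig$pos < feats$end[i]), integer(1))
  }
  out[, c("gene_id", "feature", "chrom", "start", "end", "mean_f", "mean_m",
          "n_sites", "n_dmc")]
}

#' Rank candidate sex-determining genes by differential methylation
#'
#' Counts significant DMCs overlapping each gene (promoter plus transcribed
#' span) and orders genes by that count, breaking ties by the largest
#' absolute significant difference and then by gene id.
#'
#' @param gene_ids genes to rank (must exist in `annotation`).
#' @param dm a `dm_result` from [call_dmcs()].
#' @param annotation a [gene_annotation()].
#' @return `data.frame`: gene_id, n_dmc, max_abs_diff, ordered best first.
#' @export
rank_sdr_genes <- function(gene_ids, dm, annotation) {
  if (length(gene_ids) == 0) stop("empty gene list")
  sig <- if (nrow(dm) > 0) dm[dm$significant, , drop = FALSE] else dm
  rows <- lapply(gene_ids, function(gid) {
    g <- annotation$genes[[gid]]
    if (is.null(g)) stop("unknown gene id: ", gid)
    lo <- min(g$promoter[1], g$span[1]); hi <- max(g$promoter[2], g$span[2])
    sel <- if (nrow(sig) == 0) logical(0) else
      sig$chrom == g$chrom & sig$pos >= lo & sig$pos < hi
    data.frame(gene_id = gid, n_dmc = sum(sel),
               max_abs_diff = if (any(sel)) max(abs(sig$diff[sel])) else 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$n_dmc, -tab$max_abs_diff, tab$gene_id), ]
  rownames(tab) <- NULL
  tab
}

#' Write a DM result as TSV and BED
#'
#' The BED uses 0-based half-open coordinates and scores significant sites
#' for genome-browser display.
#'
#' @param dm a `dm_result`.
#' @param tsv,bed output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_dm_result <- function(dm, tsv = NULL, bed = NULL) {
  if (!is.null(tsv))
    write.table(dm, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed) && nrow(dm) > 0) {
    b <- data.frame(dm$chrom, dm$pos, dm$pos + 1L,
                    sprintf("dmc_%s_%d", dm$chrom, dm$pos),
                    round(pmin(1000, abs(dm$diff) * 10)), dm$strand)
    write.table(b[dm$significant, ], bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv, bed))
}
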