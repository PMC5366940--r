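#' @useDynLib methylsex, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile IQR p.adjust pchisq plogis qlogis rbeta
#'   rbinom rnbinom rnorm runif coef predict fitted residuals sd setNames
#' @importFrom utils read.table write.table
NULL

CONTEXTS <- c("CG", "CHG", "CHH")
SEXES <- c("F", "M", "unknown")

#' Construct a per-cytosine call table
#'
#' The atomic data structure of the package: one row per cytosine position
#' with methylated (#Cs) and unmethylated (#Ts) read counts. Positions are
#' 0-based internally; file readers convert from the 1-based dialects at the
#' I/O boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions.
#' @param strand character vector, "+" or "-".
#' @param context methylation context, one of "CG", "CHG", "CHH".
#' @param meth,unmeth non-negative integer read counts.
#' @return A `data.frame` with the six columns above.
#' @export
cytosine_calls <- function(chrom, pos, strand, context, meth, unmeth) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), length(strand) %in% c(1L, n))
  if (any(meth < 0) || any(unmeth < 0))
    stop("methylated/unmethylated counts must be non-negative")
  bad <- !context %in% CONTEXTS
  if (any(bad))
    stop("unknown context label(s): ", paste(unique(context[bad]), collapse = ", "))
  if (any(strand != "+" & strand != "-"))
    stop("strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             strand = strand, context = context,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             stringsAsFactors = FALSE)
}

#' Construct a methylome sample
#'
#' Bundles a sample's cytosine calls with its metadata (sex, genotype,
#' planting site). The (chrom, pos, strand) keys must be unique.
#'
#' @param sample_id character scalar.
#' @param calls a call table as built by [cytosine_calls()].
#' @param sex one of "F", "M", "unknown".
#' @param genotype,site character scalars (may be `NA`).
#' @return An object of class `methylome_sample`.
#' @export
methylome_sample <- function(sample_id, calls, sex = "unknown",
                             genotype = NA_character_, site = NA_character_) {
  sex <- match.arg(sex, SEXES)
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, strand) keys in calls for sample ", sample_id)
  structure(list(sample_id = sample_id, sex = sex, genotype = genotype,
                 site = site, calls = calls),
            class = "methylome_sample")
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat("<methylome_sample>", x$sample_id,
      sprintf("(sex=%s, genotype=%s, site=%s)\n", x$sex, x$genotype, x$site))
  cat(" ", nrow(x$calls), "cytosine calls;",
      "contexts:", paste(names(table(x$calls$context)), collapse = "/"), "\n")
  invisible(x)
}

#' Per-cytosine methylation ratio
#'
#' The methylation level of a cytosine is #Cs / (#Cs + #Ts). A position with
#' zero coverage has an *undefined* ratio (`NA`), never 0: treating it as 0
#' would bias downstream averages.
#'
#' @param meth,unmeth counts of methylated (#Cs) and unmethylated (#Ts) reads.
#' @return Numeric vector in `[0, 1]`, `NA` where coverage is zero.
#' @export
methylation_ratio <- function(meth, unmeth) {
  cov <- meth + unmeth
  out <- ifelse(cov > 0, meth / cov, NA_real_)
  as.numeric(out)
}

#' Coverage filter
#'
#' Retains calls with coverage *strictly greater* than `min_coverage`
#' (the usual pre-filter keeps bases with coverage >10x, so a call at
#' exactly 10x is removed).
#'
#' @param sample a [methylome_sample()].
#' @param min_coverage non-negative integer threshold; default 10.
#' @return A filtered `methylome_sample`.
#' @export
filter_coverage <- function(sample, min_coverage = 10L) {
  stopifnot(min_coverage >= 0)
  keep <- (sample$calls$meth + sample$calls$unmeth) > min_coverage
  sample$calls <- sample$calls[keep, , drop = FALSE]
  rownames(sample$calls) <- NULL
  sample
}

#' Split a sample by methylation context
#'
#' Plant methylation machinery treats CG, CHG and CHH cytosines differently,
#' so all downstream analyses run per context. Returns the three disjoint
#' sub-samples; their sizes sum to the input size.
#'
#' @param sample a [methylome_sample()].
#' @return Named list of three `methylome_sample`s (`CG`, `CHG`, `CHH`).
#' @export
split_by_context <- function(sample) {
  ctx <- sample$calls$context
  if (anyNA(ctx)) stop("calls with missing context label")
  out <- lapply(CONTEXTS, function(cc) {
    s <- sample
    s$calls <- sample$calls[ctx == cc, , drop = FALSE]
    rownames(s$calls) <- NULL
    s
  })
  names(out) <- CONTEXTS
  out
}

#' Merge symmetric CpG dyads
#'
#' Optionally sums the counts of the two strands of a CpG dyad (position p on
#' "+" and p+1 on "-") into a single per-dyad call on the "+" strand. Off by
#' default throughout the package; whether to merge is a user decision.
#'
#' @param sample a `methylome_sample` whose CG calls are per-strand.
#' @return A `methylome_sample` with merged CG calls.
#' @export
merge_cpg_dyads <- function(sample) {
  calls <- sample$calls
  is_cg <- calls$context == "CG"
  cg <- calls[is_cg, , drop = FALSE]
  other <- calls[!is_cg, , drop = FALSE]
  # dyad anchor: "+" strand position; "-" strand CG at p belongs to dyad p-1
  anchor <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
  key <- paste(cg$chrom, anchor)
  meth <- tapply(cg$meth, key, sum)
  unmeth <- tapply(cg$unmeth, key, sum)
  first <- !duplicated(key)
  merged <- data.frame(chrom = cg$chrom[first], pos = anchor[first],
                       strand = "+", context = "CG",
                       meth = as.integer(meth[key[first]]),
                       unmeth = as.integer(unmeth[key[first]]),
                       stringsAsFactors = FALSE)
  calls <- rbind(merged, other)
  calls <- calls[order(calls$chrom, calls$pos, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  sample$calls <- calls
  sample
}

# ---- file dialects ----------------------------------------------------------

#' Read a Bismark-style methylation call file
#'
#' Two tab-separated dialects are auto-detected from the column count:
#' the 6-column coverage dialect (chrom, start, end, methylation %, count
#' methylated, count unmethylated; 1-based inclusive coordinates, no context)
#' and the 7-column cytosine/CX-report dialect (chrom, position, strand,
#' count methylated, count unmethylated, context, trinucleotide; 1-based).
#' Coordinates are converted to the internal 0-based convention. The coverage
#' dialect carries no context, so a `context_map` must be supplied for it.
#'
#' @param path file path (plain or gzip; `read.table` handles both).
#' @param context_map optional `data.frame` with columns chrom, pos (0-based),
#'   strand, context, used to annotate coverage-dialect calls.
#' @param sample_id,sex,genotype,site sample metadata (default: file basename).
#' @return A [methylome_sample()].
#' @export
read_coverage_file <- function(path, context_map = NULL,
                               sample_id = sub("\\.(cov|txt|tsv)(\\.gz)?$", "",
                                               basename(path)),
                               sex = "unknown", genotype = NA_character_,
                               site = NA_character_) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e)
    stop("cannot read '", path, "': ", conditionMessage(e)))
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty methylation call file: ", path)
    return(methylome_sample(sample_id,
                            cytosine_calls(character(0), integer(0),
                                           character(0), character(0),
                                           integer(0), integer(0)),
                            sex = sex, genotype = genotype, site = site))
  }
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = NA, quote = "", comment.char = ""),
    error = function(e) stop("malformed call file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(tab) == 6L) {
    # coverage dialect: chrom start end pct meth unmeth (1-based inclusive)
    if (!is.numeric(tab[[2]]) || !is.numeric(tab[[5]]) || !is.numeric(tab[[6]]))
      stop("malformed coverage row in '", path, "'")
    pos0 <- as.integer(tab[[2]]) - 1L
    if (is.null(context_map))
      stop("coverage dialect has no context column; supply context_map ",
           "(see read_coverage_file)")
    idx <- match(paste(tab[[1]], pos0), paste(context_map$chrom, context_map$pos))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop("position ", tab[[1]][miss], ":", pos0[miss],
           " absent from context_map (line ", miss, ")")
    }
    calls <- cytosine_calls(tab[[1]], pos0,
                            context_map$strand[idx], context_map$context[idx],
                            tab[[5]], tab[[6]])
  } else if (ncol(tab) >= 7L) {
    # CX / cytosine report dialect: chrom pos strand meth unmeth context tri
    bad <- which(!tab[[6]] %in% CONTEXTS)
    if (length(bad))
      stop("malformed context '", tab[[6]][bad[1]], "' at line ", bad[1],
           " of '", path, "'")
    calls <- cytosine_calls(tab[[1]], as.integer(tab[[2]]) - 1L,
                            tab[[3]], tab[[6]], tab[[4]], tab[[5]])
  } else {
    stop("unrecognised call-file dialect (", ncol(tab), " columns) in '",
         path, "'")
  }
  methylome_sample(sample_id, calls, sex = sex, genotype = genotype,
                   site = site)
}

#' Write a methylome sample to a Bismark-style file
#'
#' @param sample a [methylome_sample()].
#' @param path output path; a ".gz" suffix triggers gzip compression.
#' @param format "cytosine_report" (7-column CX dialect, self-contained,
#'   default) or "coverage" (6-column dialect; context is not stored and
#'   zero-coverage calls are dropped, as in the original format).
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(sample, path,
                                format = c("cytosine_report", "coverage")) {
  format <- match.arg(format)
  calls <- sample$calls
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (format == "coverage") {
    cov <- calls$meth + calls$unmeth
    calls <- calls[cov > 0, , drop = FALSE]
    pct <- formatC(100 * calls$meth / (calls$meth + calls$unmeth),
                   format = "f", digits = 6)
    lines <- paste(calls$chrom, calls$pos + 1L, calls$pos + 1L, pct,
                   calls$meth, calls$unmeth, sep = "\t")
  } else {
    tri <- ifelse(calls$context == "CG", "CGA",
                  ifelse(calls$context == "CHG", "CAG", "CAA"))
    lines <- paste(calls$chrom, calls$pos + 1L, calls$strand, calls$meth,
                   calls$unmeth, calls$context, tri, sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header columns `sample`, `sex`, `genotype`, `site`.
#'
#' @param path file path.
#' @return A `data.frame` with those four character columns.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("sample", "sex", "genotype", "site")
  if (!all(need %in% names(md)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  bad <- !md$sex %in% SEXES
  if (any(bad)) stop("invalid sex label(s): ", paste(md$sex[bad], collapse = ", "))
  md[need]
}
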