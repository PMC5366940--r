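# Synthetic bisulfite methylome generator. Emulates a two-sex, two-garden
# clonal cohort with genome-wide background methylation and one planted
# sex-linked differentially methylated gene on the sex-determining-region
# (SDR) chromosome, so the full analysis pipeline can be exercised and
# validated against known ground truth.

#' Build a synthetic genome layout
#'
#' Creates chromosomes, randomly placed cytosine sites with strand and
#' context labels, and a panel of genes on the SDR chromosome (the last
#' chromosome by default). One gene of the panel is flagged as the SDR gene
#' and is given six exons, so that introns 1, 4 and 5 exist to carry the
#' planted feature-specific methylation pattern.
#'
#' @param n_chrom number of chromosomes (default 19, a poplar-sized karyotype).
#' @param chrom_length chromosome length in bp (scalar or length `n_chrom`).
#' @param cytosine_density cytosine sites per kb.
#' @param genes_per_chrom integer vector (recycled) of gene counts per
#'   chromosome; default places a 13-gene panel on the last chromosome only.
#' @param promoter_width promoter window width, bp.
#' @param seed RNG seed; layouts are reproducible.
#' @return An object of class `genome_layout` with fields `chromosomes`
#'   (data.frame name/length), `sites` (chrom, pos, strand, context),
#'   `annotation` (a [gene_annotation()]), `sdr_gene`, `sdr_chrom`.
#' @export
build_genome <- function(n_chrom = 19L, chrom_length = 60000L,
                         cytosine_density = 25, genes_per_chrom = NULL,
                         promoter_width = 2000L, seed = 1L) {
  stopifnot(n_chrom >= 1, all(chrom_length > 0), cytosine_density > 0)
  chrom_length <- as.integer(rep_len(chrom_length, n_chrom))
  chrom_names <- paste0("Chr", seq_len(n_chrom))
  if (is.null(genes_per_chrom)) {
    genes_per_chrom <- rep(0L, n_chrom)
    genes_per_chrom[n_chrom] <- 13L
  }
  genes_per_chrom <- as.integer(rep_len(genes_per_chrom, n_chrom))
  sdr_chrom_i <- if (any(genes_per_chrom > 0)) max(which(genes_per_chrom > 0)) else NA_integer_
  set.seed(seed)
  sites <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    n <- max(1L, round(chrom_length[i] * cytosine_density / 1000))
    if (n > chrom_length[i]) stop("cytosine_density exceeds 1 site per bp")
    pos <- sort(sample.int(chrom_length[i], n)) - 1L
    data.frame(chrom = chrom_names[i], pos = pos,
               strand = sample(c("+", "-"), n, replace = TRUE),
               context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE,
                                prob = c(0.3, 0.3, 0.4)),
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL

  # deterministic gene geometry: genes evenly slotted along the chromosome,
  # each slot holding a promoter window plus the transcribed body
  genes <- list()
  sdr_gene <- NA_character_
  for (i in which(genes_per_chrom > 0)) {
    ng <- genes_per_chrom[i]
    slot <- (chrom_length[i] - promoter_width) %/% ng
    for (j in seq_len(ng)) {
      is_sdr <- (i == sdr_chrom_i) && j == ((ng + 1L) %/% 2L)
      gid <- if (i == sdr_chrom_i) sprintf("SDRG%02d", j)
             else sprintf("G%02d.%02d", i, j)
      if (is_sdr) {
        exon_len <- rep(100L, 6L)
        intron_len <- c(700L, 100L, 100L, 500L, 300L)
        sdr_gene <- gid
      } else {
        exon_len <- rep(150L, 3L)
        intron_len <- c(250L, 250L)
      }
      body <- sum(exon_len) + sum(intron_len)
      start <- promoter_width + (j - 1L) * slot
      if (start + body > chrom_length[i] || body + promoter_width > slot)
        stop("gene ", gid, " does not fit: slot ", slot, " bp, need ",
             body + promoter_width, " bp")
      bounds <- start + cumsum(c(0L, as.vector(rbind(exon_len,
                                                     c(intron_len, 0L)))))
      ex <- cbind(bounds[seq(1, by = 2, length.out = length(exon_len))],
                  bounds[seq(2, by = 2, length.out = length(exon_len))])
      genes[[gid]] <- gene_model(gid, chrom_names[i], "+", ex,
                                 promoter_width = promoter_width)
    }
  }
  structure(list(chromosomes = data.frame(name = chrom_names,
                                          length = chrom_length,
                                          stringsAsFactors = FALSE),
                 sites = sites,
                 annotation = gene_annotation(genes),
                 sdr_gene = sdr_gene,
                 sdr_chrom = if (is.na(sdr_chrom_i)) NA_character_
                             else chrom_names[sdr_chrom_i],
                 promoter_width = promoter_width, seed = seed),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout>", nrow(x$chromosomes), "chromosomes,",
      nrow(x$sites), "cytosine sites,", length(x$annotation$genes),
      "genes; SDR gene:", x$sdr_gene, "\n")
  invisible(x)
}

#' Methylation effect specification
#'
#' Describes the target methylation level of a genomic region, per sex, for
#' the simulator. Counts are drawn beta-binomially around the (logit-
#' adjusted) level with dispersion `rho`; `rho = 0` gives exact binomial
#' sampling.
#'
#' @param label free-text label ("background", "SDR-intron1", ...).
#' @param level_f,level_m methylation fraction in `[0, 1]` for females/males.
#' @param gene,feature reference a gene-feature interval ("promoter",
#'   "intron_1", "exon_2", ...) of the layout's annotation; or
#' @param region alternative explicit interval `list(chrom, start, end)`
#'   (0-based half-open).
#' @param contexts contexts the effect applies to.
#' @param rho beta-binomial dispersion (> 0, or 0 for pure binomial).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(label, level_f, level_m, gene = NULL, feature = NULL,
                        region = NULL, contexts = c("CG", "CHG", "CHH"),
                        rho = 0.05) {
  stopifnot(level_f >= 0, level_f <= 1, level_m >= 0, level_m <= 1, rho >= 0)
  if (label != "background" && is.null(region) && (is.null(gene) || is.null(feature)))
    stop("effect '", label, "' needs either gene+feature or region")
  structure(list(label = label, level_f = level_f, level_m = level_m,
                 gene = gene, feature = feature, region = region,
                 contexts = contexts, rho = rho),
            class = "effect_spec")
}

#' Default planted effects for a layout
#'
#' Genome-wide background methylation plus the planted SDR-gene pattern:
#' promoter and intron 1 strongly male-biased, intron 4 strongly methylated
#' in both sexes, intron 5 unmethylated in both sexes, and five weakly
#' sex-biased 500 bp regions scattered on non-SDR chromosomes.
#'
#' @param layout a [build_genome()] layout with an SDR gene.
#' @param background background methylation level (both sexes).
#' @param rho beta-binomial dispersion for all effects.
#' @return List of [effect_spec()]s.
#' @export
default_effects <- function(layout, background = 0.15, rho = 0.05) {
  g <- layout$sdr_gene
  if (is.na(g)) stop("layout has no SDR gene")
  eff <- list(
    effect_spec("background", background, background, rho = rho),
    effect_spec("SDR-promoter", 0.30, 0.80, gene = g, feature = "promoter",
                rho = rho),
    effect_spec("SDR-intron1", 0.20, 0.70, gene = g, feature = "intron_1",
                rho = rho),
    effect_spec("SDR-intron4", 0.90, 0.90, gene = g, feature = "intron_4",
                rho = rho),
    effect_spec("SDR-intron5", 0.02, 0.02, gene = g, feature = "intron_5",
                rho = rho))
  off_sdr <- setdiff(layout$chromosomes$name, layout$sdr_chrom)
  for (k in seq_len(min(5L, length(off_sdr)))) {
    eff[[length(eff) + 1L]] <- effect_spec(
      paste0("weak-", k), 0.15, 0.30, rho = rho,
      region = list(chrom = off_sdr[k], start = 10000L, end = 10500L))
  }
  eff
}

#' Cohort specification for the simulator
#'
#' The default mirrors a two-garden common-garden clone trial at reduced
#' scale: 9 female and 11 male genotypes, each clonally replicated at two
#' sites, giving 40 xylem samples. Genotype identity adds a random intercept
#' on the logit-methylation scale; the second site adds a fixed shift.
#'
#' @param n_female,n_male numbers of genotypes per sex.
#' @param sites site labels; every genotype is sampled at every site.
#' @param coverage_mean,coverage_size negative-binomial per-site read
#'   coverage model.
#' @param genotype_sd SD of the genotype random effect (logit scale).
#' @param site_effect additive logit shift of the second and later sites.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female = 9L, n_male = 11L, sites = c("PA", "IH"),
                        coverage_mean = 30, coverage_size = 10,
                        genotype_sd = 0.3, site_effect = 0.1, seed = 1L) {
  stopifnot(n_female >= 1, n_male >= 1, coverage_mean > 0,
            length(sites) >= 1)
  structure(list(n_female = as.integer(n_female), n_male = as.integer(n_male),
                 sites = sites, coverage_mean = coverage_mean,
                 coverage_size = coverage_size, genotype_sd = genotype_sd,
                 site_effect = site_effect, seed = seed),
            class = "cohort_spec")
}

# resolve an effect to site indices of the layout
resolve_effect_sites <- function(layout, eff) {
  s <- layout$sites
  in_ctx <- s$context %in% eff$contexts
  if (eff$label == "background" && is.null(eff$region) && is.null(eff$gene))
    return(which(in_ctx))
  if (!is.null(eff$region)) {
    r <- eff$region
    if (!r$chrom %in% layout$chromosomes$name)
      stop("effect '", eff$label, "' references unknown chromosome ", r$chrom)
    return(which(in_ctx & s$chrom == r$chrom & s$pos >= r$start & s$pos < r$end))
  }
  g <- layout$annotation$genes[[eff$gene]]
  if (is.null(g))
    stop("effect '", eff$label, "' references unknown gene ", eff$gene)
  ft <- gene_features(g)
  row <- ft[ft$feature == eff$feature, ]
  if (nrow(row) != 1L)
    stop("effect '", eff$label, "' references missing feature ", eff$feature,
         " of gene ", eff$gene)
  which(in_ctx & s$chrom == row$chrom & s$pos >= row$start & s$pos < row$end)
}

#' Simulate a methylome cohort
#'
#' Draws per-site coverage from the cohort's negative-binomial model and
#' methylated counts beta-binomially around the applicable effect level,
#' adjusted on the logit scale for the sample's genotype and site. Effects
#' later in the list override earlier ones on their target sites, so the
#' background effect comes first.
#'
#' @param layout a [build_genome()] layout.
#' @param cohort a [cohort_spec()].
#' @param effects list of [effect_spec()]s; default [default_effects()].
#' @return List of [methylome_sample()]s (one per genotype x site), each
#'   carrying sex/genotype/site metadata. Deterministic for a fixed seed.
#' @export
simulate_cohort <- function(layout, cohort = cohort_spec(),
                            effects = default_effects(layout)) {
  s <- layout$sites
  n_sites <- nrow(s)
  lev_f <- rep(0, n_sites)
  lev_m <- rep(0, n_sites)
  rho <- rep(0, n_sites)
  for (eff in effects) {
    idx <- resolve_effect_sites(layout, eff)
    lev_f[idx] <- eff$level_f
    lev_m[idx] <- eff$level_m
    rho[idx] <- eff$rho
  }

  genotypes <- c(sprintf("F%02d", seq_len(cohort$n_female)),
                 sprintf("M%02d", seq_len(cohort$n_male)))
  sex_of <- c(rep("F", cohort$n_female), rep("M", cohort$n_male))

  set.seed(cohort$seed)
  u_geno <- rnorm(length(genotypes), 0, cohort$genotype_sd)
  site_shift <- (seq_along(cohort$sites) - 1L) * cohort$site_effect

  samples <- list()
  for (gi in seq_along(genotypes)) {
    base <- if (sex_of[gi] == "F") lev_f else lev_m
    for (si in seq_along(cohort$sites)) {
      # logit-scale adjustment; exact 0/1 levels stay exact
      interior <- base > 0 & base < 1
      p <- base
      p[interior] <- plogis(qlogis(base[interior]) + u_geno[gi] + site_shift[si])
      cov <- rnbinom(n_sites, size = cohort$coverage_size,
                     mu = cohort$coverage_mean)
      pb <- p
      bb <- interior & rho > 0
      if (any(bb)) {
        a <- p[bb] * (1 - rho[bb]) / rho[bb]
        b <- (1 - p[bb]) * (1 - rho[bb]) / rho[bb]
        pb[bb] <- rbeta(sum(bb), a, b)
      }
      meth <- rbinom(n_sites, cov, pb)
      sid <- paste0(genotypes[gi], "_", cohort$sites[si])
      samples[[sid]] <- methylome_sample(
        sid,
        cytosine_calls(s$chrom, s$pos, s$strand, s$context,
                       meth, cov - meth),
        sex = sex_of[gi], genotype = genotypes[gi],
        site = cohort$sites[si])
    }
  }
  samples
}

#' Write a simulated cohort as an on-disk fixture
#'
#' Produces one Bismark-style call file per sample, one GFF3 with the gene
#' models, and one sample metadata table; the files round-trip exactly
#' through [read_coverage_file()], [read_gff3()] and
#' [read_sample_metadata()].
#'
#' @param samples list of [methylome_sample()]s.
#' @param layout the generating [build_genome()] layout.
#' @param dir output directory (created if needed).
#' @param format call-file dialect, see [write_coverage_file()].
#' @param gzip compress call files.
#' @param force overwrite an existing non-empty directory.
#' @return Character vector of the `length(samples) + 2` files written
#'   (the manifest), invisibly.
#' @export
write_fixture <- function(samples, layout, dir,
                          format = c("cytosine_report", "coverage"),
                          gzip = FALSE, force = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- paste0(if (format == "coverage") ".cov.tsv" else ".cx.tsv",
                if (gzip) ".gz" else "")
  paths <- character(0)
  for (smp in samples) {
    p <- file.path(dir, paste0(smp$sample_id, ext))
    write_coverage_file(smp, p, format = format)
    paths <- c(paths, p)
  }
  gff <- file.path(dir, "genes.gff3")
  write_gff3(layout$annotation, gff)
  md <- data.frame(sample = vapply(samples, `[[`, "", "sample_id"),
                   sex = vapply(samples, `[[`, "", "sex"),
                   genotype = vapply(samples, `[[`, "", "genotype"),
                   site = vapply(samples, `[[`, "", "site"),
                   stringsAsFactors = FALSE)
  mdp <- file.path(dir, "metadata.tsv")
  write.table(md, mdp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, gff, mdp))
}
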