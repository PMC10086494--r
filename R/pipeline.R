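#' Filter sites of a haplotype matrix
#'
#' Applies the standard chip-site filters to an already-loaded matrix:
#' minor allele frequency strictly above `maf_min`, missing rate strictly
#' below `missing_max`, and optionally SNVs only. Filters commute, so the
#' order in which they are applied does not matter.
#'
#' @param m A [haplotype_matrix()].
#' @param maf_min MAF threshold (strict `>`); `0` disables.
#' @param missing_max Missing-rate threshold (strict `<`).
#' @param snv_only Keep single-nucleotide variants only.
#' @return A filtered [haplotype_matrix()].
#' @export
filter_sites <- function(m, maf_min = 0.05, missing_max = 0.01, snv_only = TRUE) {
  af <- m$sites$alt_frequency
  maf <- pmin(af, 1 - af)
  keep <- m$sites$missing_rate < missing_max
  if (maf_min > 0) keep <- keep & !is.nan(maf) & maf > maf_min
  if (snv_only) keep <- keep & nchar(m$sites$ref) == 1L & nchar(m$sites$alt) == 1L
  subset_sites(m, keep)
}

# Clinical comparison of carriers vs the rest of a phenotype table.
.clinical_report <- function(pheno, carrier_ids) {
  pheno$carrier <- as.integer(pheno$sample %in% carrier_ids)
  car <- pheno[pheno$carrier == 1L, ]
  bg <- pheno[pheno$carrier == 0L, ]
  if (nrow(car) < 2L || nrow(bg) < 2L)
    stop("need at least two carriers and two background samples with phenotypes")
  welch_var <- function(v) {
    welch_t_summary(mean(car[[v]], na.rm = TRUE), stats::sd(car[[v]], na.rm = TRUE),
                    sum(!is.na(car[[v]])),
                    mean(bg[[v]], na.rm = TRUE), stats::sd(bg[[v]], na.rm = TRUE),
                    sum(!is.na(bg[[v]])))
  }
  cont <- c("age", "sbp", "dbp", "urate", "creatinine_mg_dl", "acr")
  cont <- cont[cont %in% names(pheno)]
  welch <- lapply(stats::setNames(cont, cont), welch_var)
  sex_tab <- contingency_table(sum(car$sex == "male"), sum(car$sex == "female"),
                               sum(bg$sex == "male"), sum(bg$sex == "female"))
  out <- list(
    n_carriers = nrow(car), n_background = nrow(bg),
    welch = lapply(welch, function(w) list(t = w$t, df = w$df, p = w$p_two_sided)),
    sex_fisher = fisher_exact_2x2(sex_tab)$p_two_sided
  )
  if (all(c("time", "event") %in% names(pheno)) && sum(car$event) > 0) {
    km <- km_curve(car$time, car$event)
    out$km_median <- km$median
    if (nlevels(droplevels(factor(car$sex))) == 2L)
      out$logrank_sex_p <- logrank_test(car$time, car$event, car$sex)$p
  }
  out
}

#' Run the full founder-evidence pipeline
#'
#' Ties the stages together in the standard analysis order: load phased
#' genotypes, locate heterozygous carriers of the focal variant, fit the
#' shared founder core on the common-SNV matrix, test rare tagging variants
#' in a window around the focal site, and (when a phenotype table is given)
#' compute the clinical comparison statistics. Writes a report bundle:
#' `summary.json` (round-trippable config plus all results), `tags.tsv`,
#' `match_matrix.tsv` and `log.txt`.
#'
#' @param vcf Path to a phased VCF.
#' @param focal A [variant_record()] or a `chrom:pos:ref:alt` string.
#' @param out_dir Output directory (created if needed).
#' @param region Optional `list(chrom, start, end)`, half-open.
#' @param pheno Optional path to a phenotype TSV with columns as in
#'   [simulate_clinical()].
#' @param maf_min,missing_max Common-site filters for the haplotype matrix.
#' @param rare_max Rarity threshold for tagging variants.
#' @param window_bp Tagging window width (bp).
#' @param tolerance Per-direction mismatch budget for extents.
#' @param one_per_family Optional retained carrier IDs for the tag report.
#' @return Invisibly, a list with `core` (the [founder_core()] fit), `tags`,
#'   `clinical` (or `NULL`) and `paths`.
#' @export
run_pipeline <- function(vcf, focal, out_dir, region = NULL, pheno = NULL,
                         maf_min = 0.05, missing_max = 0.01,
                         rare_max = 0.005, window_bp = 1e6, tolerance = 0L,
                         one_per_family = NULL) {
  if (is.character(focal)) focal <- parse_variant_id(focal)
  config <- list(vcf = vcf, focal = format_variant_id(focal),
                 region = region, pheno = pheno, maf_min = maf_min,
                 missing_max = missing_max, rare_max = rare_max,
                 window_bp = window_bp, tolerance = tolerance,
                 one_per_family = one_per_family)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  m_all <- read_phased_vcf(vcf, region = region, maf_min = 0,
                           missing_max = 1, snv_only = FALSE)
  carriers <- focal_carriers(m_all, focal)
  m_common <- filter_sites(m_all, maf_min, missing_max, snv_only = TRUE)
  fit <- founder_core(m_common, focal, tolerance = tolerance,
                      carriers = carriers)
  rare <- select_rare_window(m_all, focal, window_bp, rare_max,
                             exclude = carriers)
  tags <- tag_report(m_all, carriers, rare, one_per_family)

  clinical <- NULL
  if (!is.null(pheno)) {
    ph <- utils::read.delim(pheno, stringsAsFactors = FALSE)
    clinical <- .clinical_report(ph, carriers$carriers$sample)
  }

  paths <- list(
    summary = file.path(out_dir, "summary.json"),
    tags = file.path(out_dir, "tags.tsv"),
    match_matrix = file.path(out_dir, "match_matrix.tsv"),
    log = file.path(out_dir, "log.txt")
  )
  utils::write.table(tags, paths$tags, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_match_matrix(fit, paths$match_matrix)
  summary_obj <- list(
    config = config,
    carriers = carriers$carriers,
    core = list(
      interval = as.list(fit$core$core_interval),
      n_sites = nrow(fit$core$core_sites),
      background_matches = fit$core$background_matches,
      background_total = fit$core$background_total,
      frequency_text = fit$core$frequency_text
    ),
    extents = fit$extents,
    tags = tags,
    clinical = clinical
  )
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       digits = NA, na = "null")
  writeLines(c(
    paste("foundertrace", as.character(utils::packageVersion("foundertrace"))),
    paste("R", as.character(getRversion())),
    paste("date", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste("config", jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"))
  ), paths$log)
  invisible(list(core = fit, tags = tags, clinical = clinical, paths = paths))
}
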