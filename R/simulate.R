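#' Configuration for the founder-descent simulator
#'
#' Describes a cohort in which a set of carriers all inherit a focal variant
#' from one founder `generations` meioses back, so each carrier retains the
#' founder's chromosome on a recombination-delimited segment around the focal
#' site, while the rest of the cohort forms an unrelated background pool.
#' Default values emulate the statistical structure of a biobank-scale
#' founder-variant study: 9 heterozygous carriers against 2,500 background
#' samples (5,000 background haplotypes), a ~36 Mb region of common chip
#' sites around the focal position, four rare tagging variants at 0.3%
#' background frequency riding the founder haplotype, and a uniform 1 cM/Mb
#' recombination map.
#'
#' @param generations Meioses separating each carrier from the founder
#'   (g >= 1); one-sided ancestral segments are Exponential with mean
#'   `100/g` cM under the Haldane (no-interference) model.
#' @param n_carriers Number of heterozygous carriers.
#' @param n_background Number of non-carrier background samples
#'   (2 haplotypes each).
#' @param chrom,region_start,region_end Simulated region (1-based bp).
#' @param cM_per_Mb Uniform recombination rate; `0` means no recombination
#'   (every carrier shares the founder haplotype across the whole region).
#' @param n_common_sites Number of common biallelic SNVs.
#' @param common_freq_range Range of common-site alt frequencies
#'   (drawn Uniform).
#' @param n_rare_tags Number of rare tagging variants planted within
#'   `tag_window_bp` of the focal site.
#' @param rare_tag_freq Background alt frequency of each rare tag.
#' @param p_tag_on_founder Probability a tag rides the founder haplotype
#'   (1 = perfect linkage; 0 = unlinked null tags).
#' @param tag_window_bp Total width of the window holding the tags.
#' @param focal_pos,focal_ref,focal_alt The focal variant; the default is a
#'   synthetic complex delins.
#' @return An object of class `founder_sim_config`.
#' @export
founder_sim_config <- function(generations = 10, n_carriers = 9,
                               n_background = 2500, chrom = "16",
                               region_start = 2e6, region_end = 38e6,
                               cM_per_Mb = 1, n_common_sites = 400,
                               common_freq_range = c(0.05, 0.5),
                               n_rare_tags = 4, rare_tag_freq = 0.003,
                               p_tag_on_founder = 1, tag_window_bp = 1e6,
                               focal_pos = 20360000,
                               focal_ref = "TCTGCCCCGAAG",
                               focal_alt = "CCGCCTCCT") {
  cfg <- list(generations = generations, n_carriers = n_carriers,
              n_background = n_background, chrom = as.character(chrom),
              region_start = region_start, region_end = region_end,
              cM_per_Mb = cM_per_Mb, n_common_sites = n_common_sites,
              common_freq_range = common_freq_range,
              n_rare_tags = n_rare_tags, rare_tag_freq = rare_tag_freq,
              p_tag_on_founder = p_tag_on_founder,
              tag_window_bp = tag_window_bp, focal_pos = focal_pos,
              focal_ref = toupper(focal_ref), focal_alt = toupper(focal_alt))
  if (cfg$generations < 1) stop("generations must be >= 1")
  if (cfg$n_carriers < 1) stop("need at least one carrier")
  if (cfg$focal_pos <= cfg$region_start || cfg$focal_pos >= cfg$region_end)
    stop("focal position must lie inside the region")
  if (any(cfg$common_freq_range <= 0) || any(cfg$common_freq_range >= 1) ||
      (cfg$n_rare_tags > 0 && (cfg$rare_tag_freq <= 0 || cfg$rare_tag_freq >= 1)))
    stop("allele frequencies must lie in (0, 1)")
  if (cfg$p_tag_on_founder < 0 || cfg$p_tag_on_founder > 1)
    stop("p_tag_on_founder must lie in [0, 1]")
  if (cfg$cM_per_Mb < 0) stop("cM_per_Mb must be non-negative")
  class(cfg) <- "founder_sim_config"
  cfg
}

# Distinct random integer positions in [lo, hi], excluding `avoid`.
.draw_positions <- function(n, lo, hi, avoid = integer(0)) {
  pos <- integer(0)
  while (length(pos) < n) {
    cand <- unique(as.integer(round(stats::runif(2L * (n - length(pos)) + 10L, lo, hi))))
    cand <- setdiff(cand, c(avoid, pos))
    pos <- c(pos, cand)
  }
  sort(pos[seq_len(n)])
}

#' Simulate a founder cohort with recombination
#'
#' Generates phased genotypes for `n_carriers` heterozygous carriers of the
#' focal variant descending from one founder, plus an unrelated background
#' pool, together with the ground truth needed to validate downstream
#' analyses. Mechanics, per carrier: the distances from the focal site to the
#' ends of the retained ancestral segment are independent Exponential with
#' mean `1/g` Morgans (Haldane model, uniform `cM_per_Mb` map), truncated at
#' the region edges; within the segment the carrier's focal haplotype copies
#' the founder haplotype, outside it (and on the second haplotype) alleles
#' are fresh background draws. Background haplotypes are drawn per site
#' independently from the site's allele frequency. Rare tags are placed on
#' the founder haplotype with probability `p_tag_on_founder` and at
#' `rare_tag_freq` on background haplotypes. Fully deterministic given
#' `seed`: the same seed yields a byte-identical VCF.
#'
#' @param config A [founder_sim_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes `sim.vcf` (phased),
#'   `truth.json` and returns their paths alongside the objects.
#' @return List with `matrix` (a [haplotype_matrix()]), `truth` (class
#'   `founder_sim_truth`: `founder` alleles, `segments` data frame with the
#'   true ancestral interval `[start, end]` per carrier, `tag_positions`,
#'   `focal`, `seed`, `config`) and, with `out_dir`, `paths`.
#' @export
simulate_founder_cohort <- function(config, seed, out_dir = NULL) {
  stopifnot(inherits(config, "founder_sim_config"))
  set.seed(seed)
  cfg <- config

  tag_lo <- max(cfg$region_start, cfg$focal_pos - cfg$tag_window_bp / 2)
  tag_hi <- min(cfg$region_end, cfg$focal_pos + cfg$tag_window_bp / 2)
  tag_pos <- if (cfg$n_rare_tags > 0)
    .draw_positions(cfg$n_rare_tags, tag_lo, tag_hi, avoid = cfg$focal_pos)
  else integer(0)
  common_pos <- .draw_positions(cfg$n_common_sites, cfg$region_start,
                                cfg$region_end, avoid = c(cfg$focal_pos, tag_pos))

  pos <- as.integer(c(common_pos, tag_pos, cfg$focal_pos))
  kind <- c(rep("common", length(common_pos)), rep("tag", length(tag_pos)), "focal")
  freq <- c(stats::runif(length(common_pos), cfg$common_freq_range[1],
                         cfg$common_freq_range[2]),
            rep(cfg$rare_tag_freq, length(tag_pos)),
            0) # focal variant absent from the background pool
  ord <- order(pos)
  pos <- pos[ord]; kind <- kind[ord]; freq <- freq[ord]
  m_sites <- length(pos)
  focal_j <- which(kind == "focal")

  # founder haplotype: common sites from their frequencies, tags ride with
  # probability p_tag_on_founder, focal alt always present
  founder <- stats::rbinom(m_sites, 1L, freq)
  founder[kind == "tag"] <- stats::rbinom(sum(kind == "tag"), 1L,
                                          cfg$p_tag_on_founder)
  founder[focal_j] <- 1L

  bp_per_morgan <- if (cfg$cM_per_Mb > 0) 1e8 / cfg$cM_per_Mb else Inf
  draw_bg_hap <- function() stats::rbinom(m_sites, 1L, freq)

  n_car <- cfg$n_carriers
  seg <- data.frame(sample = character(n_car), start = numeric(n_car),
                    end = numeric(n_car), hap = integer(n_car),
                    stringsAsFactors = FALSE)
  alleles <- matrix(NA_integer_,
                    nrow = 2L * (n_car + cfg$n_background), ncol = m_sites)
  car_ids <- sprintf("CAR%03d", seq_len(n_car))
  bg_ids <- sprintf("BG%05d", seq_len(cfg$n_background))

  for (i in seq_len(n_car)) {
    left <- stats::rexp(1L, rate = cfg$generations) * bp_per_morgan
    right <- stats::rexp(1L, rate = cfg$generations) * bp_per_morgan
    a <- max(cfg$region_start, cfg$focal_pos - left)
    b <- min(cfg$region_end, cfg$focal_pos + right)
    hap_focal <- draw_bg_hap()
    inside <- pos >= a & pos <= b
    hap_focal[inside] <- founder[inside]
    hap_focal[focal_j] <- 1L # segment always contains the focal site
    hap_other <- draw_bg_hap()
    hap_other[focal_j] <- 0L
    which_hap <- stats::rbinom(1L, 1L, 0.5) + 1L
    r <- 2L * (i - 1L)
    if (which_hap == 1L) {
      alleles[r + 1L, ] <- hap_focal; alleles[r + 2L, ] <- hap_other
    } else {
      alleles[r + 1L, ] <- hap_other; alleles[r + 2L, ] <- hap_focal
    }
    seg$sample[i] <- car_ids[i]; seg$start[i] <- a; seg$end[i] <- b
    seg$hap[i] <- which_hap
  }
  if (cfg$n_background > 0) {
    nh <- 2L * cfg$n_background
    U <- matrix(stats::runif(nh * m_sites), nrow = nh)
    B <- 1L * (U < matrix(freq, nh, m_sites, byrow = TRUE))
    alleles[2L * n_car + seq_len(nh), ] <- B
  }

  base_ref <- c(common = "A", tag = "T", focal = cfg$focal_ref)
  base_alt <- c(common = "G", tag = "A", focal = cfg$focal_alt)
  sites <- data.frame(
    chrom = cfg$chrom, pos = pos, id = ".",
    ref = unname(base_ref[kind]), alt = unname(base_alt[kind]),
    stringsAsFactors = FALSE
  )
  m <- haplotype_matrix(c(car_ids, bg_ids), alleles, sites)
  truth <- structure(
    list(founder = stats::setNames(founder, pos), segments = seg,
         tag_positions = tag_pos,
         focal = variant_record(cfg$chrom, cfg$focal_pos, cfg$focal_ref,
                                cfg$focal_alt),
         seed = seed, config = cfg),
    class = "founder_sim_truth"
  )
  out <- list(matrix = m, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(out_dir, "sim.vcf")
    truth_path <- file.path(out_dir, "truth.json")
    write_phased_vcf(m, vcf_path)
    jsonlite::write_json(
      list(founder = as.integer(founder), positions = pos,
           segments = seg, tag_positions = tag_pos,
           focal = format_variant_id(truth$focal), seed = seed,
           config = unclass(cfg)),
      truth_path, auto_unbox = TRUE, digits = NA
    )
    out$paths <- list(vcf = vcf_path, truth = truth_path)
  }
  out
}

# Truncated-normal draws by rejection (narrow truncation only).
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate clinical phenotypes with a renal-survival endpoint
#'
#' Generates a per-sample phenotype table emulating an ADTKD-like cohort:
#' carriers draw a kidney-failure (renal replacement therapy) age from a
#' Normal(52, 10) distribution truncated to [30, 80]; non-carriers have a low
#' constant event hazard; everyone is censored at an independent uniform
#' age in [40, 85]. Blood pressure, creatinine and albuminuria get additive
#' or multiplicative carrier shifts scaled by `carrier_effect`; serum urate
#' has none (carriers and background share one distribution).
#' `carrier_effect = 0` removes all carrier/non-carrier differences,
#' including the survival endpoint, giving a null dataset for type-I-error
#' checks.
#'
#' @param n_carriers,n_background Group sizes.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param carrier_effect Effect scale (default 1; 0 = null).
#' @return Data frame with columns `sample`, `carrier`, `sex`, `age`,
#'   `time` (age at event/censoring), `event`, `creatinine_mg_dl`, `acr`,
#'   `sbp`, `dbp`, `urate`, `gout`.
#' @export
simulate_clinical <- function(n_carriers = 9, n_background = 491, seed = 1,
                              carrier_effect = 1) {
  set.seed(seed)
  n <- n_carriers + n_background
  carrier <- c(rep(1L, n_carriers), rep(0L, n_background))
  censor_age <- stats::runif(n, 40, 85)
  onset <- 1e-3 + stats::rexp(n, rate = 0.002) # low background hazard
  if (carrier_effect > 0 && n_carriers > 0)
    onset[carrier == 1L] <- .rtruncnorm(n_carriers, 52, 10, 30, 80)
  df <- data.frame(
    sample = sprintf("S%04d", seq_len(n)),
    carrier = carrier,
    sex = ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female"),
    age = round(stats::rnorm(n, 57.3, 8.0), 1),
    time = pmin(onset, censor_age),
    event = as.integer(onset <= censor_age),
    creatinine_mg_dl = stats::rlnorm(n, log(0.85), 0.15) *
      (1 + 0.35 * carrier_effect * carrier),
    acr = stats::rlnorm(n, log(1.0), 0.8) * (1 + 1.0 * carrier_effect * carrier),
    sbp = stats::rnorm(n, 144.2, 24.1) + 19.4 * carrier_effect * carrier,
    dbp = stats::rnorm(n, 86.4, 13.5) + 12.9 * carrier_effect * carrier,
    urate = stats::rnorm(n, 309.1, 80.4),
    gout = stats::rbinom(n, 1L, 0.02),
    stringsAsFactors = FALSE
  )
  df$time <- round(df$time, 3)
  df
}

#' Write a phenotype table as TSV
#'
#' @param df Data frame from [simulate_clinical()] (or of the same shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
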