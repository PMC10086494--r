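#' Haplotype matrix
#'
#' Phased genotypes as a matrix of 2N haplotypes (rows) by M biallelic sites
#' (columns). Entries are 0 (ref), 1 (alt) or `NA` (missing). Haplotypes
#' `2i - 1` and `2i` belong to sample `i`; sites are strictly increasing by
#' position within a chromosome.
#'
#' @param samples Character vector of N sample IDs.
#' @param alleles Integer matrix, 2N x M, entries in `{0, 1, NA}`.
#' @param sites Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`;
#'   `alt_frequency` and `missing_rate` are computed if absent.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(samples, alleles, sites) {
  samples <- as.character(samples)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(samples))
    stop("'alleles' must have two rows per sample")
  if (ncol(alleles) != nrow(sites))
    stop("'alleles' must have one column per site")
  if (any(!alleles %in% c(0L, 1L, NA_integer_)))
    stop("allele entries must be 0, 1 or NA")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    alleles <- alleles[, ord, drop = FALSE]
  }
  if (anyDuplicated(sites[c("chrom", "pos", "ref", "alt")]))
    stop("duplicate sites (same chrom, pos, ref, alt)")
  if (is.null(sites$alt_frequency))
    sites$alt_frequency <- colMeans(alleles == 1L, na.rm = TRUE)
  if (is.null(sites$missing_rate))
    sites$missing_rate <- colMeans(is.na(alleles))
  rownames(alleles) <- paste0(rep(samples, each = 2L), "_h", rep(1:2, length(samples)))
  rownames(sites) <- NULL
  structure(
    list(samples = samples, alleles = alleles, sites = sites),
    class = "haplotype_matrix"
  )
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", length(x$samples), "samples (",
      nrow(x$alleles), "haplotypes ) x", nrow(x$sites), "sites\n")
  if (nrow(x$sites) > 0L)
    cat("  region:", x$sites$chrom[1], ":", min(x$sites$pos), "-",
        max(x$sites$pos), "\n")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

# Internal: row indices of the two haplotypes of a sample.
.hap_row <- function(m, sample, hap) {
  i <- match(sample, m$samples)
  if (anyNA(i)) stop("unknown sample(s): ",
                     paste(sample[is.na(i)], collapse = ", "))
  2L * (i - 1L) + as.integer(hap)
}

#' Subset a haplotype matrix by site index
#'
#' @param m A [haplotype_matrix()].
#' @param idx Integer or logical index into the sites.
#' @return A [haplotype_matrix()] restricted to those sites.
#' @export
subset_sites <- function(m, idx) {
  haplotype_matrix(m$samples, m$alleles[, idx, drop = FALSE],
                   m$sites[idx, , drop = FALSE])
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Loads biallelic sites in a region, requiring phased GT fields (the `|`
#' separator), and applies the standard chip-data site filters: minor allele
#' frequency strictly above `maf_min` and missing rate strictly below
#' `missing_max`. Pass `maf_min = 0` to disable the frequency filter (needed
#' when rare sites or the focal variant itself must be retained) and
#' `snv_only = FALSE` to retain indels such as a focal delins.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param region Optional `list(chrom, start, end)`; positions are 1-based
#'   and the interval is half-open `[start, end)`.
#' @param maf_min Minor-allele-frequency threshold; sites kept when
#'   MAF > `maf_min`. `0` keeps every site.
#' @param missing_max Missing-rate threshold; sites kept when
#'   missing rate < `missing_max`.
#' @param snv_only Keep only single-nucleotide variants (default `TRUE`).
#' @param assume_phased_hom Accept `/`-separated genotypes when homozygous
#'   (phase is unambiguous there); otherwise any `/` separator is an error.
#' @return A [haplotype_matrix()].
#' @export
read_phased_vcf <- function(path, region = NULL, maf_min = 0.05,
                            missing_max = 0.01, snv_only = TRUE,
                            assume_phased_hom = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (is.null(samples) || length(samples) == 0L)
    stop("malformed VCF: no sample genotype columns in ", path)

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)  # biallelic records only
  if (snv_only) keep <- keep & nchar(ref) == 1L & nchar(alt) == 1L
  if (!is.null(region)) {
    keep <- keep & chrom == as.character(region$chrom) &
      pos >= region$start & pos < region$end
  }
  if (!any(keep))
    return(haplotype_matrix(samples,
                            matrix(integer(0), nrow = 2L * length(samples), ncol = 0L),
                            data.frame(chrom = character(0), pos = integer(0),
                                       id = character(0), ref = character(0),
                                       alt = character(0))))
  gt <- gt[keep, , drop = FALSE]
  # GT first field only (drop any :DP etc. that extract.gt may leave)
  gt[] <- sub(":.*$", "", gt)

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  bad_sep <- !is.na(gt) & sep == "/" &
    !(assume_phased_hom & a1 == a2)
  if (any(bad_sep))
    stop("unphased genotypes ('/' separator) found; phase the input or use ",
         "assume_phased_hom = TRUE for homozygous sites")
  malformed <- !is.na(gt) & !(sep %in% c("|", "/")) & nchar(gt) > 1L
  if (any(malformed))
    stop("malformed GT field(s), e.g.: ", gt[malformed][1])

  to_allele <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[!is.na(a) & a == "0"] <- 0L
    out[!is.na(a) & a == "1"] <- 1L
    out
  }
  # haploid-style single-char GT ("." or bare allele) -> both haplotypes NA
  single <- !is.na(gt) & nchar(gt) == 1L
  a1[single] <- "."; a2[single] <- "."
  m1 <- matrix(to_allele(a1), nrow = nrow(gt))
  m2 <- matrix(to_allele(a2), nrow = nrow(gt))

  n <- length(samples)
  alleles <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(gt))
  alleles[seq(1L, 2L * n, by = 2L), ] <- t(m1)
  alleles[seq(2L, 2L * n, by = 2L), ] <- t(m2)

  sites <- data.frame(
    chrom = chrom[keep], pos = pos[keep],
    id = ifelse(is.na(fix[keep, "ID"]), ".", fix[keep, "ID"]),
    ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE
  )
  m <- haplotype_matrix(samples, alleles, sites)
  af <- m$sites$alt_frequency
  maf <- pmin(af, 1 - af)
  ok <- m$sites$missing_rate < missing_max
  if (maf_min > 0) ok <- ok & maf > maf_min & !is.nan(maf)
  subset_sites(m, ok)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Plain-text VCF 4.2 output with `|`-separated GT fields; missing alleles
#' are written as `.`. Output is byte-deterministic for a given matrix, so
#' write/read round-trips reproduce alleles and site order exactly.
#'
#' @param m A [haplotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(m, path) {
  n <- length(m$samples)
  h1 <- m$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- m$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  f <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(paste0(f(t(h1)), "|", f(t(h2))), nrow = nrow(m$sites))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples), collapse = "\t")
  )
  if (nrow(m$sites) > 0L) {
    body <- paste(m$sites$chrom, m$sites$pos, m$sites$id, m$sites$ref,
                  m$sites$alt, ".", ".", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Identify heterozygous carriers of a focal variant
#'
#' Locates the focal site in the matrix and returns every sample carrying
#' exactly one alternate allele there, together with which of its two phased
#' haplotypes bears the variant. The model assumes heterozygous carriers of a
#' rare dominant allele; a homozygous-alternate genotype is an error.
#'
#' @param m A [haplotype_matrix()] loaded unfiltered (so the focal site,
#'   typically a rare delins, is present).
#' @param focal A [variant_record()] for the focal variant.
#' @return An object of class `carrier_set`: list with `carriers` (data frame
#'   of `sample` and `hap` in `{1, 2}`) and `focal`.
#' @export
focal_carriers <- function(m, focal) {
  stopifnot(inherits(m, "haplotype_matrix"), inherits(focal, "variant_record"))
  j <- which(m$sites$chrom == focal$chrom & m$sites$pos == focal$pos &
             m$sites$ref == focal$ref & m$sites$alt == focal$alt)
  if (length(j) != 1L)
    stop("focal site ", format_variant_id(focal),
         " absent from matrix (load with maf_min = 0, snv_only = FALSE)")
  n <- length(m$samples)
  a1 <- m$alleles[seq(1L, 2L * n, by = 2L), j]
  a2 <- m$alleles[seq(2L, 2L * n, by = 2L), j]
  if (any(!is.na(a1) & !is.na(a2) & a1 == 1L & a2 == 1L))
    stop("homozygous-alternate genotype at focal site in sample(s): ",
         paste(m$samples[which(a1 == 1L & a2 == 1L)], collapse = ", "),
         " (model assumes heterozygous carriers)")
  is_c <- !is.na(a1) & !is.na(a2) & (a1 + a2 == 1L)
  carriers <- data.frame(
    sample = m$samples[is_c],
    hap = ifelse(a1[is_c] == 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  structure(list(carriers = carriers, focal = focal), class = "carrier_set")
}

#' @export
print.carrier_set <- function(x, ...) {
  cat("carrier_set:", nrow(x$carriers), "heterozygous carriers of",
      format_variant_id(x$focal), "\n")
  invisible(x)
}
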