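#' Consensus haplotype over carrier chromosomes
#'
#' At every site of the matrix, the consensus allele is the majority vote
#' among the carriers' focal (variant-bearing) haplotypes. Missing alleles do
#' not vote; ties are broken toward the allele of the first carrier in
#' sample-ID sort order, so repeated runs are deterministic. This is the
#' putative founder haplotype against which sharing is measured.
#'
#' @param m A [haplotype_matrix()].
#' @param carriers A [focal_carriers()] `carrier_set`.
#' @return An object of class `consensus_haplotype`: list with `sites`,
#'   `alleles` (one 0/1 per site, `NA` where no carrier has data) and
#'   `support` (carriers whose focal haplotype matches the consensus).
#' @export
consensus_haplotype <- function(m, carriers) {
  stopifnot(inherits(m, "haplotype_matrix"), inherits(carriers, "carrier_set"))
  cc <- carriers$carriers
  if (nrow(cc) == 0L) stop("empty carrier set")
  ord <- order(cc$sample)
  rows <- .hap_row(m, cc$sample[ord], cc$hap[ord])
  H <- m$alleles[rows, , drop = FALSE]
  ones <- colSums(H == 1L, na.rm = TRUE)
  zeros <- colSums(H == 0L, na.rm = TRUE)
  cons <- ifelse(ones > zeros, 1L, ifelse(zeros > ones, 0L, NA_integer_))
  tie <- which(is.na(cons))
  for (j in tie) { # first non-missing allele in sample-sorted carrier order
    v <- H[, j]
    v <- v[!is.na(v)]
    if (length(v)) cons[j] <- v[1L]
  }
  support <- colSums(H == matrix(cons, nrow(H), ncol(H), byrow = TRUE),
                     na.rm = TRUE)
  structure(
    list(sites = m$sites, alleles = as.integer(cons), support = as.integer(support)),
    class = "consensus_haplotype"
  )
}

# Internal: outward scan from the focal position with a per-direction
# mismatch budget. Returns indices of matched sites reached.
.scan_extent <- function(match, idx, tolerance) {
  budget <- tolerance
  reached <- integer(0)
  for (j in idx) {
    if (match[j]) {
      reached <- c(reached, j)
    } else {
      if (budget == 0L) break
      budget <- budget - 1L
    }
  }
  reached
}

#' Shared-haplotype extent of one carrier
#'
#' Scans outward from the focal position along the carrier's focal haplotype,
#' left and right independently, each direction stopping at its
#' `(tolerance + 1)`-th mismatch against the consensus (the budget is per
#' direction, not pooled). Missing alleles never match. The extent is
#' reported as the positions of the outermost matched sites.
#'
#' @param m A [haplotype_matrix()].
#' @param sample Carrier sample ID.
#' @param hap Which haplotype (1 or 2) carries the focal variant.
#' @param consensus A [consensus_haplotype()].
#' @param focal_pos 1-based position of the focal variant (need not itself be
#'   a site of the matrix, e.g. with chip data).
#' @param tolerance Non-negative per-direction mismatch budget (default 0).
#' @return An object of class `extent_interval`: list with `sample`, `hap`,
#'   `left_pos`, `right_pos` (satisfying `left_pos <= focal_pos <= right_pos`)
#'   and `n_sites`, the number of matched sites in the extent.
#' @export
carrier_extent <- function(m, sample, hap, consensus, focal_pos, tolerance = 0L) {
  stopifnot(tolerance >= 0L)
  h <- m$alleles[.hap_row(m, sample, hap), ]
  match <- !is.na(h) & !is.na(consensus$alleles) & h == consensus$alleles
  pos <- m$sites$pos
  idx_r <- which(pos >= focal_pos)
  idx_l <- rev(which(pos < focal_pos))
  reached <- c(.scan_extent(match, idx_l, as.integer(tolerance)),
               .scan_extent(match, idx_r, as.integer(tolerance)))
  structure(
    list(sample = sample, hap = as.integer(hap),
         left_pos = if (length(reached)) min(pos[reached], focal_pos) else focal_pos,
         right_pos = if (length(reached)) max(pos[reached], focal_pos) else focal_pos,
         n_sites = length(reached)),
    class = "extent_interval"
  )
}

#' Minimal shared core of a set of carrier extents
#'
#' The minimal shared haplotype is the intersection of all per-carrier
#' extents: `[max(left_pos), min(right_pos)]`. It contains the focal position
#' by construction. Consensus alleles restricted to the interval are the core
#' alleles whose background frequency quantifies the founder evidence.
#'
#' @param extents List of [carrier_extent()] results (>= 1).
#' @param consensus A [consensus_haplotype()].
#' @return An object of class `shared_core_result` with `core_interval`
#'   (`c(left, right)` in bp), `core_sites`, `core_alleles` and the input
#'   `extents`; background counts are filled in by [background_frequency()].
#' @export
minimal_core <- function(extents, consensus) {
  if (length(extents) == 0L) stop("need at least one extent")
  left <- max(vapply(extents, `[[`, numeric(1), "left_pos"))
  right <- min(vapply(extents, `[[`, numeric(1), "right_pos"))
  idx <- which(consensus$sites$pos >= left & consensus$sites$pos <= right)
  structure(
    list(core_interval = c(left = left, right = right),
         core_sites = consensus$sites[idx, , drop = FALSE],
         core_alleles = consensus$alleles[idx],
         extents = extents,
         background_matches = NA_integer_, background_total = NA_integer_,
         frequency_text = NA_character_),
    class = "shared_core_result"
  )
}

#' Background frequency of the shared core
#'
#' Counts how many background haplotypes (both haplotypes of every non-carrier
#' sample) carry the core alleles at every core site; a missing allele is a
#' mismatch. The frequency is reported in the conventional "1 in K" form with
#' `K = floor(total / matches)`.
#'
#' @param m A [haplotype_matrix()].
#' @param core A [minimal_core()] result.
#' @param exclude A `carrier_set` or character vector of sample IDs excluded
#'   from the background (the carriers; add relatives here if needed).
#' @return The `shared_core_result` with `background_matches`,
#'   `background_total` and `frequency_text` filled in.
#' @export
background_frequency <- function(m, core, exclude) {
  excl <- if (inherits(exclude, "carrier_set")) exclude$carriers$sample else exclude
  bg_samples <- setdiff(m$samples, excl)
  rows <- c(.hap_row(m, bg_samples, 1L), .hap_row(m, bg_samples, 2L))
  key_m <- paste(m$sites$chrom, m$sites$pos, m$sites$ref, m$sites$alt)
  key_c <- paste(core$core_sites$chrom, core$core_sites$pos,
                 core$core_sites$ref, core$core_sites$alt)
  cols <- match(key_c, key_m)
  if (anyNA(cols)) stop("core sites missing from matrix")
  total <- length(rows)
  if (length(cols) == 0L || anyNA(core$core_alleles)) {
    matches <- if (length(cols) == 0L) total else 0L
  } else {
    B <- m$alleles[rows, cols, drop = FALSE]
    ok <- B == matrix(core$core_alleles, nrow(B), ncol(B), byrow = TRUE)
    ok[is.na(ok)] <- FALSE
    matches <- sum(rowSums(ok) == length(cols))
  }
  core$background_matches <- as.integer(matches)
  core$background_total <- as.integer(total)
  core$frequency_text <- if (matches == 0L) "0 matches" else
    sprintf("1 in %d", floor(total / matches))
  core
}

#' Fit the shared founder core around a focal variant
#'
#' The central computation: from phased genotypes and the set of heterozygous
#' carriers of a focal variant, build the carrier consensus haplotype, measure
#' each carrier's shared extent outward from the focal position, intersect the
#' extents into the minimal shared core, and count how often that core occurs
#' on background (non-carrier) haplotypes. A rare variant whose carriers all
#' share a long core that is vanishingly rare in the background descends from
#' a single founder rather than recurring independently.
#'
#' @param m A [haplotype_matrix()] of phased sites (typically common SNVs,
#'   MAF > 5\%, missingness < 1\%).
#' @param focal A [variant_record()] for the focal variant.
#' @param tolerance Per-direction mismatch budget for extents (default 0).
#' @param carriers Optional [focal_carriers()] `carrier_set`. If `NULL`, the
#'   focal site must be present in `m` and carriers are derived from it. Pass
#'   an explicit set when the focal variant is absent from the matrix (e.g.
#'   a delins not on the genotyping chip).
#' @return An object of class `founder_core` with components `carriers`,
#'   `consensus`, `extents` (data frame), `core` (a `shared_core_result` with
#'   background counts), `match_matrix` (carriers x sites logical) and the
#'   call parameters. Has `print`, `summary` and `plot` methods.
#' @examples
#' sim <- simulate_founder_cohort(founder_sim_config(
#'   n_carriers = 5, n_background = 50, n_common_sites = 40), seed = 1)
#' fit <- founder_core(sim$matrix, sim$truth$focal)
#' fit
#' @export
founder_core <- function(m, focal, tolerance = 0L, carriers = NULL) {
  stopifnot(inherits(m, "haplotype_matrix"), inherits(focal, "variant_record"))
  if (is.null(carriers)) carriers <- focal_carriers(m, focal)
  cc <- carriers$carriers[order(carriers$carriers$sample), , drop = FALSE]
  if (nrow(cc) == 0L) stop("no heterozygous carriers of ", format_variant_id(focal))
  cons <- consensus_haplotype(m, carriers)
  extents <- lapply(seq_len(nrow(cc)), function(i)
    carrier_extent(m, cc$sample[i], cc$hap[i], cons, focal$pos, tolerance))
  core <- minimal_core(extents, cons)
  core <- background_frequency(m, core, carriers)
  rows <- .hap_row(m, cc$sample, cc$hap)
  H <- m$alleles[rows, , drop = FALSE]
  mm <- !is.na(H) & H == matrix(cons$alleles, nrow(H), ncol(H), byrow = TRUE)
  rownames(mm) <- cc$sample
  colnames(mm) <- paste(m$sites$chrom, m$sites$pos, sep = ":")
  ext_df <- data.frame(
    sample = vapply(extents, `[[`, character(1), "sample"),
    hap = vapply(extents, `[[`, integer(1), "hap"),
    left_pos = vapply(extents, `[[`, numeric(1), "left_pos"),
    right_pos = vapply(extents, `[[`, numeric(1), "right_pos"),
    n_sites = vapply(extents, `[[`, integer(1), "n_sites"),
    stringsAsFactors = FALSE
  )
  ext_df$span_bp <- ext_df$right_pos - ext_df$left_pos
  structure(
    list(focal = focal, tolerance = as.integer(tolerance), carriers = carriers,
         consensus = cons, extents = ext_df, core = core,
         match_matrix = mm, sites = m$sites),
    class = "founder_core"
  )
}

#' @export
print.founder_core <- function(x, ...) {
  cat("Shared founder-core fit around", format_variant_id(x$focal), "\n")
  cat("  carriers:", nrow(x$extents),
      " tolerance:", x$tolerance, "mismatch(es) per direction\n")
  cat(sprintf("  extent span: %.1f Mb to %.1f Mb across carriers\n",
              min(x$extents$span_bp) / 1e6, max(x$extents$span_bp) / 1e6))
  ci <- x$core$core_interval
  cat(sprintf("  minimal shared core: %s:%d-%d (%d sites)\n",
              x$focal$chrom, as.integer(ci[1]), as.integer(ci[2]),
              nrow(x$core$core_sites)))
  cat("  background haplotypes matching core:", x$core$background_matches,
      "/", x$core$background_total,
      paste0("(", x$core$frequency_text, ")"), "\n")
  invisible(x)
}

#' @export
summary.founder_core <- function(object, ...) {
  out <- list(
    focal = format_variant_id(object$focal),
    n_carriers = nrow(object$extents),
    tolerance = object$tolerance,
    extents = object$extents,
    core_interval = object$core$core_interval,
    core_n_sites = nrow(object$core$core_sites),
    background_matches = object$core$background_matches,
    background_total = object$core$background_total,
    frequency_text = object$core$frequency_text
  )
  class(out) <- "summary.founder_core"
  out
}

#' @export
print.summary.founder_core <- function(x, ...) {
  cat("Shared founder-core fit:", x$focal, "\n\nPer-carrier extents:\n")
  print(x$extents, row.names = FALSE)
  cat(sprintf("\nMinimal shared core: %d-%d (%d sites); background %d/%d (%s)\n",
              as.integer(x$core_interval[1]), as.integer(x$core_interval[2]),
              x$core_n_sites, x$background_matches, x$background_total,
              x$frequency_text))
  invisible(x)
}

#' Plot a founder-core fit as a carrier-by-site match image
#'
#' A text-figure analogue of the classic shared-haplotype heat strip: one row
#' per carrier, one column per site, filled where the carrier's focal
#' haplotype matches the consensus and white where it does not. The focal
#' position and the minimal shared core are marked.
#'
#' @param x A [founder_core()] fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.founder_core <- function(x, ...) {
  mm <- x$match_matrix
  pos <- x$sites$pos
  graphics::image(x = pos, y = seq_len(nrow(mm)), z = t(1 * mm)[, rev(seq_len(nrow(mm))), drop = FALSE],
                  col = c("white", "#2166AC"), xlab = "position (bp)",
                  ylab = "carrier", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(mm)), labels = rev(rownames(mm)), las = 2, cex.axis = 0.7)
  graphics::abline(v = x$focal$pos, col = "red", lwd = 2)
  graphics::abline(v = x$core$core_interval, col = "darkgreen", lty = 2)
  invisible(x)
}

#' Write the carrier-by-site match matrix as TSV
#'
#' @param x A [founder_core()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_matrix <- function(x, path) {
  stopifnot(inherits(x, "founder_core"))
  df <- data.frame(sample = rownames(x$match_matrix),
                   1L * x$match_matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
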