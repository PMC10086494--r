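#' Variant record
#'
#' A single sequence change in VCF-style anchored representation: a 1-based
#' position, a non-empty reference allele and a non-empty alternate allele,
#' both uppercase A/C/G/T strings. Complex delins (a deletion plus an
#' insertion at the same locus) are first-class citizens: they are exactly
#' the records that admit many equivalent representations and therefore get
#' miscalled as several distinct variants by different callers.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position of the first reference base.
#' @param ref Reference allele string (non-empty, A/C/G/T).
#' @param alt Alternate allele string (non-empty, A/C/G/T).
#' @return An object of class `variant_record`.
#' @examples
#' variant_record("16", 19727140, "AAAAG", "A")
#' @export
variant_record <- function(chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L)
    stop("'pos' must be a positive 1-based integer position")
  if (!nzchar(ref) || !nzchar(alt))
    stop("'ref' and 'alt' must be non-empty (anchored VCF representation)")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must contain only A, C, G, T")
  if (ref == alt)
    stop("'ref' and 'alt' are identical: not a variant")
  structure(
    list(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt),
    class = "variant_record"
  )
}

#' @export
print.variant_record <- function(x, ...) {
  cat(format_variant_id(x), "\n")
  invisible(x)
}

#' Parse and format `chrom:pos:ref:alt` variant identifiers
#'
#' The colon-separated identifier used in rare-variant tables, e.g.
#' `"16:19727140:AAAAG:A"`.
#'
#' @param id Character identifier `chrom:pos:ref:alt`.
#' @return `parse_variant_id()` returns a [variant_record()];
#'   `format_variant_id()` its character identifier.
#' @export
parse_variant_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("variant id must have the form chrom:pos:ref:alt, got: ", id)
  variant_record(parts[1], as.integer(parts[2]), parts[3], parts[4])
}

#' @rdname parse_variant_id
#' @param v A `variant_record`.
#' @export
format_variant_id <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Reference window
#'
#' A stretch of reference sequence carrying its own genomic coordinates, used
#' as the local context for applying, normalizing and comparing variants.
#'
#' @param chrom Chromosome label.
#' @param start 1-based position of the first base of `sequence`.
#' @param sequence Uppercase A/C/G/T string of length >= 1.
#' @return An object of class `reference_window`.
#' @export
reference_window <- function(chrom, start, sequence) {
  sequence <- toupper(as.character(sequence))
  start <- as.integer(start)
  if (is.na(start) || start < 1L) stop("'start' must be a positive integer")
  if (!nzchar(sequence)) stop("'sequence' must be non-empty")
  if (grepl("[^ACGT]", sequence)) stop("'sequence' must contain only A, C, G, T")
  structure(
    list(chrom = as.character(chrom), start = start, sequence = sequence,
         end = start + nchar(sequence) - 1L),
    class = "reference_window"
  )
}

# Internal: 1-based offset of genomic position `pos` within the window.
.window_offset <- function(window, pos) pos - window$start + 1L

#' Apply a variant to a reference window
#'
#' Splices the alternate allele into the window sequence in place of the
#' reference allele. The edited sequence is the ground truth for variant
#' equivalence: two records describe the same variant exactly when they
#' produce the same edited sequence.
#'
#' @param window A [reference_window()].
#' @param v A [variant_record()] lying fully inside the window.
#' @return The edited sequence (character scalar).
#' @export
apply_edit <- function(window, v) {
  stopifnot(inherits(window, "reference_window"), inherits(v, "variant_record"))
  off <- .window_offset(window, v$pos)
  len <- nchar(v$ref)
  if (off < 1L || off + len - 1L > nchar(window$sequence))
    stop("variant ", format_variant_id(v), " lies outside window [",
         window$start, ", ", window$end, "]")
  found <- substr(window$sequence, off, off + len - 1L)
  if (found != v$ref)
    stop("reference mismatch at ", v$chrom, ":", v$pos, ": window has '",
         found, "', variant claims '", v$ref, "'")
  paste0(
    substr(window$sequence, 1L, off - 1L),
    v$alt,
    substr(window$sequence, off + len, nchar(window$sequence))
  )
}

#' Normalize a variant to canonical minimal left-aligned form
#'
#' Produces the community-standard canonical representation: shared trailing
#' bases are trimmed, then shared leading bases (always keeping at least one
#' base in each allele), and indels are shifted left as far as the flanking
#' reference sequence allows. Round-trips `chrom:pos:ref:alt` identifiers and
#' is idempotent. The edited product is preserved:
#' `apply_edit(w, v) == apply_edit(w, normalize_variant(v, w))`.
#'
#' @inheritParams apply_edit
#' @return A normalized [variant_record()].
#' @export
normalize_variant <- function(v, window) {
  stopifnot(inherits(window, "reference_window"), inherits(v, "variant_record"))
  # validate context before rewriting anything
  apply_edit(window, v)
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  last1 <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    changed <- FALSE
    if (nchar(ref) > 0L && nchar(alt) > 0L && last1(ref) == last1(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos - 1L < window$start)
        stop("insufficient left context in window to left-align variant at ",
             v$chrom, ":", v$pos)
      pos <- pos - 1L
      b <- substr(window$sequence, .window_offset(window, pos),
                  .window_offset(window, pos))
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  # trim shared leading bases, keeping >= 1 base in each allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  variant_record(v$chrom, pos, ref, alt)
}

#' Test whether two variant records describe the same sequence change
#'
#' Equivalence is defined purely by edited-sequence identity on a shared
#' reference window: `TRUE` iff both records splice to the same product.
#' This is the strongest checkable criterion for unifying delins records that
#' callers have anchored differently.
#'
#' @param v1,v2 [variant_record()]s inside `window`.
#' @inheritParams apply_edit
#' @return Logical scalar.
#' @export
variant_equivalent <- function(v1, v2, window) {
  identical(apply_edit(window, v1), apply_edit(window, v2))
}

#' Unify variant records into equivalence classes
#'
#' Partitions the input records into classes producing the same edited
#' sequence, reporting one canonical (normalized) representative per class.
#' This is the operation that collapses a complex delins miscalled as several
#' distinct records into the single underlying variant.
#'
#' @param variants List of [variant_record()]s, all inside `window`.
#' @inheritParams apply_edit
#' @return A list of classes; each class is a list with elements
#'   `canonical` (normalized [variant_record()]), `members` (list of the
#'   input records) and `indices` (integer positions in the input).
#' @export
unify_variants <- function(variants, window) {
  if (length(variants) == 0L) return(list())
  products <- vapply(variants, function(v) apply_edit(window, v), character(1))
  groups <- split(seq_along(variants), factor(products, levels = unique(products)))
  lapply(unname(groups), function(idx) {
    list(
      canonical = normalize_variant(variants[[idx[1L]]], window),
      members = variants[idx],
      indices = idx
    )
  })
}
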