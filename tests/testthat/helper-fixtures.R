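# Programmatic fixtures: everything is built in code at test time.

# Minimal phased VCF text from a list of records; gts is a matrix of GT
# strings (sites x samples).
write_toy_vcf <- function(path, chrom, pos, ref, alt, gts, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gts <- matrix(gts, nrow = length(pos))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom, pos[i], ".", ref[i], alt[i], ".", ".", ".", "GT",
            gts[i, ]), collapse = "\t"), character(1))
  writeLines(c(lines, body), path)
  path
}

# Haplotype matrix straight from per-haplotype allele rows (2N x M).
toy_matrix <- function(alleles, pos, chrom = "16",
                       samples = sprintf("S%02d", seq_len(nrow(alleles) / 2))) {
  haplotype_matrix(
    samples, alleles,
    data.frame(chrom = chrom, pos = pos, id = ".",
               ref = rep("A", length(pos)), alt = rep("G", length(pos)),
               stringsAsFactors = FALSE)
  )
}

# Six differently-anchored representations of one delins (12 bases deleted,
# 9 inserted) on a 60 bp toy reference, mimicking a complex indel miscalled
# as several distinct records. All apply to the same product by construction.
six_delins_representations <- function() {
  set.seed(424242)
  seq60 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  win <- reference_window("16", 1, seq60)
  p <- 21L
  del <- substr(seq60, p, p + 11L)           # 12 deleted bases
  ins <- "CCGCCTCCT"                         # 9 inserted bases
  base <- variant_record("16", p, del, ins)
  reps <- list(base)
  for (ctx in 1:5) {                         # widen anchoring context
    lpad <- substr(seq60, p - ctx, p - 1L)
    rpad <- substr(seq60, p + 12L, p + 12L + ctx - 1L)
    reps[[length(reps) + 1L]] <- variant_record(
      "16", p - ctx, paste0(lpad, del, rpad), paste0(lpad, ins, rpad))
  }
  list(window = win, variants = reps, product = apply_edit(win, base))
}

# Random variant inside a random window, for property tests.
random_variant_case <- function() {
  n <- sample(20:40, 1)
  seqs <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  win <- reference_window("1", 1, seqs)
  pos <- sample(2:(n - 6), 1)
  rlen <- sample(1:4, 1)
  ref <- substr(seqs, pos, pos + rlen - 1L)
  repeat {
    alt <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
                 collapse = "")
    if (alt != ref) break
  }
  list(window = win, v = variant_record("1", pos, ref, alt))
}
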