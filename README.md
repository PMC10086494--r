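# foundertrace

Evidence analysis for **founder variants**: did carriers of a rare variant,
found in apparently unrelated individuals, inherit it from one common
ancestor? `foundertrace` answers this from phased genotypes by detecting the
shared haplotype that descent from a founder leaves around the variant, and
by testing the statistical signatures that come with it. It is written for
statistical geneticists and renal-genetics groups working with
biobank-style cohorts (phased VCF + per-sample phenotypes), and was built
around the setting of a complex *UMOD* delins segregating in British
families with autosomal dominant tubulointerstitial kidney disease.

## What it computes

Let the focal variant sit at position *p* with a set of heterozygous
carriers whose variant-bearing haplotype is known from phase.

* **Shared core** (`founder_core()`): the consensus allele at each site is
  the majority over carrier haplotypes; each carrier's *extent* is the
  maximal run around *p* with at most `tolerance` mismatches per direction
  against the consensus; the **minimal shared core** is the intersection
  `[max left ends, min right ends]`, and its **background frequency** is
  the fraction of non-carrier haplotypes matching the core at every site
  ("1 in K"). A long core that is vanishingly rare in the background is
  the founder signature.
* **Rare-variant tagging** (`tag_report()`): rare variants (< 0.5% by
  default) within 1 Mb of *p* tested for carrier enrichment with an exact
  2×2 test computed in log space — stable at background margins of 10⁵–10⁶
  (`fisher_exact_2x2()`, two-sided by the "no more probable than observed"
  rule).
* **Delins unification** (`unify_variants()`): complex deletion–insertion
  variants admit many VCF anchorings and get miscalled as several distinct
  records; records are unified by edited-sequence identity and reported by
  their canonical left-aligned form (`normalize_variant()`).
* **Clinical layer**: Welch t-tests from published group summaries,
  chi-square, CKD-EPI 2009 eGFR, KDIGO G/A staging, Kaplan–Meier renal
  survival and the log-rank test.
* **Founder-descent simulator** (`simulate_founder_cohort()`): carriers
  inherit a recombination-delimited segment of a founder haplotype
  (independent Exponential arms with mean 100/g cM after g meioses,
  Haldane model), with planted rare tags and a background pool — the
  ground-truth instrument behind the test suite.

## Worked example

Simulate a cohort of 9 carriers descending 10 generations from one founder
against 2,500 background samples, then fit the shared core:

```r
library(foundertrace)

cfg <- founder_sim_config(n_carriers = 9, n_background = 2500)
sim <- simulate_founder_cohort(cfg, seed = 7)
fit <- founder_core(sim$matrix, sim$truth$focal)
fit
#> Shared founder-core fit around 16:20360000:TCTGCCCCGAAG:CCGCCTCCT
#>   carriers: 9  tolerance: 0 mismatch(es) per direction
#>   extent span: 8.1 Mb to 16.6 Mb across carriers
#>   minimal shared core: 16:19657101-22025749 (30 sites)
#>   background haplotypes matching core: 0 / 5000 (0 matches)
```

Each carrier shares 8–17 Mb with the consensus around the focal delins; the
~2.4 Mb interval shared by *all nine* occurs on none of the 5,000
background haplotypes — exactly the pattern expected under descent from a
common ancestor, and the spans shrink as `generations` grows. The planted
rare tagging variants are recovered with overwhelming enrichment:

```r
cs   <- focal_carriers(sim$matrix, sim$truth$focal)
tags <- tag_report(sim$matrix, cs,
                   sim$matrix$sites[sim$matrix$sites$pos %in% sim$truth$tag_positions, ])
tags[, c("variant", "carriers_with", "carriers_total", "background_with", "p")]
#>           variant carriers_with carriers_total background_with            p
#> 1 16:19929749:T:A             9              9              20 9.357217e-19
#> 2 16:19975698:T:A             9              9              13 4.647493e-20
#> 3 16:20257745:T:A             9              9              14 7.635168e-20
#> 4 16:20848909:T:A             9              9              21 1.336745e-18
```

The same test applied to published carrier/background counts reproduces
reported values, e.g. 4 of 5 carriers versus 109 of 115,140 background:

```r
fisher_exact_2x2(4, 1, 109, 115031)
#> 2x2 exact test: [4 1; 109 115031]
#>   p (two-sided) = 4.392e-12   p (one-sided enrichment) = 4.392e-12   OR = 4221
```

`run_pipeline()` chains load → carriers → shared core → tagging →
clinical statistics and writes a JSON/TSV report bundle; a thin CLI wrapper
lives in `inst/cli/foundertrace.R` (subcommands `simulate`, `normalize`,
`shared-core`, `rare-tag`, `run`).

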