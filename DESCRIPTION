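Package: kirfreq
Title: KIR Haplotype Frequency Estimation from Presence/Absence and
    Copy-Number Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates killer-cell immunoglobulin-like receptor (KIR)
    structural haplotype frequencies from gene-level genotypes typed at
    presence/absence (PA), diploid copy-number (CNV), or mixed resolution.
    Genotypes are interpreted as unordered pairs of reference haplotypes
    under Hardy-Weinberg equilibrium and frequencies are fitted with an
    expectation-maximization algorithm that also assigns each individual
    its maximum-posterior haplotype pair(s). Includes a typing resolution
    score (TRS) quantifying per-individual interpretation ambiguity,
    reference-set diagnostics for gene-content subset/superset haplotypes
    that bias PA-resolution estimates ("hidden" haplotypes), and a
    reproducible cohort simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, yaml, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
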