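Package: cnvphase
Title: Deterministic Phasing and Inheritance of Copy Number Variant
    Haplotypes in Nuclear Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases normal and copy-number-variant-carrying haplotypes
    (haploid copy numbers 0-3) within CNV regions in mother-father-child
    trios and larger nuclear families, starting from per-marker multiploid
    "CNV genotypes" produced by SNP-array CNV callers. Parental haplotype
    partitions and gamete formation schemes are enumerated exhaustively and
    scored by lexicographic parsimony (unexplainable genotypes, then
    non-Mendelian events), so that de novo deletions and duplications and
    uniparental iso-/heterodisomy are recognised automatically when
    Mendelian transmission cannot explain a family. Includes caller
    intersection and confirmation filters, family-wise region convergence,
    transmission-bias and allelic-variability analytics, a brute-force
    oracle, and a seeded family simulator with known ground-truth phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
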