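Package: popafkit
Title: Array-Informed Allele Frequency Annotation and Prioritization for Admixed Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for combining the breadth of genotyping-array
    cohorts with the depth of whole-genome sequencing in admixed populations.
    Computes population-specific allele frequency panels from array cohorts,
    annotates per-sample VCFs with local and reference allele frequencies,
    prioritizes variants with a two-proportion Z statistic, validates calls by
    array concordance with strand-ambiguity filtering, profiles samples with
    Het/Hom, Ti/Tv and known/novel metrics, places samples by PCA projection,
    supervised admixture and identity-by-state neighbor-joining trees, and
    intersects structural-variant call sets from two callers with novelty
    classification against a background database. Includes a synthetic admixed
    cohort generator (Balding-Nichols divergence, Dirichlet admixture) so the
    full pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
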