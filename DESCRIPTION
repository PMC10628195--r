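Package: heterotrace
Title: Tracing Sex-Chromosome Turnover from XY to ZW Systems
Version: 0.1.0
Authors@R:
    person("heterotrace", "maintainers", email = "heterotrace@example.org",
           role = c("aut", "cre"))
Description: Infers the location of a sex-determination region (SDR) from a
    population VCF via a sex GWAS with Bonferroni control, classifies
    heterogamety (XY vs ZW) from genotype heterozygosity, detects hemizygous
    Y-specific sequence from sexed read-depth and SNP-presence tracks, phases
    X- and Y-specific alleles from a mother and her sexed half-sib progeny,
    places the phased alleles onto a second species' Z and W chromosomes with
    a seed-and-extend flank mapper, scans for partial duplicates of a query
    gene, and renders a verdict on whether the derived Z/W pair originated
    from the ancestral Y or X using allele-identity counts plus a
    Jukes-Cantor neighbor-joining bootstrap phylogeny. A forward simulator of
    homologous XY-to-ZW transitions generates every input the pipeline
    consumes together with a ground-truth record, so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    VariantAnnotation,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
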