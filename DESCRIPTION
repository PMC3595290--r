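Package: tagdge
Title: 3'-Tag Digital Gene Expression Analysis and CAZyme Repertoire Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for SAGE-style 3'-tag digital gene
    expression (DGE) profiling of the kind produced by NlaIII/MmeI tag
    libraries. Builds virtual CATG-anchored tag indexes from predicted
    transcripts, filters raw tag libraries into clean tags with a full
    accounting ledger, quantifies per-gene expression as tags per million
    (TPM), tests differential expression between two libraries with the
    Audic-Claverie exact test under Benjamini-Hochberg FDR control, and
    classifies heterokaryon/homokaryon complementation effects across a
    three-strain design. A companion module compares carbohydrate-active
    enzyme (CAZyme) family repertoires across genomes, including lineage
    averages, rankings and double hierarchical clustering. A synthetic-data
    generator emulates the full three-strain study design with known ground
    truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
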