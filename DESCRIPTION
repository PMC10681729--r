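Package: seaati
Title: Active Cis-Regulatory Element Discovery from TF-Enriched Randomized Ligand Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery, curation, and genomic characterization of active
    cis-regulatory element (CRE) motifs from randomized double-stranded DNA
    ligand libraries enriched by the transcription factors of a nuclear
    extract over several selection rounds. Implements adaptor-anchored core
    extraction and PCR-deduplication of ligand reads, continuous and gapped
    k-mer enrichment against shuffled controls, mutual-information statistics
    for monomeric (E-MI) and dimeric (D-MI) binding signals over 3-mer
    position pairs, local-max seed discovery with multinomial position
    frequency matrix construction, information-content based motif curation
    and Pearson-correlation deduplication and classification against
    reference motif libraries, dimeric core orientation/spacing landscapes,
    exact p-value PWM thresholds with genome scanning, chromatin
    accessibility and Tn5 footprint-depth statistics, expression association
    (TPM, metagene and promoter enrichment, bound-CRE dose response), and a
    full selection-round and genome-track simulator providing ground truth
    for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
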