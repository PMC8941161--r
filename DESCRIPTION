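Package: spongetroph
Title: Genome-Informed Trophic Classification of Sponge Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers carbon and energy lifestyles of sponge-associated
    microbial symbionts from metagenome-assembled genome (MAG) annotation
    tables. Scores carbon-fixation and inorganic-energy pathways from
    combined KEGG, COG and HMM evidence and classifies each MAG as
    organoheterotroph, lithoheterotroph, CBB autotroph or other
    chemoautotroph; partitions CoxL-like (COG1529) proteins into
    percent-identity clusters with majority substrate labels; links
    metatranscriptome transcripts to MAG proteins by best blastp-style hit
    and builds binary expression/prevalence matrices; and converts
    14C-bicarbonate scintillation counts into fixed carbon per gram wet
    tissue with kill-control subtraction, light/dark partitioning, section
    gradients and medium-depletion time courses. Includes synthetic-data
    generators with planted ground truth for every input family.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
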