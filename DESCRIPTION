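Package: peccensus
Title: Genome Census of Low-Potential Protein Electron Carrier Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying genes encoding small low-potential protein
    electron carriers (PECs) - [4Fe-4S] ferredoxins, [2Fe-2S] ferredoxins and
    flavodoxins - across large genome collections. Parses InterProScan-style
    per-gene signature annotations, applies the 200-residue size filter,
    classifies genes into PEC families by InterPro signature, builds a
    per-organism census joined to taxonomy and growth-niche metadata, and
    analyses the census: per-group abundance summaries, count histograms,
    pairwise abundance matrices with quadrant fractions, specialist/generalist
    classification, compositional ternary binning, environmental-niche
    stratification (oxygen requirement, growth temperature, external pH with
    weighted statistics and paired comparisons), kernel-density length
    profiles with mode detection against a packaged structure-length
    reference, and species-tree pruning with per-leaf stacked-bar annotation
    export. Includes a seeded synthetic-data generator emulating the
    statistical structure of real annotation tables so every stage is
    testable without downloads, and a pipeline driver that emits a
    reproducible report bundle with a parameter manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
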