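Package: corticograph
Title: EEG-EMG Channel Graphs, Graph Isomorphism Network Decoding and
    Movement Quality Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous channel graphs from synchronized EEG-EMG
    recordings of isometric movements and decodes them with a Graph
    Isomorphism Network (GIN). Edges come from standardized permutation
    mutual information (SPMI) between every channel pair, node features from
    multitaper band-power fractions, and whole movements are classified and
    quality-scored by a time-based ensemble over the predicted sub-action
    sequence. Includes a synthetic EEG-EMG trial generator with planted
    band-power and corticomuscular coupling structure, preprocessing
    (resampling, zero-phase band-pass filtering, epoching, stratified
    splitting), model training with Adam, movement assessment reports with
    group comparisons, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
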