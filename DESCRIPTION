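Package: attarch
Title: Attachment-Site Architecture Modelling for Serine Integrases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses structural models of serine-integrase
    (large serine recombinase) attachment-site complexes. Assembles
    full-site and synaptic integrase-DNA models from a half-site complex
    by rigid-body (Kabsch) superposition, applies the 5-bp helical
    register shift that converts an attP-bound zinc-ribbon architecture
    into an attB-bound one, and quantifies zinc-ribbon anchor distances
    and coiled-coil reach to classify every pairing of attachment sites
    as synapsis-competent, blocked or autoinhibited. Also provides
    attachment-site sequence analysis (zinc-ribbon motif scanning,
    attP/attB register-shift detection, conservation profiling,
    half-site symmetry, pairwise protein identity), ideal B-DNA
    generation with helical step transforms, crystallographic
    solvent-content bookkeeping, and synthetic structure generators with
    analytically known geometry for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
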