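Package: mesoscene
Title: Instanced Mesoscale Molecular Scenes: Loading, Level-of-Detail,
    Culling, Clipping, Ray-Cast Rendering and Guided Tours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale computational core for visualizing integrative
    mesoscale models of viruses, bacteria and organelles. Loads instanced
    molecular scenes from mmCIF biological assemblies, the YASARA
    PetWorld multi-object mmCIF dialect, BinaryCIF, and a ZIP manifest
    container; simplifies geometry with sphere-merging level-of-detail
    hierarchies; culls instances by view frustum and hierarchical-Z
    occlusion; clips with signed-distance primitives scoped to entity
    groups; renders frames offline with ray-cast sphere impostors,
    multiscale screen-space ambient occlusion, contact shadows and
    normal-dependent transparency; and authors snapshot-based guided
    tours with interpolated camera playback and markdown-linked
    navigation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
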