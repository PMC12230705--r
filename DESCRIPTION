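Package: mvsr
Title: Build, Validate and Share Declarative Molecular Scene Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An implementation of the MolViewSpec open standard for
    declarative, tree-structured descriptions of 3D molecular scenes
    ("states"). Provides a fluent builder API that can only produce
    hierarchy-legal scene trees, schema validation of arbitrary trees,
    canonical MVSJ (JSON) serialization, MVSX (ZIP) archive packing with
    bundled assets, URL-fragment embedding, minimal mmCIF reading with an
    atom-selection language, and the geometric computations the standard
    implies (rigid transforms, bounding spheres, focus-derived cameras,
    distance and angle measurements). Ships deterministic synthetic-fixture
    generators and example scenes so the whole stack is testable offline,
    plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    grDevices,
    utils,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
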