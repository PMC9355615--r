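Package: guildassembly
Title: Community Assembly of Soil Fungal Functional Guilds via Beta-Null
    Deviation and Distance-Matrix Inference
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring community assembly processes (deterministic
    selection versus stochastic dispersal and drift) of soil fungal functional
    guilds from site-by-OTU count tables. Implements abundance-weighted
    beta-null deviation against regional-pool null communities, FUNGuild-style
    partitioning into mycorrhizal, saprotrophic and pathotrophic sub-tables,
    rarefaction and community-weighted trait means, and permutation inference
    on distance matrices (Mantel, partial Mantel, multiple regression on
    matrices with forward selection, variation partitioning, PERMANOVA, NMDS,
    quantile-category contrasts). Includes a synthetic-community generator
    with known assembly regimes for end-to-end validation, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
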