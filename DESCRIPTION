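Package: telemedgame
Title: Evolutionary Game Dynamics of Chronic-Disease Telemedicine Systems
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Four-population asymmetric evolutionary game of chronic-disease
    diagnosis-and-treatment systems: physical medical institutions, medical
    service platforms, intelligent medical device providers and chronic
    disease patients. Builds the per-profile payoff matrix, derives the
    replicator dynamics, classifies the sixteen corner equilibria by Jacobian
    eigenvalue signs (Lyapunov first method), encodes the ten stability
    conditions and their compatibility logic, reproduces the named simulation
    scenarios and speed-sensitivity experiments, and generates random
    assumption-respecting games for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
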