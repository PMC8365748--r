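Package: prisafe
Title: Safety Risk Management for Low-Molecular-Weight Process-Related
    Impurities in Biologics Manufacturing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for safety risk management of low-molecular-weight
    process-related impurities (LMW PRIs) in monoclonal-antibody
    manufacturing. Implements impurity categorization and a two-step
    risk-assessment decision tree; the permitted-daily-exposure (PDE),
    impurity-safety-factor (ISF) and threshold-of-toxicological-concern
    (TTC) dose calculus; downstream clearance-fold accounting with
    limit-of-detection lower-bound semantics and a platform minimum
    clearance budget; and a constant-volume diafiltration sieving model
    with coefficient fitting and diavolume planning. Ships transcribed
    reference tables from published spiking studies, deterministic
    synthetic fixtures, file I/O for inventories, measurements and
    profiles, and JSON/Markdown report rendering with a command-line
    front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
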