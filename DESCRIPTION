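Package: eitflow
Title: Regional Respiratory Gas Flow from Electrical Impedance Tomography
Version: 0.1.0
Authors@R:
    person("EIT", "Flow Developers", email = "eitflow@example.org", role = c("aut", "cre"))
Description: Derives global and regional respiratory gas flow from electrical
    impedance tomography (EIT) time series recorded during mechanical
    ventilation. Tomogram pixel matrices are partitioned into ventral, middle
    and dorsal regions of interest, the regional impedance curves are
    calibrated to volume using the ventilator tidal volume, and gas flow is
    obtained as the first time derivative. Four phases of the respiratory
    cycle are characterised per region and breath: peak inspiratory and
    expiratory flow (PIF, PEF) and late inspiratory and expiratory flow
    (LIF, LEF). Includes spirometry metric extraction for method comparison
    (linear regression and Bland-Altman statistics), regional tidal volume
    distribution, a closed-form multi-compartment pressure-controlled
    ventilation simulator with analytic ground truth, and a command-line
    interface for reproducible simulate/analyze/compare runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
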