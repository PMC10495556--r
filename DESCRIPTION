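Package: rpmcapacity
Title: Capacity Planning for Algorithm-Enabled Remote Patient Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Demand-capacity matching for remote patient monitoring (RPM)
    programs in which an algorithm flags patients for clinician review.
    Implements the deterministic coverage model (projected contact demand,
    provider review capacity, capped coverage percentage), single-axis
    scenario analysis with closed-form sufficiency solvers, a seeded
    Monte-Carlo workload simulator with backlog accounting, historical-log
    evaluation (contacted-to-flagged ratio statistics, projection versus
    actual comparison, calibration fitting), and a synthetic operational-log
    generator calibrated to published period-level ratio statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
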