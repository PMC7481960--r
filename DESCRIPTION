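Package: plateletsc
Title: Stochastic Platelet Supply-Chain Inventory Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage stochastic mixed-integer programming for perishable
    platelet inventory management across one blood center and several
    hospitals under demand and supply uncertainty. Provides a scenario
    generator for normally distributed daily demand and supply, a
    scenario-based MILP with age-tracked (three-day shelf life) FIFO
    inventory balances, nonanticipative first-stage ordering, big-M
    shipment indicators, an independent day-by-day event-replay cost
    oracle, KPI reporting (shortage, outdating, holding, purchases, cost
    summaries), coefficient-of-variation and cost-parameter sensitivity
    sweeps, and a rolling-horizon driver. Mixed-integer programs are
    solved with the open-source HiGHS solver.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9) on the
    PATH; scipy provides the HiGHS mixed-integer solver backend.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
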