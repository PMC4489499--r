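Package: strokechart
Title: Statechart Tracking and Analysis of Digital Art-Making Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes raw tablet stroke and selection event streams from digital
    art-making (drawing) sessions into timed behavioral states by executing a
    hierarchical, orthogonal statechart of the artwork's construction process.
    Computes a per-session table of process metrics (drawing versus idle time,
    color and tool occupancy and switching, stroke kinematics, page-use
    geometry and crossover counts), renders visual timeline reports, textual
    quantitative reports and canvas playback, and runs two-sample cohort
    comparisons (Welch t-test on means, Wilcoxon rank-sum on medians) across
    session metadata groups. Ships a synthetic session generator with
    closed-form ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
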