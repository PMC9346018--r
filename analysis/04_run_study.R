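#!/usr/bin/env Rscript
# Solve the full study: healthy and dysplastic knees, surgery at three
# correction factors, four flexion angles; write the per-angle, pooled,
# percent-change and test tables.

library(patellofem)

cfg <- study_config(resolution = 0.4)
bundle <- run_study(cfg, progress = TRUE)
write_study_tables(bundle, "results/study")
jsonlite::write_json(bundle$surgery, "results/study/surgery_reports.json",
                     auto_unbox = TRUE, digits = NA)

m <- bundle$metrics
cat("\nConverged solves:", sum(m$converged), "of", nrow(m), "\n")
agg <- aggregate(cbind(peak_pressure, mean_pressure, contact_area) ~
                   configuration, m, mean)
print(agg, digits = 3)
cat("\nOn the synthetic pair the dysplastic knee carries higher mean and",
    "peak retropatellar pressure than the healthy knee over a smaller",
    "contact area; virtual trochleoplasty shrinks the area further and",
    "concentrates load at the corrected groove. Postoperative cells at 45",
    "degrees and beyond fail to find a static equilibrium (the fold the",
    "omitted transient repositioning would traverse) and are reported as",
    "failed cells; see the methods vignette.\n")
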