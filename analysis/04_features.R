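#!/usr/bin/env Rscript
# Stage 4 — sliding-window extremum features.
#
# Maps each retained component to its most prominent channel, enumerates the
# benchmark feature grid (100 ms windows stepped by 20 ms over 0-600 ms, min
# and max, amplitude and latency) and extracts the subjects x features matrix
# from the component time courses.

library(erpica)

ds <- read_dataset("scratch/dataset")
m <- read_mixing_model("results/model_NOGO.json")

keep <- m$component_names[1:7]
channel_map <- lapply(keep, function(nm) {
  ci <- match(nm, m$component_names)
  m$channel_order[which.max(abs(m$U_inv[, ci]))]
})
names(channel_map) <- keep
conds <- as.list(rep("NOGO", length(keep)))
names(conds) <- keep

specs <- enumerate_features(reference_templates(windows_ms = 100, step_ms = 20),
                            keep, channel_map)
cat("Enumerated", nrow(specs), "features over", length(keep), "components.\n")
cat("(The dense reference grid with windows 50-150 ms at 4 ms steps would",
    "enumerate", nrow(enumerate_features(reference_templates(), keep)),
    "features.)\n")

fm <- build_feature_matrix(ds, m, specs, channel_map, conds)
write_feature_matrix(fm, "scratch/feature_matrix.csv")
cat("Feature matrix:", nrow(fm$values), "subjects x", ncol(fm$values),
    "features; no missing values:", !anyNA(fm$values), "\n")
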