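#!/usr/bin/env Rscript
# Rebuilds the packaged study caches in inst/extdata/ from scratch:
# regenerates the fixed 250-disk cohort, labels every disk with the full
# simulation pipeline (several hours of single-core CPU), and writes
#   - synthetic_cohort_labels.csv        (per-disk labels + provenance)
#   - synthetic_holdout_rotor_masks.csv  (sparse ROTOR lesions, hold-out)
# Run from the repository root: Rscript scripts/label_study_cohort.R

library(afablate)

out_dir <- "inst/extdata"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

co <- generate_cohort(65, 185, seed = 42)
man <- co$manifest
res <- vector("list", length(co$disks))
for (i in seq_along(co$disks)) {
  res[[i]] <- label_disk(co$disks[[i]])
  r <- res[[i]]
  message(sprintf("[%d/%d] %s inducible=%d labels=%d%d%d", i,
                  length(co$disks), man$id[i], r$inducible,
                  r$labels[1], r$labels[2], r$labels[3]))
}

man$pvi <- vapply(res, function(r) r$labels[["PVI"]], logical(1))
man$fibro <- vapply(res, function(r) r$labels[["FIBRO"]], logical(1))
man$rotor <- vapply(res, function(r) r$labels[["ROTOR"]], logical(1))
man$inducible <- vapply(res, function(r) r$inducible, logical(1))
man$s2_time <- vapply(res, function(r) r$s2_time, numeric(1))
for (s in c("PVI", "FIBRO", "ROTOR"))
  man[[paste0(tolower(s), "_frac")]] <-
    vapply(res, function(r) r$outcomes[[s]]$ablated_fraction, numeric(1))
write.csv(man, file.path(out_dir, "synthetic_cohort_labels.csv"),
          row.names = FALSE)

# sparse ROTOR lesion masks for the fixed hold-out disks
ids <- man$id[man$inducible]
holdout <- study_split(ids)$holdout_ids
rows <- list()
for (id in holdout) {
  i <- match(id, man$id)
  m <- res[[i]]$outcomes$ROTOR$lesions$mask
  enc <- afablate:::mask_to_runs(m, id)
  if (!is.null(enc)) rows[[id]] <- enc
}
write.csv(do.call(rbind, rows),
          file.path(out_dir, "synthetic_holdout_rotor_masks.csv"),
          row.names = FALSE)
message("caches written to ", out_dir)
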