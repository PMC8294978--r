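#!/usr/bin/env Rscript
# Assemble per-NV longitudinal series from the measurement tables, select
# the posttreatment (5 +/- 1 weeks after the last initial-block injection)
# and last-follow-up endpoints, and write the endpoint table under
# results/. For the recurrence case the endpoint signature is checked
# qualitatively: FD-structure at last follow-up rebounds toward baseline
# while the structural area stays put.

suppressMessages(library(octanv))

out <- "results"
enface <- read.csv(file.path(out, "measurements_enface.csv"))
cases <- c("case_regression", "case_recurrence", "case_noisy")
inj <- do.call(rbind, lapply(cases, function(cs)
  read.csv(file.path(out, cs, "injections.csv"))))

rows <- do.call(rbind, lapply(unique(enface$nv_id), function(nv) {
  s <- series_from_measurements(enface[enface$nv_id == nv, ], inj)
  select_endpoints(s)
}))
write.csv(rows, file.path(out, "endpoints.csv"), row.names = FALSE,
          quote = FALSE)
cat(sprintf("wrote %d endpoint rows (posttreatment week %s, last week %s)\n",
            nrow(rows), paste(rows$week_post, collapse = "/"),
            paste(rows$week_last, collapse = "/")))

reg <- rows[rows$nv_id == "SYN-REG", ]
rec <- rows[rows$nv_id == "SYN-REC", ]
cat(sprintf("regression case: FD-structure %0.1f -> %0.1f -> %0.1f %%\n",
            reg$fd_structure_baseline_pct, reg$fd_structure_post_pct,
            reg$fd_structure_last_pct))
cat(sprintf("recurrence case: FD-structure %0.1f -> %0.1f -> %0.1f %%  (rebound: %s)\n",
            rec$fd_structure_baseline_pct, rec$fd_structure_post_pct,
            rec$fd_structure_last_pct,
            rec$fd_structure_last_pct > rec$fd_structure_post_pct))
cat(sprintf("recurrence case: structure area change at last follow-up %+.1f %%\n",
            rec$change_structure_last_pct))
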