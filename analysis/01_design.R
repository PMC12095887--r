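#!/usr/bin/env Rscript
# Build the probe-judgement trial schedule and record the design counts.
library(rmfaces)

dir.create("results", showWarnings = FALSE)
sched <- generate_schedule(seed = 20260901)
write_schedule(sched, "results/schedule.csv")

main <- sched[!sched$is_training, ]
cat(sprintf("schedule: %d analysis trials + %d training trials\n",
            nrow(main), sum(sched$is_training)))
cat(sprintf("probe levels per animation: %d\n",
            length(unique(main$probe_motion_level))))
stimuli <- unlist(lapply(list(c("M1", "male"), c("M2", "male"),
                              c("F1", "female"), c("F2", "female")),
                         function(a) build_continuum(a[1], a[2])$levels$stimulus_id))
cat(sprintf("stimulus set: %d morph images across 4 avatars\n",
            length(unique(stimuli))))
# every (emotion, avatar, probe) cell is presented exactly 3 times
stopifnot(all(table(main$emotion, main$avatar_id, main$probe_motion_level) == 3))
cat("factorial crossing verified: 2 x 2 x 2 x 7 x 3\n")
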