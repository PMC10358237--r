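#!/usr/bin/env Rscript
# Step 1 — simulate a pulse-echo RF case recording.
#
# Builds a scatterer phantom with a denser nodule region, images it in two
# sections (20 frames each) under the clinical acquisition settings (50 MHz
# sampling, 312 lines/frame, 10 MHz receive band), and writes the frames to
# the binary RF container under results/case_demo/. Depth is held to 1024
# samples per line to keep the demo container small; the frame and line
# counts are the clinical ones.

suppressPackageStartupMessages(library(rfqus))

seed <- 20260925L
acq <- acquisition_config(samples_per_line = 1024L)
nodule <- roi_spec(100, 220, 256, 768)
phantom <- phantom_config(scatterer_density = 0.08, amplitude_sd = 1,
                          noise_sd = 0.03, nodule_region = nodule,
                          nodule_density = 0.16, nodule_amplitude_sd = 1.4)

cat("Simulating case (2 sections x", acq$n_frames, "frames)...\n")
case <- simulate_case(phantom, acq, seed)

out <- "results/case_demo"
write_rf_container(case$sections$transverse, file.path(out, "transverse"),
                   acq, "transverse")
write_rf_container(case$sections$longitudinal, file.path(out, "longitudinal"),
                   acq, "longitudinal")
roi <- case$roi
write.csv(data.frame(case_id = "demo", section = c("transverse", "longitudinal"),
                     frame_index = 10L, reader = 1L,
                     line_start = roi$line_start, line_stop = roi$line_stop,
                     sample_start = roi$sample_start, sample_stop = roi$sample_stop),
          file.path(out, "roi.csv"), row.names = FALSE)

frame <- case$sections$transverse[[1]]
cat(sprintf("Wrote %s: %d frames/section, %d lines x %d samples, RMS amplitude %.3f\n",
            out, acq$n_frames, nrow(frame), ncol(frame),
            sqrt(mean(unclass(frame)^2))))
cat("Nodule ROI:", format(roi$line_stop - roi$line_start), "lines x",
    format(roi$sample_stop - roi$sample_start), "samples\n")
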