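#!/usr/bin/env Rscript
# Stage 1: simulate the three ground-truthed datasets that the downstream
# analyses consume.
#
#   * an amperometric dopamine trace (electrode current + the underlying
#     concentration, with a stimulus artefact and recording noise),
#   * a two-channel 3D axon volume (TH-like axon channel and a release-site
#     cluster channel, blurred and noised like an acquired stack),
#   * a three-channel 2D synaptosome field (Bassoon / TH / Syt-1).
#
# Every stage derives its own random stream from the one master seed, so
# rerunning this script reproduces each output file bit for bit.
# Run from the repository root:  Rscript analysis/01_simulate_data.R [--seed N]
suppressPackageStartupMessages(library(dopaquant))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

run_stage("simulate-trace",
          params = list(duration_s = 4.0,
                        stimulus_times_s = 0.5,
                        amplitude_um = 1.8,
                        tau_rise_ms = 1.0,
                        tau_decay_ms = 60,
                        noise_sd_um = 0.01,
                        artefact_amplitude_na = 40),
          seed = seed, out_dir = "results/raw/trace")

run_stage("simulate-volume",
          params = list(shape_voxels = c(16L, 110L, 240L),
                        voxel_size_um = c(0.125, 0.05, 0.05),
                        n_axons = 1L, axon_bend_sd_rad = 0.1,
                        cluster_rate_inside = 0.8,
                        cluster_rate_outside = 0.6,
                        cluster_volume_range_um3 = c(0.008, 0.03),
                        psf_sigma_um = c(0.08, 0.04, 0.04),
                        noise_sd = 0.05),
          seed = seed, out_dir = "results/raw/volume")

run_stage("simulate-puncta",
          params = list(image_shape_px = c(512L, 512L),
                        n_objects = c(bassoon_th = 60L, th_only = 40L,
                                      bassoon_only = 30L),
                        syt1_positive_fraction = c(0.7, 0.2, 0.6),
                        n_oversize = 4L, n_elongated = 4L,
                        psf_sigma_um = 0.08, noise_sd = 0.02),
          seed = seed, out_dir = "results/raw/puncta")

cat("simulated datasets written under results/raw/ (seed", seed, ")\n")
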