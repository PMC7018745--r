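#!/usr/bin/env Rscript
# Receptor gating under a synaptic GABA transient, control vs nerve-injured.
#
# Simulates the three-state scheme (C0 <-> C1 <-> O) with the two rate-
# constant presets under the standard cleft transient (0.63 mM, tau 1 ms),
# summarizes each event (peak open fraction, rise, decay), computes the
# steady-state GABA dose-response curves with their closed-form EC50s, and
# writes the conductance time courses that illustrate why the injured
# condition carries more receptors yet no larger events: lower GABA
# affinity roughly offsets the 37.2% higher channel count.

suppressPackageStartupMessages(library(gabakcc2))
dir.create("results", showWarnings = FALSE)

pulse <- transmitter_pulse(0.63, 1)
summaries <- list()
for (cond in c("sham", "pni")) {
  p <- gating_preset(cond)
  traj <- simulate_gating(p, pulse, duration = 100)
  write.csv(traj, sprintf("results/gating_trajectory_%s.csv", cond),
            row.names = FALSE)
  s <- summarize_event(traj)
  dc <- gaba_dose_response(p)
  write.csv(data.frame(concentration_mM = dc$concentration,
                       open_fraction = dc$open_fraction),
            sprintf("results/gaba_dose_response_%s.csv", cond),
            row.names = FALSE)
  summaries[[cond]] <- data.frame(
    condition = cond,
    peak_open_fraction = s$peak_open_fraction,
    rise_10_90_ms = s$rise_10_90,
    decay_tau_ms = s$decay_tau,
    decay_tau_eigen_ms = decay_tau_eigen(p),
    gaba_ec50_uM = dc$ec50 * 1000,
    o_max = dc$o_max)
  # conductance with the injured channel-count scaling (1.372 vs 1)
  g <- conductance_timecourse(traj, if (cond == "pni") 1.372 else 1)
  write.csv(g, sprintf("results/conductance_%s.csv", cond), row.names = FALSE)
}
summary_tab <- do.call(rbind, summaries)
write.csv(summary_tab, "results/gating_summary.csv", row.names = FALSE)

red <- 100 * (1 - summary_tab$peak_open_fraction[2] /
                summary_tab$peak_open_fraction[1])
cat(sprintf("control event: peak open fraction %.1f%%, decay %.1f ms (eigenvalue %.1f ms)\n",
            100 * summary_tab$peak_open_fraction[1],
            summary_tab$decay_tau_ms[1], summary_tab$decay_tau_eigen_ms[1]))
cat(sprintf("injured event: peak open fraction %.1f%%, decay %.1f ms\n",
            100 * summary_tab$peak_open_fraction[2],
            summary_tab$decay_tau_ms[2]))
cat(sprintf("GABA EC50 shifts from %.2f to %.2f uM (lower affinity after injury)\n",
            summary_tab$gaba_ec50_uM[1], summary_tab$gaba_ec50_uM[2]))
cat(sprintf("peak reduction with the preset constants: %.1f%%\n", red))
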