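#!/usr/bin/env Rscript
# NMR stage: simulate per-residue T1/T2 decay series for open-like and
# closed-like domain correlation-time maps, fit every residue, summarize per
# domain, and compute the isotropic tau_c; also demonstrates hetNOE, CSP and
# CSI profiles on synthetic shift tables.
#
# Output: results/nmr_tc.tsv, results/nmr_csi_demo.tsv

library(sgtadimer)

seed <- 20260923
nu_N <- 70.94e6  # 15N frequency on a 700 MHz spectrometer

maps <- list(open_like = list(NT = 10.5, TPR = 9.5),
             closed_like = list(NT = 10.5, TPR = 12))
rows <- list()
for (nm in names(maps)) {
  doms <- list(list(name = "NT", range = c(5, 65), tc_ns = maps[[nm]]$NT),
               list(name = "TPR", range = c(87, 206), tc_ns = maps[[nm]]$TPR))
  ds <- simulate_relaxation_dataset(doms, nu_N, noise_sd = 0.03,
                                    rng_seed = seed_stream(seed, match(nm, names(maps))))
  f1 <- fit_relaxation_set(ds$t1); f2 <- fit_relaxation_set(ds$t2)
  for (d in doms) {
    s <- summarize_domain(f1, f2, d$range, nu_N, d$name)
    rows[[length(rows) + 1]] <- data.frame(
      scenario = nm, domain = d$name, n = s$n, mean_T1_s = s$mean_T1_s,
      mean_T2_s = s$mean_T2_s, tc_truth_ns = d$tc_ns,
      tc_recovered_ns = s$tc_ns, tc_se_ns = s$tc_se_ns)
  }
}
tc <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tc, "results/nmr_tc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Domain correlation times:\n"); print(tc, row.names = FALSE)
cat("\nThe central TPR domain tumbles slower (higher tau_c) in the",
    "closed-like scenario while the N-terminal domain is unchanged.\n\n")

# CSI demonstration: a random-coil C-terminal region with two helical
# stretches around the NNP- and Q-rich-like segments
ref <- random_coil_shifts()
set.seed(seed)
res <- 213:313
types <- sample(ref$residue_type, length(res), replace = TRUE)
tab <- data.frame(residue_id = res, residue_type = types,
                  ca_ppm = ref$ca_ppm[match(types, ref$residue_type)],
                  co_ppm = ref$co_ppm[match(types, ref$residue_type)])
helix1 <- res >= 224 & res <= 241   # NNP-like stretch
helix2 <- res >= 275 & res <= 290   # Q-rich-like stretch
tab$ca_ppm[helix1 | helix2] <- tab$ca_ppm[helix1 | helix2] + 2.5
tab$co_ppm[helix1 | helix2] <- tab$co_ppm[helix1 | helix2] + 1.2
tab$ca_ppm[res >= 245 & res <= 252] <- NA  # unassigned broadened gap
prof <- csi(tab)
write.table(prof, "results/nmr_csi_demo.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("CSI calls:", paste(sprintf("%s:%d", names(table(prof$call)),
                                table(prof$call)), collapse = "  "), "\n")
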