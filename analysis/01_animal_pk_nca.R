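#!/usr/bin/env Rscript
# Animal PK stage: the study's raw rat/dog concentration-time data are not
# public, so profiles are regenerated from the published NCA summary
# (CL, Vdss) as one-compartment ground truth, sampled on the study schedule,
# and re-analysed by NCA to show the analysis stage recovers the inputs.

suppressPackageStartupMessages(library(pbpkro))
dir.create("results", showWarnings = FALSE)

inputs <- thy1773_inputs()
times <- c(5 / 60, 0.25, 0.5, 1, 2, 4, 8, 12, 24)  # study sampling schedule
doses <- c(rat = 1, dog = 0.5)                     # mg/kg
f_obs <- c(rat = 0.466, dog = 0.45)                # published oral F

rows <- list()
for (sp in c("rat", "dog")) {
  pk <- inputs$animal_pk[[sp]]
  truth_iv <- ground_truth_pk("one_compartment",
                              list(cl = pk$cl_total, v = pk$vdss),
                              "iv_bolus", dose = doses[[sp]])
  truth_po <- ground_truth_pk("one_compartment",
                              list(cl = pk$cl_total, v = pk$vdss,
                                   ka = 3, f = f_obs[[sp]]),
                              "oral", dose = doses[[sp]])
  nca_iv <- compute_nca(generate_profile(truth_iv, times, noise_cv = 0.1,
                                         lloq = 0.1, seed = 100 + match(sp, c("rat", "dog"))))
  nca_po <- compute_nca(generate_profile(truth_po, times, noise_cv = 0.1,
                                         lloq = 0.1, seed = 200 + match(sp, c("rat", "dog"))))
  f_hat <- bioavailability(nca_po, nca_iv)
  cl_renal <- renal_clearance(pk$fe_urine, nca_iv$cl_total)
  rows[[sp]] <- data.frame(
    species = sp, cl_total = nca_iv$cl_total, vd_ss = nca_iv$vd_ss,
    t_half_iv = nca_iv$t_half, auc_inf_iv = nca_iv$auc_0_inf,
    cmax_po = nca_po$cmax, tmax_po = nca_po$tmax, f = f_hat,
    cl_renal = cl_renal,
    cl_truth = pk$cl_total, vdss_truth = pk$vdss)
  cat(sprintf(
    "%s: NCA CL %.0f (truth %.0f) mL/h/kg, Vdss %.0f (truth %.0f) mL/kg, F %.1f%%, CLr %.1f mL/h/kg\n",
    sp, nca_iv$cl_total, pk$cl_total, nca_iv$vd_ss, pk$vdss, 100 * f_hat, cl_renal))
}
out <- do.call(rbind, rows)
write.csv(out, "results/animal_nca.csv", row.names = FALSE)
cat("NCA on 10%-noise synthetic profiles recovers the generating CL/Vdss;",
    "the published summary values feed the interspecies stage (02).\n")
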