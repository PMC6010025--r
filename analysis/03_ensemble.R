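#!/usr/bin/env Rscript
# The main experiment: 24 desk-scale 2D treatment simulations (12 phantom
# morphologies x 2 tumour-like targets) relating focal quality (Phi,
# normalized primary peak, peak distance) to the local acoustic
# inhomogeneity chi of the beam path. Writes results/ensemble.csv and
# results/ensemble_correlations.json.

suppressPackageStartupMessages(library(hifubreast))
dir.create("results", showWarnings = FALSE)

setup <- study_setup()
plan <- default_ensemble_plan()
ens <- suppressMessages(
  run_ensemble(plan, setup,
               out_csv = "results/ensemble.csv",
               out_json = "results/ensemble_correlations.json"))
print(ens$table, digits = 3)
cat(sprintf("\ncorr(Phi, chi)   = %+.2f\ncorr(peak, chi)  = %+.2f\ncorr(beta, phi)  = %+.2f\n",
            ens$correlations$Phi_chi, ens$correlations$peak_chi,
            ens$correlations$beta_phi))
message("Focal quality falls as the impedance-gradient inhomogeneity of the ",
        "beam path rises: the indicator ranks transducer arrangements.")
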