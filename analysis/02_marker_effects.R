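#!/usr/bin/env Rscript
# Train BayesR marker effects for both traits on the founder panel written
# by 01_founders.R, and report training accuracy and GBLUP heritability as
# sanity checks. Writes the posterior-mean effects to results/.

library(safsim)

dos <- import_dosages_csv("results/founder_dosages.csv")
phen <- import_phenotypes_csv("results/founder_phenotypes.csv")

cfg <- bayesr_config(n_iter = 4000, burn_in = 1000, thin = 5, seed = 10)
effects <- fit_marker_effects(dos, phen, cfg)

g <- predict_gebv(dos, effects)
cat(sprintf("training-set GEBV-phenotype correlation: GY %.2f, OL %.2f\n",
            cor(g[, "GY"], phen$GY), cor(g[, "OL"], phen$OL)))

grm <- compute_grm(dos)
cat(sprintf("GBLUP h2 estimates: GY %.2f (target 0.54), OL %.2f (target 0.80)\n",
            estimate_h2_gblup(phen$GY, grm),
            estimate_h2_gblup(phen$OL, grm)))

out <- data.frame(marker = names(effects$GY$beta),
                  beta_GY = effects$GY$beta,
                  beta_OL = effects$OL$beta,
                  p_null_GY = effects$GY$class_probs[, 1],
                  p_null_OL = effects$OL$class_probs[, 1])
write.csv(out, "results/marker_effects.csv", row.names = FALSE)
big <- function(e) sum(e$class_probs[, 4] > 0.5)
cat(sprintf("markers confidently in the large-effect class: GY %d, OL %d of %d\n",
            big(effects$GY), big(effects$OL), nrow(out)))
cat(sprintf("largest |beta|: GY %.3f, OL %.3f\n",
            max(abs(out$beta_GY)), max(abs(out$beta_OL))))
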