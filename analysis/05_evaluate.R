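#!/usr/bin/env Rscript
# The results readout: Pearson correlation and MSE between texture-model
# estimates and the DXA reference for each target, in-sample and 5-fold
# cross-validated, plus per-target scatter exports.

library(mfxbmd)

feats <- utils::read.csv("results/features.csv", check.names = FALSE)
cohort <- readRDS("scratch/cohort.rds")
X <- as.matrix(feats[, paste0("f", 1:90)])
seed <- 1L

dir.create("results/evaluation", showWarnings = FALSE)
rows <- list()
for (tg in c("lumbar_bmc", "lumbar_bmd", "hip_bmc", "hip_bmd")) {
  y <- vapply(cohort, function(cs) cs$dxa[[tg]], numeric(1))
  model <- read_model(sprintf("results/models/lasso_%s.json", tg))
  ins <- evaluate_predictions(predict(model, X), y, target_name = tg)
  cv <- cross_validated_eval(
    X, y, model_spec = list(method = "lasso",
                            lambda_grid = default_lambda_grid(X, y)),
    k_folds = 5, seed = seed, case_ids = feats$case_id, target_name = tg
  )
  export_scatter(cv, sprintf("results/evaluation/scatter_%s.csv", tg),
                 sprintf("results/evaluation/scatter_%s.png", tg))
  rows[[tg]] <- data.frame(
    target = tg,
    r_insample = ins$pearson_r, mse_insample = ins$mse,
    r_cv = cv$pearson_r, mse_cv = cv$mse, n = cv$n
  )
  cat(sprintf("%-10s in-sample r = %.3f (MSE %.4g) | 5-fold CV r = %.3f (MSE %.4g)\n",
              tg, ins$pearson_r, ins$mse, cv$pearson_r, cv$mse))
}
res <- do.call(rbind, rows)
utils::write.csv(res, "results/evaluation/summary.csv", row.names = FALSE)
cat("evaluation written under results/evaluation/\n")
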