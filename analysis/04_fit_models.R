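#!/usr/bin/env Rscript
# Fit the two regressor families on the fused feature table: OLS and LASSO
# (penalty chosen by 5-fold case-level cross-validation) for each of the
# four DXA targets. Writes one model JSON per target and a weight summary.

library(mfxbmd)

feats <- utils::read.csv("results/features.csv", check.names = FALSE)
cohort <- readRDS("scratch/cohort.rds")
X <- as.matrix(feats[, paste0("f", 1:90)])
seed <- 1L

dir.create("results/models", showWarnings = FALSE)
summary_rows <- list()
for (tg in c("lumbar_bmc", "lumbar_bmd", "hip_bmc", "hip_bmd")) {
  y <- vapply(cohort, function(cs) cs$dxa[[tg]], numeric(1))
  grid <- default_lambda_grid(X, y)
  sel <- select_lambda(X, y, grid, k_folds = 5, seed = seed,
                       case_ids = feats$case_id)
  lasso <- fit_lasso(X, y, sel$lambda, target_name = tg)
  ols <- fit_ols(X, y, target_name = tg)
  write_model(lasso, sprintf("results/models/lasso_%s.json", tg))
  write_model(ols, sprintf("results/models/ols_%s.json", tg))
  summary_rows[[tg]] <- data.frame(
    target = tg, lambda = sel$lambda, nonzero = sum(lasso$weights != 0),
    lambda_max = max(grid)
  )
  cat(sprintf("%-10s lambda = %.4g (of max %.4g), %d / 90 weights nonzero\n",
              tg, sel$lambda, max(grid), sum(lasso$weights != 0)))
}
utils::write.csv(do.call(rbind, summary_rows), "results/models/summary.csv",
                 row.names = FALSE)
cat("models written under results/models/\n")
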