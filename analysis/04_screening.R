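#!/usr/bin/env Rscript
# Applicability domain and virtual screening with the packaged model.
#
# Builds the applicability domain of a fit at the study geometry (Williams
# leverages and standardized residuals), projects the descriptor space with
# NCA supervised by activity tertiles, scores novelty with LOF, and
# predicts initial rates for screening candidates with the published
# reference model -- flagging, not suppressing, out-of-domain candidates.
# Closes with the hydrogen-carrier capacity of quinoline.

library(midasqspr)
dir.create("results", showWarnings = FALSE)
seed <- 20250430

d <- make_linear_qspr(n = 32, k = 4, noise_sd = 0.21, seed = seed)
tr <- 1:25; te <- 26:32
fit <- fit_mlr(d$X[tr, ], d$y[tr])

## Williams plot quantities
wr <- williams_report(fit, X_query = d$X[te, ])
cat(sprintf("Williams: h* = %.3f; training leverages sum to %.2f\n",
            wr$h_star, sum(wr$training$leverage)))
cat(sprintf("training outliers (|std res| > 3): %d; influential (h > h*): %d\n",
            sum(wr$training$outlier), sum(wr$training$influential)))
cat(sprintf("test rows above h*: %d of %d\n", sum(wr$query$influential),
            length(te)))
write.csv(cbind(row = tr, wr$training), "results/04_williams_training.csv",
          row.names = FALSE)

## NCA projection supervised by activity tertiles
bins <- activity_bins(d$y[tr], n_bins = 3)
nca <- nca_fit(d$X[tr, ], bins, dim = 2)
cat(sprintf("NCA: 1-NN LOO accuracy %.2f -> %.2f over %d accepted steps\n",
            nca$acc_before, nca$acc_after, length(nca$objective) - 1))
write.csv(data.frame(row = tr, nca$Z, class = bins),
          "results/04_nca_projection.csv", row.names = FALSE)

## LOF novelty of the held-out rows in the NCA space
lof_test <- lof_scores(nca$Z, nca_project(nca, d$X[te, ]), k_neighbors = 8)
cat("LOF of test rows:", round(lof_test, 2), "\n")

## screening candidates: one in-distribution, one far outside
cand <- rbind(colMeans(d$X[tr, ]) + 0.2,
              colMeans(d$X[tr, ]) + 8 * apply(d$X[tr, ], 2, sd))
sc <- screen_candidates(cand, fit, nca$Z, nca_project(nca, cand),
                        ids = c("near_centroid", "far_extrapolation"))
print(sc, digits = 3)
write.csv(sc, "results/04_screening.csv", row.names = FALSE)

## reference-model arithmetic and hydrogen capacity
mod <- reference_model()
cat(sprintf("\nReference model at D = 0: log10(r0) = %.2f -> r0 = %.2e M/s\n",
            predict_r0(mod, c(0, 0, 0, 0))$log_response,
            predict_r0(mod, c(0, 0, 0, 0))$r0))
cat(sprintf("Quinoline + 5 H2: %.2f %%wt hydrogen capacity\n",
            h2_capacity(c(C = 9, H = 7, N = 1), 5)))
cat("wrote results/04_*.csv\n")
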