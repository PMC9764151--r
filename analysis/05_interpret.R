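#!/usr/bin/env Rscript
# Interpretation of a personalized model: Grad-CAM saliency over the
# class-average beats and a t-SNE embedding of the pooled last-stage
# features, before (generic) and after personalization. Requires the cache
# written by 04_personalize.R.

library(ecgkalemia)
dir.create("results", showWarnings = FALSE)

if (!file.exists("scratch/personal_demo.rds"))
  stop("run analysis/04_personalize.R first")
demo <- readRDS("scratch/personal_demo.rds")
seed <- demo$seed

# regenerate the personal cohort and the demo subject's beats
pcfg <- cohort_config(n_subjects = 12, records_per_class = 10, duration_s = 30,
                      seed = seed + 5000L)
pbs <- build_beat_set(cohort_records(generate_cohort(pcfg)))
sid <- demo$fit$metrics$subject_id[1]
sel <- pbs$meta$subject_id == sid
X <- pbs$X[sel, , drop = FALSE]
lab <- pbs$meta$label[sel]
cat(sprintf("subject %s: %d beats (%d hyper / %d normo)\n", sid, nrow(X),
            sum(lab == "hyper"), sum(lab == "normo")))

generic <- checkpoint_model(demo$pretrained)
personal <- checkpoint_model(demo$fit$checkpoint)
avg <- average_class_beats(X, lab)

cam <- data.frame(
  sample = 1:120,
  mean_hyper_beat = avg$hyper,
  mean_normo_beat = avg$normo,
  generic_saliency = grad_cam(generic, avg$hyper, 2L),
  personal_saliency = grad_cam(personal, avg$hyper, 2L))
utils::write.csv(cam, "results/grad_cam_demo.csv", row.names = FALSE)
# QRS-window saliency mass; an all-zero map (the model sees no positive
# evidence for the class anywhere in the beat) reports NA
focus <- function(s) if (sum(s) > 0) sum(s[21:61]) / sum(s) else NA_real_
cat(sprintf("saliency mass in the QRS window: generic %s, personalized %s\n",
            format(focus(cam$generic_saliency), digits = 2),
            format(focus(cam$personal_saliency), digits = 2)))

# t-SNE of pooled features, subsampled for the quadratic-cost embedding
set.seed(seed)
idx <- sample(nrow(X), min(300, nrow(X)))
emb <- data.frame(
  label = lab[idx],
  generic = embed_tsne(nn_features(generic, X[idx, ]), perplexity = 20, seed = seed),
  personal = embed_tsne(nn_features(personal, X[idx, ]), perplexity = 20, seed = seed))
utils::write.csv(emb, "results/tsne_demo.csv", row.names = FALSE)
sep_score <- function(Y) {
  km <- stats::kmeans(Y, 2, nstart = 10)
  truth <- as.integer(emb$label == "hyper") + 1L
  max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
}
set.seed(seed)
cat(sprintf("2-means purity of the embedding: generic %.2f, personalized %.2f\n",
            sep_score(cbind(emb$generic.1, emb$generic.2)),
            sep_score(cbind(emb$personal.1, emb$personal.2))))
cat("wrote results/grad_cam_demo.csv, results/tsne_demo.csv\n")
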