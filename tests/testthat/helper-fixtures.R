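# Shared test fixtures, all built in code.

# A deliberately small network spec so gradient checks and fine-tuning
# exercises run in seconds. Keeps the 4-stage geometry of the real nets
# unless `stages` says otherwise.
tiny_spec <- function(block = "basic", stages = 2L, widths = NULL,
                      input_length = 24L, stem_width = 4L) {
  s <- resnet_spec("resnet18_1d", input_length = input_length)
  s$block <- block
  s$layout <- rep(1L, stages)
  s$widths <- if (is.null(widths)) as.integer(4 * 2^(seq_len(stages) - 1)) else widths
  s$strides <- c(1L, rep(2L, stages - 1L))
  s$expansion <- if (block == "bottleneck") 2L else 1L
  s$stem_width <- as.integer(stem_width)
  s$stem_kernel <- 5L
  s
}

# Small noiseless cohort for detector / segmentation tests.
clean_cohort <- function(n_subjects = 2, records_per_class = 1, duration_s = 10,
                         seed = 42, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                records_per_class = records_per_class,
                                duration_s = duration_s, subject_spread = 0,
                                noise_sd = 0, seed = seed, ...))
}

# Brute-force AUC by pair counting (independent oracle).
auc_brute <- function(scores, truths) {
  pos <- scores[truths == "hyper"]; neg <- scores[truths == "normo"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive Mann-Whitney two-sided p by direct permutation (oracle).
mw_exact_brute <- function(a, b) {
  pool <- c(a, b); n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u <- u_of(a, b)
  us <- apply(utils::combn(length(pool), n1), 2,
              function(ii) u_of(pool[ii], pool[-ii]))
  min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
}
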