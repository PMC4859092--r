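# Study designs for the planted-structure benchmarks.

# 4 blocks x 3 classes; classes of one block share a planted branch, blocks
# target distinct pathways with alternating direction. Conditions: effect
# size 2, noise 0.3 (log2 sd), 20 samples/class, 10 pathways.
benchmark_block_design <- function(seed) {
  classes <- data.frame(
    class_label = c("HC", sprintf("B%dC%d", rep(1:4, each = 3), rep(1:3, 4))),
    target_pathway = c(NA, rep(1:4, each = 3)),
    target_sink = c(NA, rep(1L, 12)),
    direction = c(NA, rep(rep(c("up", "down"), 2), each = 3)),
    effect_size = c(1, rep(2, 12)),
    n_samples = 20,
    is_control = c(TRUE, rep(FALSE, 12)))
  synthetic_design(n_pathways = 10, noise_sd = 0.3, seed = seed,
                   classes = classes)
}

# two super-groups of 3 classes: "cancer-like" up-deregulation of pathway 1
# versus "inflammation-like" down-deregulation of pathway 2, whole-pathway
# planting so group portraits share their spot.
benchmark_group_design <- function(seed) {
  classes <- data.frame(
    class_label = c("HC", paste0("CA", 1:3), paste0("IN", 1:3)),
    target_pathway = c(NA, rep(1, 3), rep(2, 3)),
    target_sink = c(NA, rep(1L, 6)),
    direction = c(NA, rep("up", 3), rep("down", 3)),
    effect_size = c(1, rep(2, 6)),
    n_samples = 20,
    is_control = c(TRUE, rep(FALSE, 6)),
    branch_mode = c(NA, rep("pathway", 6)))
  synthetic_design(n_pathways = 4, noise_sd = 0.3, seed = seed,
                   classes = classes)
}

# run simulation -> fold change -> PSF for a design
benchmark_psf <- function(design) {
  pw <- generate_pathways(design)
  sim <- simulate_expression(design, pw$graphs, pw$truth)
  fc <- compute_fold_change(sim$values, sim$sheet)$values
  psf <- compute_psf_matrix(pw$graphs, fc)
  list(pw = pw, sim = sim, psf = psf)
}
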