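## Shared fixtures built in code. Heavy objects (the trained desk-scale
## models) are memoised so several test files can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

## a tiny deterministic two-transcript annotation on two chromosomes
tiny_transcripts <- function() {
  spliceformer:::transcript_set(list(
    transcript_model("t1", "g1", "chrA", "+",
                     rbind(c(1, 10), c(21, 30)), support_level = 1L),
    transcript_model("t2", "g2", "chrB", "-",
                     rbind(c(1, 10), c(21, 30)), support_level = 1L)))
}

tiny_store <- function() {
  set.seed(42)
  genome_store(list(
    chrA = paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")))
}

## small untrained model for shape/determinism checks
tiny_model <- function(seed = 7L, use_transformer = TRUE) {
  key <- paste0("tiny_model_", seed, "_", use_transformer)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- spliceformer_config(context = 200L, embed_dim = 8L,
                               block_plan = list(c(5L, 1L, 1L),
                                                 c(5L, 2L, 1L)),
                               slots = c(6L, 6L), n_layers = 2L,
                               n_heads = 2L, ff_dim = 16L,
                               use_transformer = use_transformer)
    .fixture_cache[[key]] <- spliceformer_init(cfg, seed = seed)
  }
  .fixture_cache[[key]]
}

random_window <- function(L, seed = 1L) {
  set.seed(seed)
  one_hot_encode(paste(sample(c("A", "C", "G", "T"), L, TRUE),
                       collapse = ""))
}

## the desk-scale study: default synthetic genome, scaled model and its
## encoder-only ablation trained identically; trained once per test run
study_genome <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- generate_genome(seed = 11L)
  }
  .fixture_cache$sim
}

study_schedule <- function() {
  optimizer_schedule(warmup_steps = 50L, epochs = 11L, halve_after = 8L,
                     batch_size = 1L)
}

study_model <- function(ablation = FALSE) {
  key <- if (ablation) "model_ablation" else "model_full"
  if (is.null(.fixture_cache[[key]])) {
    sim <- study_genome()
    cfg <- scaled_config(use_transformer = !ablation)
    .fixture_cache[[key]] <- spliceformer(
      sim, config = cfg, schedule = study_schedule(), lambda = 1e-6,
      seed = 5L, windows_per_epoch = 350L)
  }
  .fixture_cache[[key]]
}
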