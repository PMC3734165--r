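# Shared fixtures: the reference synthetic data set (seed 1, default
# config) and one full pipeline run over it, generated once per test run.

.synth_cache <- new.env(parent = emptyenv())

default_synth <- function() {
  if (is.null(.synth_cache$gen)) {
    data_dir <- file.path(tempdir(), "rootnet-default-data")
    run_dir <- file.path(tempdir(), "rootnet-default-run")
    .synth_cache$gen <- generate_synthetic_data(synthetic_config(seed = 1),
                                                data_dir)
    .synth_cache$summary <- suppressMessages(
      run_pipeline(pipeline_config(data_dir, run_dir)))
    .synth_cache$data_dir <- data_dir
    .synth_cache$run_dir <- run_dir
  }
  list(gen = .synth_cache$gen, summary = .synth_cache$summary,
       data_dir = .synth_cache$data_dir, run_dir = .synth_cache$run_dir)
}

read_run <- function(run_dir, file) {
  read.delim(file.path(run_dir, file), stringsAsFactors = FALSE)
}

# tiny three-transcript transcriptome used across unit tests
toy_transcriptome <- function() {
  set.seed(42)
  seqs <- vapply(c(400L, 300L, 350L), function(l)
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = ""),
    "")
  data.frame(transcript_id = c("TX0001.1", "TX0002.1", "TX0003.2"),
             gene_id = c("TX0001", "TX0002", "TX0003"),
             sequence = seqs, stringsAsFactors = FALSE)
}
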