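# Internal helpers shared across modules.

# Deterministic child seeds so that re-running one stage of a pipeline
# reproduces exactly the stream it saw inside the full run.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stage <- as.integer(stage)
  as.integer((as.double(seed) * 1009 + stage * 9973) %% 2147483629)
}

# Floor applied to per-neuron standard deviations before dividing, so a
# zero-variance column becomes an effectively constant feature instead of
# producing NaN/Inf.
SD_FLOOR <- sqrt(.Machine$double.eps)

floor_sd <- function(s) {
  s[!is.finite(s) | s < SD_FLOOR] <- SD_FLOOR
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable short fingerprint of an R object (used to stamp pipeline outputs).
config_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
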