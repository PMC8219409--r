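# Derive a stage-specific sub-seed from the root seed so one flag reproduces
# every stage. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 101L, partition = 211L, split = 307L,
               balance = 401L, model = 503L, missing = 601L, raw = 701L)
  if (!stage %in% names(offsets)) stop("unknown stage '", stage, "'")
  (abs(as.integer(seed)) %% 1000000L) * 1013L + offsets[[stage]]
}

round_half_up <- function(x) floor(x + 0.5)
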