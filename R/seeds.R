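#' Derive a stage seed from a master seed
#'
#' Deterministically maps (`master_seed`, `stage_label`, `replicate_index`)
#' to an integer seed below 2^31. Seeds for consecutive replicate indices of
#' the same stage are guaranteed distinct; distinct stage labels map to
#' well-separated streams via a string hash. All randomness in the package
#' flows through seeds derived this way, so whole experiments are
#' reproducible from a single master seed.
#'
#' @param master_seed Integer master seed.
#' @param stage_label Character scalar naming the pipeline stage.
#' @param index Replicate index (non-negative integer, may be a vector).
#' @return Integer vector of seeds in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "burn_in", 0:3)
#' @export
derive_seed <- function(master_seed, stage_label, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage_label), length(stage_label) == 1L,
            all(index >= 0))
  p <- 2147483587  # prime < 2^31
  bytes <- utf8ToInt(stage_label)
  a <- (master_seed %% p)
  for (b in bytes) a <- (a * 69069 + b + 1) %% p
  # second pass with a different multiplier to spread label space
  for (b in rev(bytes)) a <- (a * 40692 + b + 13) %% p
  ((a + index) %% (p - 1)) + 1
}
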