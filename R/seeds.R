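# Deterministic per-stage seeding.
#
# Every source of randomness in the package derives from one global seed
# plus a fixed, documented stage offset, so stages can be re-run in any
# order (or skipped) without changing each other's draws. The caller's RNG
# state is restored on exit.

.stage_offsets <- c(
  masks = 101L, betas = 202L, presslog = 303L,
  permutation = 404L, searchlight = 505L, rfe = 606L, replicate = 707L
)

stage_seed <- function(seed, stage, extra = 0L) {
  off <- .stage_offsets[[stage]]
  if (is.null(off)) stop("unknown seeding stage: ", stage)
  # keep within 32-bit integer range
  as.integer((as.double(seed) * 7919 + off + as.double(extra) * 13) %% 2147483629)
}

with_stage_seed <- function(seed, stage, code, extra = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage, extra))
  force(code)
}
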