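## evaluate `code` under a temporary RNG state seeded with `seed`;
## a NULL seed leaves the global RNG stream untouched by us (code still draws)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
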