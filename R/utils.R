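# Shared internal helpers.

# 20 canonical amino acids; "X" is tolerated in input sequences but is never
# treated as satisfying a fixed-residue constraint.
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

#' Run code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators do not perturb
#' the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
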