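#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the package (LD pruning, synthetic generation,
#' bootstrap replicates, ...) draws its own seed deterministically from a
#' single master seed and a stage label, so that any stage can be reproduced
#' in isolation.  The derivation is an FNV-1a hash of the master seed and the
#' label, reduced modulo 2^31 - 1; it is pure integer arithmetic and therefore
#' stable across platforms.
#'
#' @param master integer master seed.
#' @param what stage label (string or integer), e.g. `"prune"` or a bootstrap
#'   replicate index.
#' @return a positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "prune")
#' derive_seed(1, 17)
derive_seed <- function(master, what) {
  stopifnot(length(master) == 1L, is.finite(master))
  bytes <- c(
    as.integer(charToRaw(sprintf("%d", as.integer(master)))),
    as.integer(charToRaw(":")),
    as.integer(charToRaw(as.character(what)))
  )
  h <- 2166136261
  for (b in bytes) {
    h <- .xor32(h, b)
    h <- .mul32(h, 16777619)
  }
  as.integer(h %% 2147483646) + 1L
}

# 32-bit xor / multiply on doubles (R integers would overflow)
.xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}
.mul32 <- function(a, b) {
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) * b) %% 65536
  (hi * 65536 + lo) %% 4294967296
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Stable 32-bit content hash of an R object (used for the run manifest).
.config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames")),
               collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- .xor32(h, b)
    h <- .mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
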