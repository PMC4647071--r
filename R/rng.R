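#' Derive a reproducible substream seed
#'
#' Deterministically maps a master seed plus a sequence of labels (population
#' names, cell ids, purpose tags) to a seed below 2^31, so independent parts
#' of a build (placement, each wiring pathway, each stimulus train, analysis
#' subsampling) draw from independent, order-insensitive substreams.
#'
#' @param master integer master seed
#' @param ... further labels (character or integer scalars)
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
substream_seed <- function(master, ...) {
  labels <- c(as.character(as.integer(master)), vapply(list(...), as.character, ""))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (s in labels) {
    for (cc in utf8ToInt(s)) {
      h <- (h * 131 + cc) %% m
    }
    h <- (h * 31 + 7) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
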