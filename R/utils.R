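`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that any stage (design, patterns, noise, permutations) can
#' be reproduced in isolation. The mapping is a cheap deterministic hash kept
#' below `.Machine$integer.max`; it is not cryptographic.
#'
#' @param seed Integer master seed.
#' @param name Character stream name, e.g. `"design.run3"`.
#' @return An integer seed.
#' @export
substream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 131 + h * 7919) %% 2147483629)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_sl <- function(...) stop(sprintf(...), call. = FALSE)

# Write a data.frame as TSV keeping full double precision so that read
# round-trips are exact.
write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "n/a"
      out[[j]] <- v
    } else if (is.integer(out[[j]])) {
      v <- as.character(out[[j]])
      v[is.na(out[[j]])] <- "n/a"
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
}

read_tsv_exact <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
             stringsAsFactors = FALSE)
}
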