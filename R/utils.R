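#' @useDynLib rohsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm rpois runif setNames dpois
#' @importFrom utils head tail write.table
NULL

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a child seed from a parent seed and stream keys
#'
#' Deterministic mixing of a parent seed with integer or string keys, used
#' throughout the package to give every pipeline stage its own independent
#' random stream. Results stay below 2^31 (valid R integers).
#'
#' @param seed parent integer seed.
#' @param ... integer or character stream keys.
#' @return An integer seed.
#' @export
child_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    kk <- if (is.character(k)) sum(utf8ToInt(k)) else as.double(k)
    x <- (x * 48271 + kk * 16807 + 1) %% 2147483647
  }
  as.integer(x)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- light interval helpers (0-based half-open data.frames: contig,start,end) ---

empty_intervals <- function() {
  data.frame(contig = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(iv) {
  iv[order(iv$contig, iv$start), , drop = FALSE]
}

interval_total_len <- function(iv) sum(iv$end - iv$start)

# total length of intersection of two interval sets (per contig, via IRanges)
intersect_len <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (ct in intersect(unique(a$contig), unique(b$contig))) {
    ia <- IRanges::IRanges(start = a$start[a$contig == ct] + 1L,
                           end = a$end[a$contig == ct])
    ib <- IRanges::IRanges(start = b$start[b$contig == ct] + 1L,
                           end = b$end[b$contig == ct])
    tot <- tot + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  tot
}
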