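#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist kmeans median p.adjust prcomp rnbinom rnorm runif
#'   sd var wilcox.test
#' @importFrom utils read.csv write.csv head modifyList
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
with_seed <- function(seed, code) {
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
  force(code)
}

## Row-broadcast addition of a bias vector.
addb <- function(X, b) sweep(X, 2L, b, `+`)

## Deterministic top-k by decreasing value, ties broken by lower index.
top_k_stable <- function(v, k) {
  ord <- order(-v, seq_along(v))
  sort(ord[seq_len(min(k, length(v)))])
}

assert_finite_matrix <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains NA/NaN/Inf values", what), call. = FALSE)
  }
  invisible(x)
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  }
}
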