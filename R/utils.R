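#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores the caller's stream, so seeded operations never perturb
#' surrounding randomness. `seed = NULL` runs the code untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific seed from a root seed
#'
#' Every random stage of the pipeline draws its seed from one root seed and
#' the stage name, so a single integer reproduces a full run and no stage
#' consumes global unseeded randomness. The result always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Root integer seed.
#' @param stage Character stage name.
#' @return A positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "kmeans")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 65521) * 32749 + (h %% 1048573) * 127 + 1) %% 2147483646L + 1L
}

# column-wise sample SD (denominator n - 1), NA-tolerant
col_sds <- function(x, na.rm = FALSE) {
  apply(x, 2, stats::sd, na.rm = na.rm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
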