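#' @keywords internal
#' @importFrom e1071 naiveBayes
#' @importFrom MASS lda
#' @importFrom randomForest randomForest
#' @importFrom ranger ranger
#' @importFrom rpart rpart
#' @importFrom xgboost xgb.train
#' @importFrom yaml read_yaml
#' @importFrom stats predict
"_PACKAGE"

## Run an expression under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so package functions never disturb the
## global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

## Derive a child seed from a parent seed and a stream index, staying inside
## the 32-bit signed-integer range R requires.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}

#' Round half up to a fixed number of decimals
#'
#' Decimal rounding with ties going away from zero, the convention used when
#' clinical journals print percentages (base R `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(12.25, 1)  # 12.3, where round() gives 12.2
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count, printed-style
#'
#' Computes `100 * count / total` rounded half-up to `digits` decimals, the
#' form in which cohort descriptive tables print proportions.
#'
#' @param count,total non-negative counts, `total > 0`.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @examples
#' pct(423, 3307)  # 12.8
#' @export
pct <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, digits)
}

## Small stable fingerprint (FNV-1a over the deparsed object) used to stamp
## configs into reports; not cryptographic.
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
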