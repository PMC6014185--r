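#' Logit and inverse-logit
#'
#' Numerically safe logit transforms used throughout the prevalence models.
#'
#' @param p probabilities in (0, 1).
#' @return `logit()` returns log(p / (1 - p)); `invlogit()` its inverse.
#' @export
logit <- function(p) log(p) - log1p(-p)

#' @rdname logit
#' @param x real values on the logit scale.
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

#' Derive a per-stage seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master
#' seed so each stage is independently rerunnable. The derivation is a simple
#' multiplicative hash of the stage label folded into 31 bits.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label (e.g. "sdm", "geostat").
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exponential correlation between two coordinate sets (matrices with x, y cols)
exp_corr <- function(coords_a, coords_b = NULL, phi) {
  stopifnot(phi > 0)
  if (is.null(coords_b)) {
    d <- as.matrix(stats::dist(coords_a))
  } else {
    d <- outer(seq_len(nrow(coords_a)), seq_len(nrow(coords_b)), function(i, j) {
      sqrt((coords_a[i, 1] - coords_b[j, 1])^2 + (coords_a[i, 2] - coords_b[j, 2])^2)
    })
  }
  exp(-d / phi)
}
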