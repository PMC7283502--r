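#' Activation functions
#'
#' `relu()` is the rectified linear unit `max(0, x)`. `lrelu_softplus()` is
#' the hybrid activation used in the detector head: a shifted softplus
#' `ln(e^x + 1) - ln 2` for `x >= 0` and a leaky linear branch `a * x` for
#' `x < 0` (default slope `a = 0.01`). The function is continuous at 0
#' (both branches give 0), monotone non-decreasing, and asymptotically
#' `x - ln 2` as `x -> Inf`. Large arguments are handled with `log1p`
#' identities so the evaluation is numerically stable.
#'
#' @param x numeric vector or array.
#' @param a negative-side slope, must be > 0.
#' @return same shape as `x`.
#' @examples
#' lrelu_softplus(0)        # 0
#' lrelu_softplus(-2)       # -0.02
#' lrelu_softplus(1)        # log(exp(1) + 1) - log(2)
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname relu
#' @export
lrelu_softplus <- function(x, a = 0.01) {
  if (a <= 0) stopf("slope `a` must be > 0",
                    class = "strawdetect_invalid_argument")
  pos <- x >= 0
  out <- x
  # softplus(x) - log 2, stable form: x + log1p(exp(-x)) - log 2 for x >= 0
  out[pos] <- x[pos] + log1p(exp(-x[pos])) - log(2)
  out[!pos] <- a * x[!pos]
  out
}

# derivative of lrelu_softplus: sigmoid(x) on x >= 0, a on x < 0
lrelu_softplus_grad <- function(x, a = 0.01) {
  pos <- x >= 0
  out <- x
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- a
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))
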