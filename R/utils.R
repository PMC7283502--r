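#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so that
# (inputs, seed) -> output is a pure function.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item child seed from a master seed. Kept below 2^31 so it is a
# valid R integer.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + as.double(index) * 104729) %% 2147483629)
}

stopf <- function(fmt, ..., class = "strawdetect_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stopf("`%s` must be an H x W x 3 numeric array", arg,
          class = "strawdetect_invalid_argument")
  }
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Quantize a [0,1] raster to 8-bit levels so PNG round-trips are exact.
quantize8 <- function(x) round(clip01(x) * 255) / 255
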