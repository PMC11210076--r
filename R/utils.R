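# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom stats fft nextn approx median quantile sd var rnorm runif rpois
#' @importFrom tibble tibble as_tibble is_tibble
#' @import Rcpp
#' @useDynLib nvcoh, .registration = TRUE
NULL

stop_nvcoh <- function(msg, class) {
  abort(msg, class = c(class, "nvcoh_error"))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_nvcoh(sprintf("`%s` must be a finite numeric scalar.", name),
               "nvcoh_validation_error")
  }
  if (positive && x <= 0) {
    stop_nvcoh(sprintf("`%s` must be > 0.", name), "nvcoh_validation_error")
  }
  invisible(x)
}

assert_numeric_series <- function(x, name = "x", min_length = 2L) {
  if (!is.numeric(x) || length(x) < min_length) {
    stop_nvcoh(sprintf("`%s` must be numeric with at least %d samples.",
                       name, min_length), "nvcoh_validation_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_nvcoh(sprintf("`%s` contains missing or non-finite values.", name),
               "nvcoh_validation_error")
  }
  invisible(x)
}

# Deterministic sub-seed derivation: one master seed expands to independent
# stream seeds for subjects/channels/components.  Keeps every derived seed
# in the 32-bit signed range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else as.numeric(p)
  })))
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2^31)) %% 2147483629
  as.integer(h %% 2147483562L) + 1L
}

with_seed_nv <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Circular mean of angles; returns value in (-pi, pi].
circular_mean <- function(theta) {
  z <- mean(exp(1i * theta))
  a <- Arg(z)
  if (a <= -pi) a <- a + 2 * pi
  a
}

wrap_pi <- function(theta) {
  a <- (theta + pi) %% (2 * pi) - pi
  a[a <= -pi] <- a[a <= -pi] + 2 * pi
  a
}
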