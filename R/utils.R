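#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance augment
NULL

# Seed the RNG for the caller's scope; previous RNG state is restored when the
# calling function exits, so generators are reproducible without clobbering
# the session RNG stream.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number or NULL.")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be %s.", name, if (strict) "> 0" else ">= 0"))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x != round(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be a non-negative integer.", name))
  }
  invisible(as.integer(x))
}

#' @export
print.motorlab_fit <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  g <- glance(x)
  for (nm in names(g)) {
    val <- g[[nm]]
    cat("  ", nm, ": ", if (is.numeric(val)) signif(val, 5) else as.character(val),
        "\n", sep = "")
  }
  invisible(x)
}
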