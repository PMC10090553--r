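#' @keywords internal
"_PACKAGE"

# Shared validation and small helpers used across modules.

stop_validation <- function(...) {
  stop(structure(
    class = c("codepnet_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_parse <- function(...) {
  stop(structure(
    class = c("codepnet_parse_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_integrity <- function(...) {
  stop(structure(
    class = c("codepnet_integrity_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Canonicalize gene or cell-line symbols
#'
#' Uppercases and strips surrounding whitespace. This single convention is
#' applied everywhere identifiers enter the package (matrices, gene sets,
#' symbol lists), so that symbol namespaces that differ only in case or
#' padding join cleanly.
#'
#' @param x Character vector of symbols.
#' @param strip_entrez If `TRUE`, a trailing parenthesized token (as in
#'   DepMap-style `"SYMBOL (1234)"` headers) is removed before
#'   canonicalization.
#' @return Character vector of canonical symbols.
#' @export
#' @examples
#' canonicalize_symbols(c(" ret ", "Zbtb7a"))
#' canonicalize_symbols("ZBTB7A (51341)", strip_entrez = TRUE)
canonicalize_symbols <- function(x, strip_entrez = FALSE) {
  x <- as.character(x)
  if (strip_entrez) {
    x <- sub("\\s*\\([^)]*\\)\\s*$", "", x)
  }
  toupper(trimws(x))
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. Every stochastic operation in the package goes
# through this, so generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number, got: ",
                    deparse(substitute(seed)))
  }
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

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_na = FALSE) {
  if (length(x) != 1L || (!allow_na && (!is.numeric(x) || !is.finite(x)))) {
    stop_validation(name, " must be a single finite number")
  }
  if (is.finite(x) && (x < lower || x > upper)) {
    stop_validation(name, " must lie in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop_validation(name, " must be an integer >= ", min)
  }
  as.integer(x)
}
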