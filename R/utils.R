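#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt pf qnorm pnorm rnorm rbinom runif sd var coef lm anova
#'   p.adjust bartlett.test ks.test complete.cases setNames vcov model.matrix
#' @importFrom utils combn head
NULL

# Condition constructors ------------------------------------------------------
# Two error families: configuration errors (bad spec/config values) and data
# errors (inconsistent or malformed inputs). Both subclass "wscoremap_error".

config_error <- function(msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c("wscoremap_config_error", "wscoremap_error", "error")))
}

data_error <- function(msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c("wscoremap_data_error", "wscoremap_error", "error")))
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    config_error("'seed' must be a single integer")
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
  force(code)
}

#' Format a count as a percentage of a total
#'
#' The percentage-formatting rule used by every summary table in the package:
#' `100 * count / total`, rounded half-up at the requested number of decimal
#' places (so 62/101 prints as 61.4 and 2/15 prints as 13 at zero decimals).
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (positive).
#' @param digits Decimal places to keep (default 1).
#' @return Numeric percentage on the 0-100 scale, rounded to `digits`.
#' @examples
#' pct(16, 117)      # 13.7
#' pct(2, 15, 0)     # 13
#' @export
pct <- function(count, total, digits = 1) {
  if (!is.numeric(count) || !is.numeric(total) || any(total <= 0)) {
    data_error("pct() needs numeric count and positive total")
  }
  round(100 * count / total, digits)
}

# Shared argument checks
check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    config_error(sprintf("'%s' must be a single number in [%s, %s]",
                         name, format(min), format(max)))
  }
  invisible(x)
}
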