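#' @keywords internal
"_PACKAGE"

# Condition helpers ----------------------------------------------------------

stop_photomics <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "photomics_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

param_error <- function(fmt, ...) stop_photomics(fmt, ..., class = "photomics_param_error")
data_error <- function(fmt, ...) stop_photomics(fmt, ..., class = "photomics_data_error")
format_error <- function(fmt, ...) stop_photomics(fmt, ..., class = "photomics_format_error")

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    param_error("'%s' must be a single non-missing number", name)
  }
  if (finite && !is.finite(x)) param_error("'%s' must be finite", name)
  if (positive && x <= 0) param_error("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) param_error("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Seeded evaluation without touching global RNG state ------------------------

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    param_error("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Rounding half away from zero (base round() is banker's)
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Population (denominator-N) standard deviation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Trapezoidal integral of y over uniformly spaced samples with step dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2) * dt
}

#' Normalize gene/protein identifiers
#'
#' Applies the package's identifier dialect before any set operation:
#' case-fold to upper case and strip a trailing numeric version suffix after
#' the final dot (e.g. \code{"ENSMUSG00000025326.14"} becomes
#' \code{"ENSMUSG00000025326"}; \code{"Gpx4"} becomes \code{"GPX4"}).
#'
#' @param ids character vector of identifiers.
#' @return character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_ids(c("Gpx4", "ENSMUSG00000025326.14"))
normalize_ids <- function(ids) {
  if (length(ids) == 0L) return(character(0))
  ids <- as.character(ids)
  toupper(sub("\\.[0-9]+$", "", ids))
}
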