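# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes programmatically.
dpph_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dpph_error"), call = call))
}

# round() uses banker's rounding; image software rounds half away from zero.
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == as.integer(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Role vocabulary for wells and measurements
#'
#' Each drop on the plate (or tube in the spectrophotometric branch) plays one
#' of four roles: `reaction` (sample + DPPH), `reagent_blank` (DPPH mixture
#' without antioxidant: the zero-scavenging reference), `extract_blank`
#' (sample + solvent only: the sample's own colour), `solvent_control`
#' (solvent + DPPH).
#'
#' @format Character vector of the four role names.
#' @export
well_roles <- c("reaction", "reagent_blank", "extract_blank", "solvent_control")
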