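# Internal helpers: error conditions, seed management, validation.

abort_param <- function(msg) {
  stop(structure(list(message = msg, call = sys.call(-1)),
                 class = c("calcytox_param_error", "calcytox_config_error",
                           "error", "condition")))
}

abort_config <- function(msg) {
  stop(structure(list(message = msg, call = sys.call(-1)),
                 class = c("calcytox_config_error", "error", "condition")))
}

abort_gating <- function(msg) {
  stop(structure(list(message = msg, call = sys.call(-1)),
                 class = c("calcytox_gating_error", "error", "condition")))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort_param(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    abort_param(sprintf("`%s` must be strictly positive", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort_param(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

#' Derive a well-level RNG seed from a master seed
#'
#' Wells on a plate are simulated independently but must be jointly
#' reproducible from a single master seed. The rule is a fixed
#' linear-congruential mix, exact in double precision:
#' `(master * 48271 + index * 1299721) mod (2^31 - 2) + 1`.
#'
#' @param master_seed integer master seed for the plate.
#' @param index non-negative integer stream index (well index, or a
#'   sub-stage offset within a well).
#' @return a positive integer seed strictly below `2^31`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483646
  as.integer((as.double(master_seed) %% m * 48271 +
                as.double(index) * 1299721) %% m) + 1L
}
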