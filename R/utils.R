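# Internal helpers: typed conditions, seed derivation, small numeric utilities.

# Condition classes used throughout:
#   gaitmood_config_error     -- bad user configuration (CLI exit code 2)
#   gaitmood_format_error     -- malformed files / data (CLI exit code 3)
#   gaitmood_contract_error   -- API contract violation (shape/width mismatch)
#   gaitmood_stratification_error -- split impossible for a class
#   gaitmood_geometry_error   -- feature set undefined for the topology
#   gaitmood_metric_error     -- metric undefined (e.g. zero samples)
#   gaitmood_version_error    -- model artifact inconsistent on load
gm_stop <- function(msg, class = "contract") {
  stop(structure(
    class = c(paste0("gaitmood_", class, "_error"),
              "gaitmood_error", "error", "condition"),
    list(message = msg, call = NULL)))
}

gm_warn <- function(msg, class = "warning") {
  warning(structure(
    class = c(paste0("gaitmood_", class), "gaitmood_warning",
              "warning", "condition"),
    list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-9
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Deterministic sub-seed derivation. Offsets are small documented constants;
# results stay inside the 32-bit signed range R requires for set.seed().
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483629)
}

# Largest-remainder apportionment of n items to length(fractions) buckets.
# Ties between equal remainders are resolved in favour of the LAST bucket
# first (for train/validation/test fractions: test, then validation).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact + 1e-12)
  remainder <- exact - base
  leftover <- round(n - sum(base))
  if (leftover > 0) {
    ord <- order(-remainder, -seq_along(fractions))
    take <- ord[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
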