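# Shared constants and small internal helpers.

# organ bookkeeping shared by the physiology and engine modules

.PERFUSED_ORGANS <- c("lung", "liver", "kidney", "gut", "muscle", "adipose",
                      "skin", "bone", "brain", "heart", "spleen", "rest")

# organs fed directly from arterial blood (lung sits in series with the
# heart and receives the full cardiac output)
.SYSTEMIC_ORGANS <- setdiff(.PERFUSED_ORGANS, "lung")

.BLOOD_COMPARTMENTS <- c("arterial_blood", "venous_blood")

.DISEASE_STAGES <- c("healthy", "CP-A", "CP-B", "CP-C",
                     "CKD-moderate", "CKD-severe")

#' Path to a packaged data file
#'
#' @param file File name under `inst/extdata`.
#' @return Absolute path to the installed data file.
#' @keywords internal
hcq_extdata <- function(file) {
  path <- system.file("extdata", file, package = "hcqpbpk")
  if (!nzchar(path)) {
    stop("packaged data file not found: ", file, call. = FALSE)
  }
  path
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded sampling inside the package
#' never disturbs the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in multi-stage runs flows from one root seed; each stage
#' uses `sub_seed(root, label)` so stages are independent but reproducible.
#' Kept below 2^31 - 1 so the result is a valid R integer.
#'
#' @param seed Root integer seed.
#' @param label Character tag for the consuming stage.
#' @return Integer seed.
#' @keywords internal
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small per-session cache for packaged YAML tables (read once per path)
.hcq_cache <- new.env(parent = emptyenv())

cached_yaml <- function(path) {
  key <- normalizePath(path, mustWork = TRUE)
  if (!exists(key, envir = .hcq_cache)) {
    assign(key, yaml::read_yaml(key), envir = .hcq_cache)
  }
  get(key, envir = .hcq_cache)
}
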