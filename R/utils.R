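# Internal helpers shared across modules.

# Canonical trait column order of the scored table. The two relative
# lateralization indices are kept next to their absolute counterparts; the
# default 12-node network drops them.
trait_names <- function() {
  c(
    "growth", "basal_metabolism", "stress_metabolism", "activity",
    "thigmotaxis", "scototaxis", "sociability",
    "motor_lat_rel", "motor_lat_abs", "visual_lat_rel", "visual_lat_abs",
    "spatial_learning", "flexibility", "memory"
  )
}

network_nodes <- function(node_set = c("12", "14")) {
  node_set <- as.character(node_set)
  node_set <- match.arg(node_set)
  if (node_set == "14") {
    return(trait_names())
  }
  setdiff(trait_names(), c("motor_lat_rel", "visual_lat_rel"))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  force(code)
}

# Deterministic per-stage seed derived from a master seed; stays inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483647)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

stop_traitnet <- function(...) {
  stop(..., call. = FALSE)
}
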