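# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit child seed from a master seed and a stage label, so
# pipeline stages can be re-run in isolation with reproducible streams.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483587  # large prime < 2^31; keeps arithmetic in exact doubles
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% 2147483399 + 1)
}

# Content hash of an arbitrary R object (md5 of its serialization).
hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
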