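# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic operations
# funnel their seeds through this so that library use never clobbers the
# user's RNG stream.
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed from a master seed and stream indices; kept
# strictly below 2^31 so it is always a valid R integer seed.
derive_seed_ <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_ <- function(msg, class = NULL) {
  rlang::abort(msg, class = c(class, "phylocomm_error"))
}

assert_ <- function(cond, msg, class = NULL) {
  if (!isTRUE(cond)) abort_(msg, class)
}

# Standardise the three tabular currencies of the package.
as_abundance_table_ <- function(table) {
  assert_(is.data.frame(table), "abundance table must be a data frame")
  need <- c("sample_id", "taxon_id", "abundance")
  assert_(all(need %in% names(table)),
          paste0("abundance table needs columns: ", paste(need, collapse = ", ")))
  out <- tibble::as_tibble(table)[, need]
  assert_(all(is.finite(out$abundance)) && all(out$abundance >= 0),
          "abundances must be finite and non-negative")
  out
}

as_growth_vector_ <- function(x) {
  assert_(is.data.frame(x), "growth vector must be a data frame")
  need <- c("sample_id", "unit_id", "value")
  assert_(all(need %in% names(x)),
          paste0("growth vector needs columns: ", paste(need, collapse = ", ")))
  out <- tibble::as_tibble(x)[, need]
  assert_(all(is.finite(out$value)), "growth values must be finite")
  out
}

# full-precision, locale-stable numeric formatting for serialisation keys
fmt_num_ <- function(x) sprintf("%.17g", x)
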