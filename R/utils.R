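## Internal helpers shared across modules.

.LABELS <- c("negative", "positive")

## Evaluate `expr` under a temporary RNG state seeded with `seed`, then restore
## whatever state the caller had. All randomness in the package flows through
## this so that results are reproducible and callers' RNG streams are untouched.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Fold strings into a base seed; kept below 2^31 so it is a valid R integer.
.deriveSeed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (tok in unlist(list(...))) {
    for (code in utf8ToInt(as.character(tok))) {
      s <- (s * 31 + code) %% 2147483647
    }
  }
  as.integer(s)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.matchLabel <- function(label) {
  match.arg(label, .LABELS)
}

## md5 of a character payload, via a temporary file (tools::md5sum is file-based).
.md5String <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf, sep = "")
  unname(tools::md5sum(tf))
}
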