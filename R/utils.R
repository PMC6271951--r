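# Seed handling: evaluate an expression under a fixed seed without touching
# the caller's RNG stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "oxascreen")
  if (!nzchar(path)) stop(sprintf("bundled fixture not found: %s", file))
  path
}
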