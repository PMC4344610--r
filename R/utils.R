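# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angle(s) into (-180, 180]
wrap180 <- function(a) a - 360 * ceiling((a - 180) / 360)

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop_gt("gt_degenerate_geometry",
                                       "cannot normalize a zero-length vector")
  v / n
}

# classed errors so callers/tests can discriminate failure modes
stop_gt <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "glycotorsion_error")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_gt("gt_validation_error", "%s must be finite numeric", what)
  invisible(x)
}

# normalize optional snapshot weights against a required length
resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1 / n, n))
  check_finite(weights, "weights")
  if (length(weights) != n)
    stop_gt("gt_validation_error",
            "weights length (%d) does not match number of frames (%d)",
            length(weights), n)
  if (any(weights < 0))
    stop_gt("gt_validation_error", "weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0)
    stop_gt("gt_validation_error", "weights must sum to a positive value")
  weights / s
}

# tiny polynomial string hash used to stamp output files with their config
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# run code with a local, restored RNG state: no hidden global side effects
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# write a data.frame as CSV with comment header lines (read back with comment.char = "#")
write_csv_commented <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
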