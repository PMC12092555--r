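# internal numeric helpers

log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a locally-set RNG seed without disturbing the caller's stream;
# seed = NULL leaves the current stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# derive a reproducible 31-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(utf8ToInt(digest_chars(key)), 4)
  s <- sum(raw * 256^(0:3)) %% 2147483647
  as.integer(s)
}

# tiny deterministic rolling hash over UTF-8 bytes (31-bit), no external deps
hash31 <- function(key) {
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

digest_chars <- function(key) {
  h <- hash31(key)
  intToUtf8(c(h %% 256, (h %/% 256) %% 256, (h %/% 65536) %% 256,
              (h %/% 16777216) %% 256) + 32)
}

# hash of a dataset, used to refuse Bayes factors across different data;
# values are rounded to 12 significant digits so raw data and a faithful
# summary round-trip hash identically
data_hash <- function(y1, y2) {
  key <- paste(c(length(y1), length(y2),
                 sprintf("%.12g", c(y1, y2))), collapse = ",")
  sprintf("%08x", hash31(key))
}

stop_mbt <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mbt(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop_mbt(sprintf("`%s` = %g is outside its allowed range (%g, %g).",
                     name, x, lower, upper))
  }
  invisible(x)
}
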