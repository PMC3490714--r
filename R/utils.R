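# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.  seed = NULL uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# full-precision decimal formatting so TSV round trips are lossless
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# canonical (lexicographically ordered) undirected pair labels
canonicalPairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b, key = paste(a, b, sep = "\r"))
}

checkPhase <- function(phase, n = NULL) {
  phase <- as.character(phase)
  if (anyNA(phase) || !all(phase %in% c("dark", "light"))) {
    stop("'phase' must be 'dark' or 'light' with no missing values")
  }
  if (!is.null(n) && length(phase) != n) {
    stop("'phase' has wrong length")
  }
  phase
}
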