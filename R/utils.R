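# internal helpers shared across modules

# Deterministic substream seed from a master seed and a character tag.
# Polynomial rolling hash mod (2^31 - 1) so derived seeds stay valid
# 32-bit integers regardless of the master seed or tag length.
hashSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(tag)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Run expr with a local RNG state seeded from (seed, tag); restores the
# caller's RNG so substreams cannot interfere with each other.
withSubstream <- function(seed, tag, expr) {
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
  set.seed(hashSeed(seed, tag))
  expr
}

# column-wise mean imputation for a variants x samples dosage matrix
imputeMissingDosage <- function(dos) {
  miss <- is.na(dos)
  if (!any(miss)) {
    return(dos)
  }
  rm_ <- rowMeans(dos, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  dos[miss] <- rm_[idx[, 1L]]
  dos
}

writeTsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "."
  )
  invisible(path)
}

readTsv <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  utils::read.table(path,
    sep = "\t", header = TRUE, na.strings = ".",
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
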