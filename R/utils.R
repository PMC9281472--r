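## internal numeric helpers shared across modules

.sigmoid <- function(x) plogis(x)

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

## evaluate expr under a derived RNG seed without touching global RNG state.
## offset keeps independent stages of one run on distinct streams while all
## flowing from a single user seed; kept below 2^31 by the modulus.
.withSeed <- function(seed, expr, offset = 0L) {
  s <- (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
  withr::with_seed(s, expr)
}

## cycle check over a child -> parents map (DFS, three colours)
.ontoHasCycle <- function(parentMap) {
  state <- new.env(parent = emptyenv())
  visit <- function(t) {
    st <- state[[t]]
    if (identical(st, 1L)) return(TRUE)   # back edge
    if (identical(st, 2L)) return(FALSE)
    state[[t]] <- 1L
    for (p in parentMap[[t]]) if (visit(p)) return(TRUE)
    state[[t]] <- 2L
    FALSE
  }
  for (t in names(parentMap)) if (visit(t)) return(TRUE)
  FALSE
}

## FNV-1a over a canonical JSON rendering; used for config fingerprints
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit overflow-safe multiply by the FNV prime 16777619
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint a configuration list
#'
#' Canonicalizes a (possibly nested) configuration list to JSON with sorted
#' keys and hashes it, so that two runs share a fingerprint exactly when
#' their configurations are identical.
#'
#' @param config a named list.
#' @return an 8-hex-digit string.
#' @export
configFingerprint <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  .fnv1a(as.character(txt))
}
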