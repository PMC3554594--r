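# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

# FNV-1a 32-bit hash over a character scalar, returned as 8-char hex.
# Used for config fingerprints in manifests; arithmetic kept in double
# (exact below 2^53) with explicit mod-2^32 reduction.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  mul_mod32 <- function(a, b) {
    hi <- a %/% 65536
    lo <- a %% 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mul_mod32(h, 16777619)
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# xor for doubles holding 32-bit unsigned values
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 2147483648
  hi_b <- b %/% 2147483648
  lo <- bitwXor(as.integer(a %% 2147483648), as.integer(b %% 2147483648))
  (bitwXor(as.integer(hi_a), as.integer(hi_b))) * 2147483648 + as.numeric(lo)
}

# Deterministic sub-seed derivation: one user seed fans out to independent
# per-stage streams.  Kept below 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, label) {
  h <- fnv1a32(paste0(label, ":", format(seed, scientific = FALSE)))
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483629) + 1L
}

# Canonical join-key form: integer-looking values lose leading zeros and
# type differences ("0123", 123, "123" all compare equal); everything else
# compares as the exact string.
canonical_key <- function(x) {
  x <- as.character(x)
  num <- !is.na(x) & grepl("^[+-]?[0-9]+$", x)
  x[num] <- sub("^\\+", "", x[num])
  x[num] <- sub("^(-?)0+(?=[0-9])", "\\1", x[num], perl = TRUE)
  x
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# empty-string and NA both count as SQL NULL in relational rows
is_null_value <- function(x) is.na(x) | (is.character(x) & !is.na(x) & x == "")
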