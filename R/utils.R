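# Internal helpers: integer encoding of label sequences, context codes, seeds.

# Map labels onto 1..C indices of a sorted vocabulary; error on unknown labels
# unless allow_na.
encode_labels <- function(labels, vocabulary, allow_na = FALSE) {
  idx <- match(labels, vocabulary)
  if (!allow_na && anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("labels outside vocabulary: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  idx
}

# 1-based base-C code for a k-length integer context (k = 0 -> 1).
context_code <- function(syms, C) {
  if (length(syms) == 0L) return(1)
  code <- 0
  for (s in syms) code <- code * C + (s - 1)
  code + 1
}

# Vectorised rolling context codes for all positions of a sequence.
# Returns, for each position m in (k+1)..length(x), the code of the k symbols
# preceding m, aligned with the "next" symbol x[m].
rolling_codes <- function(x, k, C) {
  L <- length(x)
  if (L <= k) return(list(ctx = numeric(0), nxt = integer(0), pos = integer(0)))
  pos <- (k + 1L):L
  ctx <- rep(1, length(pos))
  if (k > 0L) {
    ctx <- rep(0, length(pos))
    for (j in seq_len(k)) {
      ctx <- ctx * C + (x[pos - (k - j + 1L)] - 1)
    }
    ctx <- ctx + 1
  }
  list(ctx = ctx, nxt = x[pos], pos = pos)
}

# Decode a 1-based base-C context code back to its k integer symbols.
decode_code <- function(code, k, C) {
  if (k == 0L) return(integer(0))
  code <- code - 1
  out <- integer(k)
  for (j in k:1) {
    out[j] <- (code %% C) + 1
    code <- code %/% C
  }
  as.integer(out)
}

context_label <- function(syms, vocabulary) {
  if (length(syms) == 0L) return("<root>")
  paste(vocabulary[syms], collapse = " ")
}

# Deterministic child seed derivation, kept within 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size = 1L) x[sample.int(length(x), size)]
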