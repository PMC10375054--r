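# internal helpers shared across modules

# run `code` under a fixed RNG seed without disturbing the caller's RNG;
# NULL seed means "use the current RNG stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# deterministically derive a stage-specific seed from a master seed so that
# adding a pipeline stage does not perturb the streams of earlier stages
derive_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 1000003L
  as.integer((as.numeric(seed) + 1009 * h) %% 2147483629)
}

# log(sum(exp(x))) guarding against -Inf and overflow
logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# alignment tibble -> character matrix (rows = sequences, cols = sites)
seq_matrix <- function(aln) {
  m <- matrix("", nrow = nrow(aln), ncol = aln_length(aln))
  sp <- strsplit(aln$sequence, "", fixed = TRUE)
  for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  rownames(m) <- aln$id
  m
}

is_base <- function(m) m == "A" | m == "C" | m == "G" | m == "T"
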