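# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# makes data.table's `[` dispatch correctly from package code
.datatable.aware <- TRUE

#' Random fixed-length DNA sequences
#'
#' @param n number of sequences
#' @param len sequence length in nt
#' @return character vector of length `n`
#' @keywords internal
#' @noRd
random_seq <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Random sequences, guaranteed distinct (resamples collisions).
random_unique_seq <- function(n, len) {
  out <- random_seq(n, len)
  for (i in 1:100) {
    dup <- duplicated(out)
    if (!any(dup)) return(out)
    out[dup] <- random_seq(sum(dup), len)
  }
  stop("could not generate ", n, " unique sequences of length ", len)
}

# Integer matrix view of equal-length strings: one column per string,
# one row per position. Fast path for vectorised Hamming distances.
seq_int_matrix <- function(x, len = nchar(x[1])) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = len))
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = len)
}

# Hamming distance from each string in x to a single reference string.
hamming_to_ref <- function(x, ref) {
  len <- nchar(ref)
  if (length(x) == 0L) return(integer(0))
  m <- seq_int_matrix(x, len)
  r <- utf8ToInt(ref)
  as.integer(colSums(m != r))
}

# Pairwise Hamming distance between x[i] and y[i] (equal-length strings).
hamming_pairwise <- function(x, y) {
  if (length(x) == 0L) return(integer(0))
  len <- nchar(x[1])
  mx <- seq_int_matrix(x, len)
  my <- seq_int_matrix(y, len)
  as.integer(colSums(mx != my))
}

# Weighted majority vote; ties broken by lexicographic order.
majority_vote <- function(values, weights = rep(1, length(values))) {
  agg <- rowsum(as.numeric(weights), values)
  w <- agg[, 1]
  cand <- rownames(agg)[w == max(w)]
  sort(cand)[1]
}

# Draw a per-stage 31-bit seed from a top-level seed and a stage name, so a
# stage's stream does not depend on which stages ran before it.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- (as.numeric(seed) %% 2147483647) + sum(codes * seq_along(codes) * 257)
  as.integer(h %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
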