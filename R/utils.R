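#' @noRd
DNA_BASES4 <- c("A", "C", "G", "T")

# scalar argument checks ------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name, lower = 0, upper = 1)
}

# seeded evaluation: all randomness flows through one local generator per
# call; the caller's RNG state is untouched.
with_local_seed <- function(seed, code) {
  seed <- assert_count(seed, "seed", min = 0L)
  withr::with_seed(seed, code)
}

# derive a stream-specific child seed, kept below 2^31
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

# sequence <-> integer codes (A=0, C=1, G=2, T=3, anything else -1)
encode_dna <- function(x) {
  codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES4) - 1L
  codes[is.na(codes)] <- -1L
  codes
}

decode_dna <- function(codes) {
  paste(DNA_BASES4[codes + 1L], collapse = "")
}

# encode each promoter once (forward and reverse-complement codes) so
# repeated scans over a motif library do not re-parse sequences
encode_promoter_codes <- function(seqs) {
  lapply(seqs, function(s) {
    fwd <- encode_dna(s)
    rc <- rev(3L - fwd)
    rc[rc > 3L | rc < 0L] <- -1L
    list(fwd = fwd, rc = rc)
  })
}

revcomp_chr <- function(x) {
  out <- chartr("ACGTacgt", "TGCAtgca",
                vapply(x, function(s) {
                  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
                }, character(1), USE.NAMES = FALSE))
  names(out) <- names(x)
  out
}

# coerce a promoter collection (DNAStringSet or named character) to a named
# character vector, validating unique ids
as_promoter_chr <- function(promoters) {
  if (methods::is(promoters, "DNAStringSet")) {
    out <- as.character(promoters)
  } else if (is.character(promoters)) {
    out <- promoters
  } else {
    stop("promoters must be a DNAStringSet or a named character vector",
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("promoters must be named by gene id", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate gene ids in promoter set", call. = FALSE)
  }
  toupper(out)
}

# empirical single-base composition of a set of sequences, in A,C,G,T order
base_frequencies <- function(sequences) {
  seqs <- as_promoter_chr(sequences)
  tab <- table(factor(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      levels = DNA_BASES4))
  n <- sum(tab)
  if (n == 0) stop("no bases in sequence set", call. = FALSE)
  as.numeric(tab) / n
}

validate_background_freqs <- function(bg) {
  if (!is.numeric(bg) || length(bg) != 4L || any(bg < 0) ||
      abs(sum(bg) - 1) > 1e-6) {
    stop("background frequencies must be a 4-vector (A,C,G,T) summing to 1",
         call. = FALSE)
  }
  bg / sum(bg)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
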