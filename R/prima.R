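# Threshold-scan motif detection with an exact null score distribution
# (PRIMA-style), plus the hypergeometric over-representation test.
#
# Scores are log2 odds log2(P(window|matrix)/P(window|background)) summed
# over columns, discretised to an integer grid of width `grain` bits so the
# null distribution under the order-0 background model can be computed
# exactly by dynamic programming over columns. A base with matrix
# probability 0 maps to a large negative sentinel (effectively -Inf).

NEG_SENTINEL <- -10000000L

# integer-scaled per-column log-odds scores (4 x W)
pwm_int_scores <- function(motif, background_freqs, grain = 0.001) {
  stopifnot(inherits(motif, "MotifMatrix"))
  bg <- validate_background_freqs(background_freqs)
  assert_scalar_number(grain, "grain", lower = 1e-12)
  if (any(bg == 0)) {
    stop("background frequencies must be strictly positive for log-odds scoring",
         call. = FALSE)
  }
  s <- log2(motif$matrix / bg)
  si <- round(s / grain)
  si[!is.finite(si)] <- NEG_SENTINEL
  storage.mode(si) <- "integer"
  si
}

#' Exact null distribution of a PWM's window score
#'
#' Computes, by dynamic programming over matrix columns, the exact
#' distribution of the integer-discretised log2-odds window score under the
#' order-0 background model. Used to set the scan threshold as an exact
#' quantile rather than by sampling.
#'
#' @param motif a \code{\link{motif_matrix}}.
#' @param background_freqs base frequencies (A,C,G,T) of the background
#'   model; must be strictly positive.
#' @param grain discretisation grain in bits (default 0.001); scores are
#'   rounded to multiples of \code{grain} before convolution.
#' @return a data frame with columns \code{score} (integer units of
#'   \code{grain}) and \code{prob}, sorted by score, probabilities summing
#'   to 1.
#' @export
pwm_null_distribution <- function(motif, background_freqs, grain = 0.001) {
  si <- pwm_int_scores(motif, background_freqs, grain)
  bg <- validate_background_freqs(background_freqs)
  W <- ncol(si)
  # dense convolution over the finite score support; windows touching a
  # zero-probability base (sentinel score, effectively -Inf) are collapsed
  # into a single floor atom whose background mass is retained
  fin <- si > NEG_SENTINEL
  if (!any(apply(fin, 2L, any))) {
    return(data.frame(score = NEG_SENTINEL, prob = 1))
  }
  col_min <- vapply(seq_len(W), function(j) min(si[fin[, j], j]), numeric(1))
  col_max <- vapply(seq_len(W), function(j) max(si[fin[, j], j]), numeric(1))
  lo <- 0; hi <- 0
  vec <- 1
  floorp <- 0
  for (j in seq_len(W)) {
    n_new <- hi + col_max[j] - (lo + col_min[j]) + 1
    new <- numeric(n_new)
    for (b in 1:4) {
      if (!fin[b, j]) next
      off <- si[b, j] - col_min[j]
      idx <- seq_along(vec) + off
      new[idx] <- new[idx] + vec * bg[b]
    }
    floorp <- floorp + sum(vec) * sum(bg[!fin[, j]])
    vec <- new
    lo <- lo + col_min[j]
    hi <- hi + col_max[j]
  }
  keep <- vec > 0
  scores <- as.integer(seq(lo, hi))[keep]
  probs <- vec[keep]
  if (floorp > 0) {
    scores <- c(NEG_SENTINEL, scores)
    probs <- c(floorp, probs)
  }
  data.frame(score = scores, prob = probs)
}

#' Score threshold at an exact null quantile
#'
#' @param null a distribution from \code{\link{pwm_null_distribution}}.
#' @param quantile the null quantile q; the threshold is the smallest
#'   integer score s with P(S >= s) <= 1 - q.
#' @return integer threshold (same units as the null distribution).
#' @export
prima_threshold <- function(null, quantile = 0.999) {
  assert_probability(quantile, "quantile")
  tail_p <- rev(cumsum(rev(null$prob)))
  ok <- which(tail_p <= (1 - quantile) + 1e-15)
  if (length(ok) == 0L) return(max(null$score) + 1L)
  null$score[min(ok)]
}

#' Threshold scan of promoters for putative binding sites
#'
#' Scores every window of every promoter on both strands with the
#' integer-discretised log2-odds score and calls a window a putative site
#' when its score reaches the exact null-quantile threshold. A gene is a
#' "hit" when it has at least one putative site. Windows containing
#' ambiguous bases are skipped and counted.
#'
#' @param promoters a \code{DNAStringSet} or named character vector.
#' @param motif a \code{\link{motif_matrix}}; must not be wider than the
#'   promoters.
#' @param background_freqs base frequencies of the background model;
#'   default is the empirical composition of \code{promoters}.
#' @param score_threshold_quantile null quantile for the threshold
#'   (default 0.999).
#' @param grain score discretisation grain in bits (default 0.001).
#' @param null optional precomputed null distribution (from
#'   \code{\link{pwm_null_distribution}} with the same motif, background
#'   and grain) to avoid recomputation in repeated scans.
#' @return a list with \code{hits} (named logical per gene),
#'   \code{positions} (data frame gene_id, position — 0-based start in
#'   forward-strand coordinates — strand, score in grain units),
#'   \code{threshold}, \code{n_windows} (scored), \code{n_skipped}
#'   (ambiguous windows), and \code{null} (the null distribution).
#' @export
scan_prima <- function(promoters, motif, background_freqs = NULL,
                       score_threshold_quantile = 0.999, grain = 0.001,
                       null = NULL) {
  seqs <- as_promoter_chr(promoters)
  if (is.null(background_freqs)) background_freqs <- base_frequencies(seqs)
  si <- pwm_int_scores(motif, background_freqs, grain)
  W <- ncol(si)
  if (any(nchar(seqs) < W)) {
    stop("motif is wider than at least one promoter", call. = FALSE)
  }
  if (is.null(null)) null <- pwm_null_distribution(motif, background_freqs, grain)
  thr <- prima_threshold(null, score_threshold_quantile)

  codes <- encode_promoter_codes(seqs)
  hits <- logical(length(seqs))
  names(hits) <- names(seqs)
  pos_list <- list()
  n_windows <- 0L
  n_skipped <- 0L
  for (i in seq_along(seqs)) {
    fwd <- codes[[i]]$fwd
    sf <- .pwm_window_scores_cpp(fwd, si)
    sr <- .pwm_window_scores_cpp(codes[[i]]$rc, si)
    n_windows <- n_windows + sum(!is.na(sf)) + sum(!is.na(sr))
    n_skipped <- n_skipped + sum(is.na(sf)) + sum(is.na(sr))
    hf <- which(!is.na(sf) & sf >= thr)
    hr <- which(!is.na(sr) & sr >= thr)
    if (length(hf) || length(hr)) {
      hits[i] <- TRUE
      L <- length(fwd)
      pos_list[[length(pos_list) + 1L]] <- data.frame(
        gene_id = names(seqs)[i],
        position = c(hf - 1L, L - W + 1L - hr),  # 0-based forward coords
        strand = c(rep("+", length(hf)), rep("-", length(hr))),
        score = c(sf[hf], sr[hr]),
        stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(pos_list)) do.call(rbind, pos_list) else
    data.frame(gene_id = character(0), position = integer(0),
               strand = character(0), score = integer(0),
               stringsAsFactors = FALSE)
  list(hits = hits, positions = positions, threshold = thr,
       n_windows = n_windows, n_skipped = n_skipped, null = null,
       grain = grain)
}

# hit indicators from precomputed codes (fast path for library scans)
prima_hits_codes <- function(codes, si, thr) {
  vapply(codes, function(cd) {
    sf <- .pwm_window_scores_cpp(cd$fwd, si)
    if (any(!is.na(sf) & sf >= thr)) return(TRUE)
    sr <- .pwm_window_scores_cpp(cd$rc, si)
    any(!is.na(sr) & sr >= thr)
  }, logical(1))
}

#' Upper-tail hypergeometric over-representation test
#'
#' Probability of observing at least \code{k} hit genes among \code{n}
#' target genes when \code{K} of the \code{N} background genes are hits:
#' \eqn{P(X \ge k)} for \eqn{X \sim Hypergeom(N, K, n)}. The target set is
#' assumed to be a subset of the background set.
#'
#' @param k hit genes in the target set.
#' @param n target set size.
#' @param K hit genes in the background set.
#' @param N background set size.
#' @return the raw upper-tail p-value.
#' @export
#' @examples
#' hypergeom_enrichment(k = 4, n = 4, K = 5, N = 10)  # 5/210
hypergeom_enrichment <- function(k, n, K, N) {
  k <- assert_count(k, "k", min = 0L)
  n <- assert_count(n, "n", min = 0L)
  K <- assert_count(K, "K", min = 0L)
  N <- assert_count(N, "N", min = 1L)
  if (n > N || K > N || k > min(n, K) || k < max(0L, n - (N - K))) {
    stop("inconsistent hypergeometric counts (need n <= N, K <= N, max(0, n-(N-K)) <= k <= min(n, K))",
         call. = FALSE)
  }
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Write hit positions as BED
#'
#' 0-based, half-open intervals with the motif score and strand.
#'
#' @param positions the \code{positions} table from \code{\link{scan_prima}}.
#' @param width motif width (interval length).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(positions, width, path) {
  bed <- data.frame(chrom = positions$gene_id,
                    start = positions$position,
                    end = positions$position + width,
                    name = paste0("site", seq_len(nrow(positions))),
                    score = positions$score,
                    strand = positions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
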