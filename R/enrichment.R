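# Orchestration of binding-site enrichment over a motif library, two
# methods and several gene sets, with per-stratum FDR correction.

#' Run binding-site enrichment over a motif library
#'
#' For every motif x method x gene-set combination, computes a raw
#' enrichment p-value of the target promoters against the background
#' promoters: the threshold-scan method ("prima") counts hit genes and
#' applies the upper-tail hypergeometric test; the HMM method ("demon")
#' scores every promoter with the motif HMM and applies the one-sided
#' rank-sum test. Benjamini-Hochberg correction is applied across the
#' motif library within each method x gene-set stratum (mirroring testing
#' one library of matrices at a time).
#'
#' @param promoters a \code{DNAStringSet} or named character vector
#'   containing every background (and hence target) promoter.
#' @param target_sets a character vector of target gene ids (labelled set
#'   "all"), or a named list of such vectors (e.g. list(all=, down=, up=)).
#' @param background_ids gene ids of the background set; every target set
#'   must be a subset.
#' @param matrices list of \code{\link{motif_matrix}} objects.
#' @param methods any of "prima", "demon".
#' @param fdr_threshold q-value threshold recorded on the result rows.
#' @param score_threshold_quantile PRIMA null quantile (default 0.999).
#' @param tau DEMON site-entry rate; default 1/median promoter length.
#' @param background_freqs background base frequencies; default empirical
#'   composition of the background promoters.
#' @param grain PRIMA score discretisation grain (bits).
#' @return data frame of class \code{EnrichmentResult}, one row per motif
#'   x method x set, sorted by q within stratum: motif_id, method, set, p,
#'   q, significant, and supporting counts (k, n, K, N for prima; median
#'   target/background scores for demon).
#' @export
run_enrichment <- function(promoters, target_sets, background_ids,
                           matrices, methods = c("prima", "demon"),
                           fdr_threshold = 0.05,
                           score_threshold_quantile = 0.999,
                           tau = NULL, background_freqs = NULL,
                           grain = 0.001) {
  seqs <- as_promoter_chr(promoters)
  if (is.character(target_sets)) target_sets <- list(all = target_sets)
  if (!is.list(target_sets) || is.null(names(target_sets))) {
    stop("target_sets must be a character vector or a named list", call. = FALSE)
  }
  methods <- match.arg(methods, c("prima", "demon"), several.ok = TRUE)
  if (length(matrices) == 0L) {
    return(structure(data.frame(motif_id = character(0), method = character(0),
                                set = character(0), p = numeric(0),
                                q = numeric(0)),
                     class = c("EnrichmentResult", "data.frame")))
  }
  missing_bg <- setdiff(background_ids, names(seqs))
  if (length(missing_bg)) {
    stop(sprintf("background ids absent from promoter set: %s",
                 paste(head(missing_bg, 5), collapse = ", ")), call. = FALSE)
  }
  for (nm in names(target_sets)) {
    miss <- setdiff(target_sets[[nm]], names(seqs))
    if (length(miss)) {
      stop(sprintf("target ids (set '%s') absent from promoter set: %s",
                   nm, paste(head(miss, 5), collapse = ", ")), call. = FALSE)
    }
    out <- setdiff(target_sets[[nm]], background_ids)
    if (length(out)) {
      stop(sprintf("target set '%s' is not a subset of the background set",
                   nm), call. = FALSE)
    }
  }
  bg_seqs <- seqs[background_ids]
  if (is.null(background_freqs)) background_freqs <- base_frequencies(bg_seqs)
  background_freqs <- validate_background_freqs(background_freqs)
  if (is.null(tau)) tau <- 1 / median(nchar(bg_seqs))

  codes <- encode_promoter_codes(bg_seqs)
  log_bg <- log(background_freqs)
  bgll <- function(v) { k <- v >= 0L & v <= 3L; sum(log_bg[v[k] + 1L]) }
  bgll_fwd <- vapply(codes, function(cd) bgll(cd$fwd), numeric(1))
  bgll_rc <- vapply(codes, function(cd) bgll(cd$rc), numeric(1))

  rows <- list()
  for (mat in matrices) {
    if ("prima" %in% methods) {
      si <- pwm_int_scores(mat, background_freqs, grain)
      null <- pwm_null_distribution(mat, background_freqs, grain)
      thr <- prima_threshold(null, score_threshold_quantile)
      hits <- setNames(prima_hits_codes(codes, si, thr), names(bg_seqs))
      K <- sum(hits)
      N <- length(bg_seqs)
      for (nm in names(target_sets)) {
        ids <- target_sets[[nm]]
        k <- sum(hits[ids])
        p <- hypergeom_enrichment(k, length(ids), K, N)
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = mat$motif_id, method = "prima", set = nm, p = p,
          k = k, n = length(ids), K = K, N = N,
          median_target = NA_real_, median_background = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if ("demon" %in% methods) {
      hmm <- motif_hmm(mat, background_freqs, tau)
      scores <- setNames(demon_scores_codes(codes, hmm, bgll_fwd, bgll_rc),
                         names(bg_seqs))
      for (nm in names(target_sets)) {
        ids <- target_sets[[nm]]
        tgt <- scores[ids]
        bgs <- scores[setdiff(background_ids, ids)]
        if (length(bgs) == 0L) bgs <- scores  # target == background
        p <- demon_enrichment(tgt, bgs)
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = mat$motif_id, method = "demon", set = nm, p = p,
          k = NA_integer_, n = length(ids), K = NA_integer_,
          N = length(bg_seqs),
          median_target = median(tgt), median_background = median(bgs),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (meth in unique(res$method)) {
    for (nm in unique(res$set)) {
      idx <- res$method == meth & res$set == nm
      res$q[idx] <- fdr_adjust(res$p[idx])
    }
  }
  res$significant <- res$q < fdr_threshold
  res <- res[order(res$method, res$set, res$q, res$p), ]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"))
}

#' Read a gene list (one id per line)
#' @param path text file.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[ids != ""]
}

#' Write a gene list (one id per line)
#' @param ids character vector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
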