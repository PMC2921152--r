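#' Construct a motif matrix (PWM)
#'
#' A motif matrix is a 4 x W column-stochastic probability matrix with rows
#' A, C, G, T.
#'
#' @param motif_id identifier.
#' @param mat 4 x W numeric matrix; columns must each sum to 1 (within
#'   1e-9) and W must be at least 2.
#' @param source "transfac" or "constructed".
#' @param pseudocount the pseudocount used in construction (metadata).
#' @return object of class \code{MotifMatrix}.
#' @export
motif_matrix <- function(motif_id, mat, source = c("constructed", "transfac"),
                         pseudocount = NA_real_) {
  source <- match.arg(source)
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != 4L) {
    stop("mat must be a numeric 4 x W matrix", call. = FALSE)
  }
  if (ncol(mat) < 2L) stop("motif width must be >= 2", call. = FALSE)
  if (any(mat < 0)) stop("matrix entries must be non-negative", call. = FALSE)
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("matrix columns must each sum to 1 (within 1e-9)", call. = FALSE)
  }
  rownames(mat) <- DNA_BASES4
  structure(list(motif_id = as.character(motif_id), matrix = mat,
                 source = source, pseudocount = pseudocount),
            class = "MotifMatrix")
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cat(sprintf("MotifMatrix '%s' (%s), width %d, consensus %s\n",
              x$motif_id, x$source, ncol(x$matrix), motif_consensus(x)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Consensus sequence of a motif (most probable base per column)
#' @param motif a \code{MotifMatrix}.
#' @return a character string of length W.
#' @export
motif_consensus <- function(motif) {
  stopifnot(inherits(motif, "MotifMatrix"))
  paste(DNA_BASES4[apply(motif$matrix, 2L, which.max)], collapse = "")
}

#' Reverse-complement a motif matrix
#' @param motif a \code{MotifMatrix}.
#' @return a \code{MotifMatrix} for the opposite strand.
#' @export
motif_reverse_complement <- function(motif) {
  stopifnot(inherits(motif, "MotifMatrix"))
  m <- motif$matrix[4:1, ncol(motif$matrix):1, drop = FALSE]
  rownames(m) <- DNA_BASES4
  motif_matrix(motif$motif_id, m, source = motif$source,
               pseudocount = motif$pseudocount)
}

#' Build a PWM from a single linear binding-site sequence
#'
#' Each column assigns weight 1 to the observed base and 0 to the others,
#' then a symmetric pseudocount corrects the indicators to allow flexible
#' recognition: the observed base gets probability
#' \eqn{(1+\epsilon)/(1+4\epsilon)} and every other base
#' \eqn{\epsilon/(1+4\epsilon)}. This is how a single published site (such
#' as the poly-pyrimidine SSDP site) is turned into a scannable matrix.
#'
#' @param site a DNA string over A/C/G/T, length >= 2.
#' @param pseudocount \eqn{\epsilon \ge 0} (default 0.1).
#' @param motif_id identifier (default "site").
#' @return a \code{MotifMatrix} with source "constructed".
#' @export
#' @examples
#' build_pwm_from_site("CTCTTT", pseudocount = 0.1, motif_id = "SSDP")
build_pwm_from_site <- function(site, pseudocount = 0.1, motif_id = "site") {
  if (!is.character(site) || length(site) != 1L || nchar(site) < 2L) {
    stop("site must be a single DNA string of length >= 2", call. = FALSE)
  }
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  codes <- encode_dna(site)
  bad <- which(codes < 0L)
  if (length(bad)) {
    stop(sprintf("invalid characters in site at position(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  W <- length(codes)
  eps <- pseudocount
  mat <- matrix(eps / (1 + 4 * eps), nrow = 4L, ncol = W)
  mat[cbind(codes + 1L, seq_len(W))] <- (1 + eps) / (1 + 4 * eps)
  motif_matrix(motif_id, mat, source = "constructed", pseudocount = eps)
}

# TRANSFAC flat-file matrix I/O -----------------------------------------
#
# Minimal dialect: records separated by //, an ID line, a P0 header naming
# the base order, numbered count rows (01, 02, ...) with 4 values and an
# optional consensus letter. Anything else is carried over as ignorable.

#' Load motif matrices from a TRANSFAC-style flat file
#'
#' @param path file in TRANSFAC matrix format.
#' @param pseudocount per-base pseudocount added when converting counts to
#'   column probabilities: \eqn{p = (count + \epsilon) / (total + 4\epsilon)}
#'   (default 0).
#' @return a named list of \code{MotifMatrix} objects (source "transfac").
#' @export
load_transfac_matrices <- function(path, pseudocount = 0) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  id <- NULL
  base_order <- NULL
  counts <- NULL
  flush_record <- function(lineno) {
    if (is.null(id)) return(invisible(NULL))
    if (is.null(counts) || length(counts) == 0L) {
      stop(sprintf("matrix record '%s' has no count rows (near line %d)",
                   id, lineno), call. = FALSE)
    }
    m <- do.call(cbind, counts)  # 4 x W in file base order
    m <- m[match(DNA_BASES4, base_order), , drop = FALSE]
    eps <- pseudocount
    probs <- sweep(m + eps, 2L, colSums(m) + 4 * eps, "/")
    out[[id]] <<- motif_matrix(id, probs, source = "transfac",
                               pseudocount = eps)
    id <<- NULL; base_order <<- NULL; counts <<- NULL
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^XX", ln)) next
    if (grepl("^//", ln)) { flush_record(i); next }
    if (grepl("^ID\\s+", ln)) {
      id <- sub("^ID\\s+", "", ln)
      next
    }
    if (grepl("^(P0|PO)\\s+", ln)) {
      base_order <- toupper(strsplit(sub("^(P0|PO)\\s+", "", ln),
                                     "\\s+")[[1]])
      if (!setequal(base_order, DNA_BASES4)) {
        stop(sprintf("record '%s': P0 line must name A C G T (line %d)",
                     if (is.null(id)) "?" else id, i), call. = FALSE)
      }
      counts <- list()
      next
    }
    if (grepl("^[0-9]+\\s+", ln)) {
      if (is.null(base_order)) {
        stop(sprintf("count row before P0 header at line %d", i),
             call. = FALSE)
      }
      fields <- strsplit(ln, "\\s+")[[1]][-1]
      vals <- suppressWarnings(as.numeric(fields))
      vals <- vals[!is.na(vals)]
      if (length(vals) != 4L) {
        stop(sprintf("record '%s': malformed count row at line %d (need 4 numeric values)",
                     if (is.null(id)) "?" else id, i), call. = FALSE)
      }
      counts[[length(counts) + 1L]] <- vals
      next
    }
    # other annotation lines (AC, BF, DE, ...) are ignored
  }
  flush_record(length(lines))
  if (length(out) == 0L) stop("no matrix records found in file", call. = FALSE)
  out
}

#' Write motif matrices in TRANSFAC flat format
#'
#' Probabilities are written at full precision so that a round trip through
#' \code{\link{load_transfac_matrices}} (with pseudocount 0) reproduces the
#' matrices exactly.
#'
#' @param matrices list of \code{MotifMatrix} objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_transfac_matrices <- function(matrices, path) {
  if (inherits(matrices, "MotifMatrix")) matrices <- list(matrices)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in matrices) {
    stopifnot(inherits(m, "MotifMatrix"))
    writeLines(sprintf("ID %s", m$motif_id), con)
    writeLines("P0      A      C      G      T", con)
    for (j in seq_len(ncol(m$matrix))) {
      writeLines(sprintf("%02d %s %s", j,
                         paste(format(m$matrix[, j], digits = 17),
                               collapse = " "),
                         motif_consensus(m) |> substr(j, j)), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' The packaged placeholder SSDP binding site
#'
#' SSDP was identified through binding to a single-stranded poly-pyrimidine
#' element; the exact published site sequence is not redistributed here.
#' This accessor returns a synthetic poly-pyrimidine placeholder
#' (non-canonical, clearly labelled) so the single-site matrix-construction
#' path can run end to end; supply your own site sequence to
#' \code{\link{build_pwm_from_site}} for real analyses.
#'
#' @param pseudocount flexibility correction passed to
#'   \code{\link{build_pwm_from_site}} (default 0.1).
#' @return a \code{MotifMatrix} with id "SSDP_placeholder".
#' @export
ssdp_placeholder_matrix <- function(pseudocount = 0.1) {
  build_pwm_from_site("CTTCTCCTCTCC", pseudocount = pseudocount,
                      motif_id = "SSDP_placeholder")
}
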