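# Candidate target-gene selection from two-channel arrays: within-array
# print-tip loess and between-array quantile normalisation, low-intensity
# filtering, per-gene fixed-effect ANOVA across mutant/control contrasts,
# BH correction and up/down partitioning.

#' Construct an ArrayExperiment from element and design tables
#'
#' @param elements data frame with columns element_id, gene_id, array_id,
#'   printtip, ch1, ch2 (raw non-negative channel intensities). Duplicate
#'   elements per gene are permitted and are never averaged.
#' @param design data frame with columns array_id, genotype_group
#'   ("mutant"/"control") and optionally contrast_pair.
#' @return object of class \code{ArrayExperiment}.
#' @export
array_experiment <- function(elements, design) {
  need <- c("element_id", "gene_id", "array_id", "printtip", "ch1", "ch2")
  if (!all(need %in% names(elements))) {
    stop(sprintf("elements table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(elements$ch1 < 0) || any(elements$ch2 < 0)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  if (!all(c("array_id", "genotype_group") %in% names(design))) {
    stop("design must have columns array_id and genotype_group", call. = FALSE)
  }
  missing_arr <- setdiff(unique(elements$array_id), design$array_id)
  if (length(missing_arr)) {
    stop(sprintf("arrays without design annotation: %s",
                 paste(missing_arr, collapse = ", ")), call. = FALSE)
  }
  if (is.null(design$contrast_pair)) design$contrast_pair <- "pairA"
  structure(list(elements = elements, design = design, truth = NULL),
            class = "ArrayExperiment")
}

#' Flag low-intensity array elements
#'
#' An element is flagged (discarded downstream) when its intensity is
#' strictly below the per-array median in \emph{both} channels; ties with
#' the median are retained. No other background correction is applied.
#'
#' @param exp an \code{ArrayExperiment}.
#' @return the experiment with a logical \code{filtered} column added to
#'   \code{$elements}.
#' @export
filter_low_intensity <- function(exp) {
  stopifnot(inherits(exp, "ArrayExperiment"))
  el <- exp$elements
  med1 <- stats::ave(el$ch1, el$array_id, FUN = median)
  med2 <- stats::ave(el$ch2, el$array_id, FUN = median)
  el$filtered <- el$ch1 < med1 & el$ch2 < med2
  exp$elements <- el
  exp
}

#' Within-array print-tip loess normalisation
#'
#' Per array and print-tip group, fits a locally weighted regression of
#' the log ratio M on the mean log intensity A and subtracts the fitted
#' trend; A is unchanged. Elements already flagged by
#' \code{\link{filter_low_intensity}} are excluded from the fit and keep
#' their raw M.
#'
#' @param exp an \code{ArrayExperiment} (optionally already filtered).
#' @param span loess span (default 0.3, the two-colour convention).
#' @return object of class \code{NormalizedExperiment}: list with
#'   \code{data} (element_id, gene_id, array_id, printtip, M, A, filtered)
#'   and the \code{design} table.
#' @export
normalize_within_array <- function(exp, span = 0.3) {
  stopifnot(inherits(exp, "ArrayExperiment"))
  assert_scalar_number(span, "span", lower = 0.05, upper = 1)
  el <- exp$elements
  if (is.null(el$filtered)) el$filtered <- FALSE
  if (any(el$ch1 <= 0 | el$ch2 <= 0)) {
    stop("zero intensities cannot be log-transformed; filter them first",
         call. = FALSE)
  }
  M <- log2(el$ch1) - log2(el$ch2)
  A <- (log2(el$ch1) + log2(el$ch2)) / 2
  key <- interaction(el$array_id, el$printtip, drop = TRUE)
  cnt <- table(key[!el$filtered])
  if (any(cnt < 10)) {
    bad <- names(cnt)[cnt < 10][1]
    stop(sprintf("print-tip group '%s' has fewer than 10 usable elements",
                 bad), call. = FALSE)
  }
  for (g in levels(key)) {
    idx <- which(key == g & !el$filtered)
    fit <- limma::loessFit(M[idx], A[idx], span = span)
    M[idx] <- M[idx] - fit$fitted
  }
  structure(list(data = data.frame(
    element_id = el$element_id, gene_id = el$gene_id,
    array_id = el$array_id, printtip = el$printtip,
    M = M, A = A, filtered = el$filtered, stringsAsFactors = FALSE),
    design = exp$design), class = "NormalizedExperiment")
}

# quantile-normalise the columns of a matrix to the mean of order
# statistics (thin wrapper kept visible for testing)
quantile_normalize_matrix <- function(x) {
  limma::normalizeQuantiles(x)
}

#' Between-array quantile normalisation
#'
#' The two log2 channel intensity vectors of every array (recovered from M
#' and A) are quantile-normalised jointly across all arrays and channels —
#' every column is mapped onto the mean of the order statistics — and M
#' and A are recomputed. Requires complete element sets: every array must
#' carry the same elements.
#'
#' @param norm a \code{NormalizedExperiment}.
#' @return a \code{NormalizedExperiment} with updated M and A.
#' @export
normalize_between_arrays <- function(norm) {
  stopifnot(inherits(norm, "NormalizedExperiment"))
  d <- norm$data
  arrays <- unique(d$array_id)
  if (length(arrays) < 2L) {
    stop("between-array normalisation needs at least 2 arrays", call. = FALSE)
  }
  counts <- table(d$array_id)
  if (length(unique(counts)) != 1L) {
    stop("arrays have unequal element counts; complete element sets required",
         call. = FALSE)
  }
  ord <- order(d$array_id, d$element_id)
  if (anyDuplicated(d$element_id[d$array_id == arrays[1]])) {
    # duplicate element ids: order must still align across arrays
    per <- split(d$element_id[ord], d$array_id[ord])
    if (!all(vapply(per, identical, logical(1), per[[1]]))) {
      stop("element sets differ across arrays", call. = FALSE)
    }
  }
  n_el <- counts[[1]]
  idx <- matrix(ord, nrow = n_el)  # rows elements, cols arrays
  l2ch1 <- matrix(d$A[idx] + d$M[idx] / 2, nrow = n_el)
  l2ch2 <- matrix(d$A[idx] - d$M[idx] / 2, nrow = n_el)
  qn <- quantile_normalize_matrix(cbind(l2ch1, l2ch2))
  k <- ncol(l2ch1)
  q1 <- qn[, seq_len(k), drop = FALSE]
  q2 <- qn[, k + seq_len(k), drop = FALSE]
  d$M[idx] <- q1 - q2
  d$A[idx] <- (q1 + q2) / 2
  norm$data <- d
  norm
}

#' Per-gene fixed-effect ANOVA for differential expression
#'
#' For each gene, fits a fixed-effect linear model of the normalised log
#' ratio M with a genotype-class factor (trans-heteroallelic mutant vs
#' corresponding heterozygote control) across all hybridizations, plus a
#' contrast-pair covariate when more than one pair is present. The F-test
#' of the genotype term gives the raw p-value; the sign of the
#' mutant-minus-control mean M gives the direction. Filtered elements are
#' excluded. Genes with fewer than 2 usable observations in either
#' genotype class get NA p-values and are excluded from FDR correction.
#'
#' @param norm a \code{NormalizedExperiment}.
#' @return object of class \code{DEResult}: data frame with columns
#'   gene_id, F, p, q, direction ("down"/"up"/NA), effect (mean mutant
#'   minus control M), n_obs.
#' @export
anova_differential <- function(norm) {
  stopifnot(inherits(norm, "NormalizedExperiment"))
  d <- norm$data[!norm$data$filtered, , drop = FALSE]
  des <- norm$design
  d$group <- des$genotype_group[match(d$array_id, des$array_id)]
  d$pair <- des$contrast_pair[match(d$array_id, des$array_id)]
  use_pair <- length(unique(d$pair)) > 1L

  genes <- unique(norm$data$gene_id)
  res <- data.frame(gene_id = genes, F = NA_real_, p = NA_real_,
                    q = NA_real_, direction = NA_character_,
                    effect = NA_real_, n_obs = 0L,
                    stringsAsFactors = FALSE)
  sp <- split(seq_len(nrow(d)), d$gene_id)
  for (g in names(sp)) {
    rows <- d[sp[[g]], ]
    i <- match(g, res$gene_id)
    res$n_obs[i] <- nrow(rows)
    tab <- table(factor(rows$group, levels = c("control", "mutant")))
    if (any(tab < 2L)) next  # unreplicated: p left NA
    eff <- mean(rows$M[rows$group == "mutant"]) -
      mean(rows$M[rows$group == "control"])
    res$effect[i] <- eff
    if (var(rows$M) < 1e-24) {  # constant response: no evidence
      res$F[i] <- 0
      res$p[i] <- 1
      next
    }
    fml <- if (use_pair && length(unique(rows$pair)) > 1L) {
      M ~ pair + group
    } else {
      M ~ group
    }
    fit <- lm(fml, data = rows)
    av <- anova(fit)
    j <- match("group", rownames(av))
    Fv <- av[j, "F value"]
    pv <- av[j, "Pr(>F)"]
    if (!is.finite(Fv)) {  # zero residual variance with a real effect
      Fv <- Inf
      pv <- 0
    }
    res$F[i] <- Fv
    res$p[i] <- pv
  }
  tested <- !is.na(res$p)
  res$q[tested] <- fdr_adjust(res$p[tested])
  res$direction[tested] <- ifelse(res$effect[tested] < 0, "down",
                                  ifelse(res$effect[tested] > 0, "up",
                                         NA_character_))
  class(res) <- c("DEResult", class(res))
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' clipped to 1.
#'
#' @param pvalues numeric vector of p-values in [0,1].
#' @return vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numeric in [0,1] with no NA", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed target genes
#'
#' Genes with q below the threshold, partitioned by direction relative to
#' the heterozygote controls (down = lower in mutants).
#'
#' @param de a \code{DEResult}.
#' @param threshold FDR threshold (default 0.05).
#' @return list with character vectors \code{down}, \code{up} and the
#'   combined \code{selected}.
#' @export
select_targets <- function(de, threshold = 0.05) {
  stopifnot(inherits(de, "DEResult"))
  assert_probability(threshold, "threshold")
  sel <- !is.na(de$q) & de$q < threshold & !is.na(de$direction)
  list(down = de$gene_id[sel & de$direction == "down"],
       up = de$gene_id[sel & de$direction == "up"],
       selected = de$gene_id[sel])
}

#' Write a DEResult as TSV
#' @param de a \code{DEResult}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_de_result <- function(de, path) {
  write_tsv(as.data.frame(de), path)
}
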