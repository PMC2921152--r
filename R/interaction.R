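# Statistics and calling rules of the dominant-modifier screens:
# wing-notching severity distributions (rank test over ordinal classes),
# scutellar-bristle duplication (pseudocount control rate + exact binomial
# tails + FDR), and Table-style gene x sensitizer summaries.

#' Rank test for a shift between two ordinal severity distributions
#'
#' Expands class counts to per-fly severity values and compares the two
#' independent samples by the rank-sum statistic (the rank-based test
#' appropriate for two independent ordinal samples; the original study
#' refers to its rank test by the Wilcoxon name, preserved in the output
#' metadata). The two-sided p-value uses the normal approximation with tie
#' correction — ties are ubiquitous with a handful of classes. Direction:
#' "enhancer" when the test sample is stochastically more severe (higher
#' mean rank) than the control, "suppressor" when less severe.
#'
#' @param test,control \code{\link{severity_distribution}} objects over the
#'   same class scheme, each with at least 10 flies.
#' @return list with \code{p} (two-sided), \code{direction} ("enhancer",
#'   "suppressor" or "none"), \code{statistic} (test-sample rank sum),
#'   \code{method}.
#' @export
wing_severity_test <- function(test, control) {
  stopifnot(inherits(test, "SeverityDistribution"),
            inherits(control, "SeverityDistribution"))
  if (length(test$counts) != length(control$counts)) {
    stop("test and control use different class schemes", call. = FALSE)
  }
  n <- sum(test$counts)
  m <- sum(control$counts)
  if (n < 10 || m < 10) {
    stop("both distributions need at least 10 flies", call. = FALSE)
  }
  x <- rep(seq_along(test$counts), test$counts)
  y <- rep(seq_along(control$counts), control$counts)
  r <- rank(c(x, y))
  stat <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(p = 1, direction = "none", statistic = stat,
                method = "Wilcoxon rank test (normal approximation, tie-corrected)"))
  }
  z <- (stat - mu) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  direction <- if (z > 0) "enhancer" else if (z < 0) "suppressor" else "none"
  list(p = min(p, 1), direction = direction, statistic = stat,
       method = "Wilcoxon rank test (normal approximation, tie-corrected)")
}

#' Combine per-sex, per-allele wing results into an interactor call
#'
#' A gene is designated an interactor ("+" enhancer or "-" suppressor)
#' when every significant result agrees in direction and either (a) every
#' allele is significant in both sexes, or (b) at least one allele is
#' significant in both sexes and every other allele is significant in at
#' least one sex with the same direction. Anything else — including
#' significant results with conflicting directions — is "0" (the conflict
#' case is flagged).
#'
#' @param results data frame with columns \code{allele}, \code{sex}
#'   ("female"/"male"), \code{p}, \code{direction} ("enhancer"/
#'   "suppressor"/"none"); one row per allele x sex.
#' @param alpha significance threshold (default 0.05).
#' @param gene gene label carried to the call.
#' @return list with \code{gene}, \code{code} ("+", "-" or "0"),
#'   \code{conflict} (logical) and \code{n_alleles}.
#' @export
call_wing_interactor <- function(results, alpha = 0.05, gene = "") {
  need <- c("allele", "sex", "p", "direction")
  if (!all(need %in% names(results)) || nrow(results) == 0L) {
    stop("results must have columns allele, sex, p, direction", call. = FALSE)
  }
  assert_probability(alpha, "alpha")
  results$sig <- results$p < alpha & results$direction %in%
    c("enhancer", "suppressor")
  sig_dirs <- unique(results$direction[results$sig])
  conflict <- length(sig_dirs) > 1L
  code <- "0"
  if (!conflict && length(sig_dirs) == 1L) {
    per_allele <- vapply(split(results, results$allele),
                         function(a) sum(a$sig), integer(1))
    both <- per_allele >= 2L
    one <- per_allele >= 1L
    if (any(both) && all(one)) {
      code <- if (sig_dirs == "enhancer") "+" else "-"
    }
  }
  list(gene = gene, code = code, conflict = conflict,
       n_alleles = length(unique(results$allele)))
}

#' Control frequency of the duplicated-bristle phenotype
#'
#' The pseudocounted rate \eqn{\hat p = (d + 1)/(n + 1)} from the control
#' cross, where n is the total number of flies and d the number displaying
#' the duplicated scutellar bristle phenotype.
#'
#' @param control a \code{\link{bristle_cross}} with role "control".
#' @return the estimated probability.
#' @export
#' @examples
#' bristle_control_rate(bristle_cross(99, 3, role = "control"))  # 0.04
bristle_control_rate <- function(control) {
  stopifnot(inherits(control, "BristleCross"))
  if (control$role != "control") {
    stop("control rate must be computed from a control cross", call. = FALSE)
  }
  (control$d + 1) / (control$n + 1)
}

#' Exact binomial test of a bristle modifier cross
#'
#' Compares the duplicated-bristle count of a test cross of m flies with
#' the binomial model Binomial(m, p̂) at the control rate p̂: the
#' enhancement p-value is the exact upper tail P(X >= d) and the
#' suppression p-value the exact lower tail P(X <= d). The reported p is
#' the smaller tail with the corresponding direction.
#'
#' @param test a \code{\link{bristle_cross}} with role "test".
#' @param p_hat control rate from \code{\link{bristle_control_rate}}, in
#'   (0, 1].
#' @return list with \code{p} (min tail), \code{direction}
#'   ("enhancer"/"suppressor"), \code{p_enhance}, \code{p_suppress},
#'   \code{d}, \code{m}.
#' @export
bristle_binomial_test <- function(test, p_hat) {
  stopifnot(inherits(test, "BristleCross"))
  if (test$role != "test") {
    stop("bristle_binomial_test expects a test cross", call. = FALSE)
  }
  assert_scalar_number(p_hat, "p_hat", lower = 0, upper = 1)
  if (p_hat <= 0) stop("p_hat must be in (0, 1]", call. = FALSE)
  m <- test$n
  if (m < 1) stop("test cross must contain at least one fly", call. = FALSE)
  d <- test$d
  p_up <- pbinom(d - 1, m, p_hat, lower.tail = FALSE)  # P(X >= d)
  p_dn <- pbinom(d, m, p_hat)                          # P(X <= d)
  if (p_up <= p_dn) {
    list(p = p_up, direction = "enhancer", p_enhance = p_up,
         p_suppress = p_dn, d = d, m = m)
  } else {
    list(p = p_dn, direction = "suppressor", p_enhance = p_up,
         p_suppress = p_dn, d = d, m = m)
  }
}

#' FDR-correct a bristle screen and call interactors
#'
#' Benjamini-Hochberg correction across all test crosses of the screen;
#' a cross is called "+" (enhancer) or "-" (suppressor) when its q-value
#' is below the threshold, else "0".
#'
#' @param tests list of results from \code{\link{bristle_binomial_test}},
#'   optionally named by gene.
#' @param fdr_threshold q-value threshold (default 0.05).
#' @return data frame with columns gene, p, q, direction, code.
#' @export
bristle_fdr_and_call <- function(tests, fdr_threshold = 0.05) {
  if (length(tests) == 0L) stop("no tests supplied", call. = FALSE)
  assert_probability(fdr_threshold, "fdr_threshold")
  p <- vapply(tests, function(t) t$p, numeric(1))
  dir <- vapply(tests, function(t) t$direction, character(1))
  q <- fdr_adjust(p)
  code <- ifelse(q < fdr_threshold, ifelse(dir == "enhancer", "+", "-"), "0")
  genes <- names(tests)
  if (is.null(genes)) genes <- sprintf("test%02d", seq_along(tests))
  data.frame(gene = genes, p = p, q = q, direction = dir, code = code,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Table-style gene x sensitizer interaction tables ----------------------

SCREEN_CODES <- c("+", "-", "0", "n")

normalize_code <- function(x) {
  x <- trimws(x)
  x[x == "−"] <- "-"  # unicode minus
  x
}

#' Parse a gene-by-sensitizer interaction table
#'
#' Reads a TSV with a header row: gene id and symbol columns followed by
#' one column per sensitizer genotype, cells coded "+" (enhancer), "-"
#' (suppressor), "0" (no interaction) or "n" (not tested). The unicode
#' minus sign is accepted for "-".
#'
#' @param path TSV file.
#' @return object of class \code{ScreenTable}: data frame with attributes
#'   \code{sensitizers} (the sensitizer column names).
#' @export
parse_screen_table <- function(path) {
  tab <- read_tsv(path, check.names = FALSE)
  if (ncol(tab) < 3L) {
    stop("screen table needs gene columns plus at least one sensitizer column",
         call. = FALSE)
  }
  sens <- names(tab)[-(1:2)]
  for (s in sens) {
    tab[[s]] <- normalize_code(as.character(tab[[s]]))
    bad <- which(!tab[[s]] %in% SCREEN_CODES)
    if (length(bad)) {
      stop(sprintf("unknown interaction code '%s' at row %d, column '%s'",
                   tab[[s]][bad[1]], bad[1], s), call. = FALSE)
    }
  }
  structure(tab, sensitizers = sens, class = c("ScreenTable", "data.frame"))
}

#' The packaged replica of the published interaction table
#'
#' Loads the gene-by-sensitizer interaction table distributed with the
#' package: 39 candidate target genes scored against the wing-notching
#' sensitizer (Dlmo) and the two bristle-duplication sensitizers (ssdp,
#' Chip).
#'
#' @return a \code{ScreenTable}.
#' @export
ldb_screen_table <- function() {
  parse_screen_table(system.file("extdata", "screen_table.tsv",
                                 package = "ldbscreen", mustWork = TRUE))
}

#' Summarise a gene-by-sensitizer interaction table
#'
#' Per sensitizer column: tested (cells other than "n"), interacting
#' (cells "+" or "-"), enhancer and suppressor counts, with percentages to
#' one decimal. For the bristle sensitizer pair (when the table has at
#' least ssdp- and Chip-style columns, i.e. columns 2 and 3 of the code
#' block), also reports: distinct genes interacting with either or both,
#' distinct enhancer-role and suppressor-role gene counts (a gene may hold
#' both roles on different sensitizers), and per-direction overlaps. When
#' a reference count for the both-sensitizer overlap is supplied and
#' disagrees with the table, a discrepancy note is emitted.
#'
#' @param table a \code{ScreenTable}.
#' @param bristle_columns which sensitizer columns form the bristle pair
#'   (default the 2nd and 3rd, if present).
#' @return object of class \code{ScreenSummary}: list with \code{per_column}
#'   (data frame), \code{bristle} (list or NULL) and \code{notes}.
#' @export
summarize_screen <- function(table, bristle_columns = NULL) {
  stopifnot(inherits(table, "ScreenTable"))
  sens <- attr(table, "sensitizers")
  per <- do.call(rbind, lapply(sens, function(s) {
    v <- table[[s]]
    tested <- sum(v != "n")
    inter <- sum(v %in% c("+", "-"))
    enh <- sum(v == "+")
    sup <- sum(v == "-")
    data.frame(sensitizer = s, tested = tested, interacting = inter,
               enhancers = enh, suppressors = sup,
               pct_interacting = round(100 * inter / max(tested, 1), 1),
               pct_enhancers = round(100 * enh / max(inter, 1), 1),
               pct_suppressors = round(100 * sup / max(inter, 1), 1),
               stringsAsFactors = FALSE)
  }))
  notes <- character(0)
  bristle <- NULL
  if (is.null(bristle_columns) && length(sens) >= 3L) {
    bristle_columns <- sens[2:3]
  }
  if (!is.null(bristle_columns) && all(bristle_columns %in% sens)) {
    a <- table[[bristle_columns[1]]]
    b <- table[[bristle_columns[2]]]
    tested <- a != "n" | b != "n"
    inter_a <- a %in% c("+", "-")
    inter_b <- b %in% c("+", "-")
    enh_genes <- a == "+" | b == "+"
    sup_genes <- a == "-" | b == "-"
    bristle <- list(
      columns = bristle_columns,
      tested = sum(tested),
      interacting_either = sum(inter_a | inter_b),
      interacting_both = sum(inter_a & inter_b),
      enhancer_roles = sum(enh_genes),
      suppressor_roles = sum(sup_genes),
      interacting_roles = sum(enh_genes) + sum(sup_genes),
      enhancers_by_column = c(sum(a == "+"), sum(b == "+")),
      suppressors_by_column = c(sum(a == "-"), sum(b == "-")),
      enhancer_overlap = sum(a == "+" & b == "+"),
      suppressor_overlap = sum(a == "-" & b == "-"))
    names(bristle$enhancers_by_column) <- bristle_columns
    names(bristle$suppressors_by_column) <- bristle_columns
    if (bristle$interacting_both != 5L) {
      # the published text reports 5 genes interacting with both bristle
      # sensitizers; the table itself may differ — surface it
      notes <- c(notes, sprintf(
        "table yields %d genes interacting with both %s and %s (published text reports 5)",
        bristle$interacting_both, bristle_columns[1], bristle_columns[2]))
    }
  }
  structure(list(per_column = per, bristle = bristle, notes = notes),
            class = "ScreenSummary")
}

#' @export
print.ScreenSummary <- function(x, ...) {
  cat("Screen summary (per sensitizer):\n")
  print(x$per_column, row.names = FALSE)
  if (!is.null(x$bristle)) {
    b <- x$bristle
    cat(sprintf("\nBristle pair (%s, %s): %d tested, %d interacting with either (%d with both)\n",
                b$columns[1], b$columns[2], b$tested, b$interacting_either,
                b$interacting_both))
    cat(sprintf("  enhancer-role genes: %d (%s); suppressor-role genes: %d (%s)\n",
                b$enhancer_roles,
                paste(sprintf("%s %d", names(b$enhancers_by_column),
                              b$enhancers_by_column), collapse = ", "),
                b$suppressor_roles,
                paste(sprintf("%s %d", names(b$suppressors_by_column),
                              b$suppressors_by_column), collapse = ", ")))
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
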