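#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' mirror the design of the original study: 22 two-channel hybridizations
#' probing ~14,000 transcripts with mutant-vs-heterozygote contrasts, and
#' 500 bp upstream regions scanned for binding sites. Sizes are routinely
#' overridden downward for quick runs; the statistical structure does not
#' change with size.
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param n_genes number of genes (array elements); default 14142, the
#'   number of predicted transcripts probed on the arrays being emulated.
#' @param n_arrays number of two-channel hybridizations (default 22).
#' @param n_printtips number of print-tip groups per array (default 16, a
#'   conventional 4x4 print head).
#' @param de_fraction proportion of genes carrying a true expression effect.
#' @param de_log2_effect magnitude of the true log2 fold change.
#' @param noise_sd SD of the per-channel log2 intensity noise.
#' @param promoter_length upstream region length in bases (default 500).
#' @param background_gc GC content of the background sequence model
#'   (default 0.43, typical of Drosophila non-coding sequence).
#' @param plant_rate_target expected planted binding sites per target
#'   promoter.
#' @param plant_rate_background expected planted sites per background
#'   promoter.
#' @param affinity_jitter mixing weight in [0,1] flattening sampled sites
#'   toward uniform base usage, creating sites of varying affinity.
#' @param n_duplicates number of replicate spots (array elements) per gene
#'   per array (default 2; duplicate elements are a feature of the arrays
#'   being emulated and are kept as replicates, never averaged).
#' @param dye_bias_sd SD of the per-array additive dye bias (log2).
#' @param distortion_sd scale of the per-print-tip intensity-dependent
#'   distortion of the log ratio.
#' @return an object of class \code{SimulationConfig} (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 200, n_arrays = 8)
simulation_config <- function(seed = 1L,
                              n_genes = 14142L,
                              n_arrays = 22L,
                              n_printtips = 16L,
                              de_fraction = 189 / 14142,
                              de_log2_effect = 1,
                              noise_sd = 0.25,
                              promoter_length = 500L,
                              background_gc = 0.43,
                              plant_rate_target = 2,
                              plant_rate_background = 0.2,
                              affinity_jitter = 0,
                              n_duplicates = 2L,
                              dye_bias_sd = 0.3,
                              distortion_sd = 0.3) {
  cfg <- list(
    seed = assert_count(seed, "seed", min = 0L),
    n_genes = assert_count(n_genes, "n_genes"),
    n_arrays = assert_count(n_arrays, "n_arrays"),
    n_printtips = assert_count(n_printtips, "n_printtips"),
    de_fraction = assert_probability(de_fraction, "de_fraction"),
    de_log2_effect = assert_scalar_number(de_log2_effect, "de_log2_effect"),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd", lower = 0),
    promoter_length = assert_count(promoter_length, "promoter_length"),
    background_gc = assert_probability(background_gc, "background_gc"),
    plant_rate_target = assert_scalar_number(plant_rate_target,
                                             "plant_rate_target", lower = 0),
    plant_rate_background = assert_scalar_number(plant_rate_background,
                                                 "plant_rate_background",
                                                 lower = 0),
    affinity_jitter = assert_probability(affinity_jitter, "affinity_jitter"),
    n_duplicates = assert_count(n_duplicates, "n_duplicates"),
    dye_bias_sd = assert_scalar_number(dye_bias_sd, "dye_bias_sd", lower = 0),
    distortion_sd = assert_scalar_number(distortion_sd, "distortion_sd",
                                         lower = 0)
  )
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Generate a set of background promoter sequences
#'
#' Draws \code{n} upstream sequences of fixed length from an order-0
#' background model parameterized only by GC content: each position is
#' independently A/T with probability \code{(1-gc)/2} each and G/C with
#' probability \code{gc/2} each.
#'
#' @param config a \code{\link{simulation_config}} object (uses
#'   \code{promoter_length}, \code{background_gc} and \code{seed}).
#' @param n number of promoters.
#' @param prefix gene-id prefix; ids are \code{<prefix>0001} etc.
#' @return a named \code{Biostrings::DNAStringSet} of length \code{n}.
#' @export
#' @examples
#' proms <- generate_promoter_set(simulation_config(seed = 7), n = 5)
generate_promoter_set <- function(config, n, prefix = "gene") {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- assert_count(n, "n")
  len <- config$promoter_length
  gc <- config$background_gc
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_local_seed(config$seed, {
    bases <- sample(DNA_BASES4, n * len, replace = TRUE, prob = probs)
    vapply(seq_len(n), function(i) {
      paste(bases[((i - 1L) * len + 1L):(i * len)], collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Plant binding sites into promoters
#'
#' Writes a Poisson-distributed number of motif occurrences into each
#' promoter at non-overlapping, uniformly chosen positions on a random
#' strand. Each site string is sampled column-wise from the motif's
#' probability matrix, optionally flattened toward uniform base usage by
#' \code{affinity_jitter} so that planted sites vary in affinity.
#'
#' @param promoters a \code{DNAStringSet} or named character vector.
#' @param motif a \code{\link{motif_matrix}}.
#' @param rate expected number of sites per promoter (Poisson mean).
#' @param affinity_jitter mixing weight in [0,1] toward the uniform base
#'   distribution when sampling site strings.
#' @param seed integer seed.
#' @return a list with elements \code{promoters} (modified
#'   \code{DNAStringSet}) and \code{sites} (data frame with columns
#'   \code{gene_id}, \code{position} (0-based site start on the forward
#'   strand), \code{strand}, \code{site} — the sampled site string as
#'   written, in the orientation of \code{strand}).
#' @export
plant_motif_sites <- function(promoters, motif, rate, affinity_jitter = 0,
                              seed = 1L) {
  stopifnot(inherits(motif, "MotifMatrix"))
  seqs <- as_promoter_chr(promoters)
  assert_scalar_number(rate, "rate", lower = 0)
  assert_probability(affinity_jitter, "affinity_jitter")
  W <- ncol(motif$matrix)
  lens <- nchar(seqs)
  if (any(W > lens)) {
    stop("motif is wider than at least one promoter", call. = FALSE)
  }
  probs <- (1 - affinity_jitter) * motif$matrix + affinity_jitter * 0.25

  recs <- list()
  seqs_out <- seqs
  with_local_seed(seed, {
    counts <- rpois(length(seqs), rate)
    for (i in seq_along(seqs)) {
      k <- counts[i]
      if (k == 0) next
      L <- lens[i]
      used <- integer(0)  # occupied starts (1-based)
      for (s in seq_len(k)) {
        site <- paste(vapply(seq_len(W), function(j) {
          sample(DNA_BASES4, 1L, prob = probs[, j])
        }, character(1)), collapse = "")
        strand <- sample(c("+", "-"), 1L)
        placed <- FALSE
        for (attempt in seq_len(100L)) {
          pos <- sample.int(L - W + 1L, 1L)
          if (!any(abs(used - pos) < W)) {
            written <- if (strand == "+") site else revcomp_chr(site)
            substr(seqs_out[i], pos, pos + W - 1L) <- written
            used <- c(used, pos)
            recs[[length(recs) + 1L]] <- data.frame(
              gene_id = names(seqs)[i], position = pos - 1L,
              strand = strand, site = site, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          warning(sprintf("dropped a site in %s after 100 placement attempts",
                          names(seqs)[i]))
        }
      }
    }
  })
  sites <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene_id = character(0), position = integer(0),
               strand = character(0), site = character(0),
               stringsAsFactors = FALSE)
  list(promoters = Biostrings::DNAStringSet(seqs_out), sites = sites)
}

#' Simulate a two-channel expression experiment with known truth
#'
#' Generates raw two-channel intensities for \code{n_genes} elements on
#' \code{n_arrays} hybridizations. On the log2 scale each channel is
#' base expression + per-array dye bias (channel 1) + a per-print-tip
#' intensity-dependent distortion of the ratio + genotype effect + noise,
#' then exponentiated to the raw scale. Arrays alternate between
#' trans-heteroallelic mutant samples and their corresponding heterozygote
#' controls (channel 2 carries a common reference), split across two
#' contrast pairs as in the emulated design. A random \code{de_fraction}
#' of genes carries \code{±de_log2_effect} in mutant-labelled arrays only.
#'
#' @param config a \code{\link{simulation_config}}; requires
#'   \code{n_arrays >= 4} and \code{de_fraction * n_genes >= 1} unless
#'   \code{de_fraction == 0}.
#' @return an object of class \code{ArrayExperiment}: list with
#'   \code{elements} (element_id, gene_id, array_id, printtip, ch1, ch2),
#'   \code{design} (array_id, genotype_group, contrast_pair) and
#'   \code{truth} (gene_id, is_de, sign).
#' @export
generate_expression_experiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$n_arrays < 4) {
    stop("n_arrays must be >= 4 for a mutant/control contrast design",
         call. = FALSE)
  }
  n_de <- round(config$de_fraction * config$n_genes)
  if (config$de_fraction > 0 && n_de < 1) {
    stop("de_fraction * n_genes must be >= 1 when de_fraction > 0",
         call. = FALSE)
  }

  ng <- config$n_genes
  na <- config$n_arrays
  nt <- config$n_printtips
  nd <- config$n_duplicates
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  array_ids <- sprintf("array%02d", seq_len(na))
  # first half of arrays = contrast pair A, second half = pair B;
  # within a pair, alternate mutant / control
  pair <- ifelse(seq_len(na) <= ceiling(na / 2), "pairA", "pairB")
  group <- ifelse(seq_len(na) %% 2L == 1L, "mutant", "control")
  design <- data.frame(array_id = array_ids, genotype_group = group,
                       contrast_pair = pair, stringsAsFactors = FALSE)

  out <- with_local_seed(config$seed, {
    base_g <- rnorm(ng, mean = 9, sd = 1.5)
    # nd replicate spots per gene, laid out gene-major; print-tip group
    # follows the spot layout
    gene_of_el <- rep(seq_len(ng), each = nd)
    base <- base_g[gene_of_el]
    nel <- ng * nd
    tip <- rep_len(seq_len(nt), nel)
    de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer(0)
    sign_de <- integer(ng)
    if (n_de > 0) sign_de[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    dye <- rnorm(na, 0, config$dye_bias_sd)
    # per (array, tip) quadratic ratio distortion in centred A
    c1 <- matrix(rnorm(na * nt, 0, config$distortion_sd / 2), na, nt)
    c2 <- matrix(rnorm(na * nt, 0, config$distortion_sd / 8), na, nt)

    rows <- vector("list", na)
    for (a in seq_len(na)) {
      eff <- if (group[a] == "mutant") {
        (sign_de * config$de_log2_effect)[gene_of_el]
      } else 0
      acent <- base - 9
      distort <- c1[a, tip] * acent + c2[a, tip] * acent^2
      l2ch1 <- base + eff + dye[a] / 2 + distort / 2 +
        rnorm(nel, 0, config$noise_sd)
      l2ch2 <- base - dye[a] / 2 - distort / 2 +
        rnorm(nel, 0, config$noise_sd)
      rows[[a]] <- data.frame(
        element_id = sprintf("el%05d_%d", gene_of_el,
                             rep(seq_len(nd), times = ng)),
        gene_id = gene_ids[gene_of_el], array_id = array_ids[a],
        printtip = tip,
        ch1 = 2^l2ch1, ch2 = 2^l2ch2, stringsAsFactors = FALSE)
    }
    truth <- data.frame(gene_id = gene_ids, is_de = sign_de != 0L,
                        sign = sign_de, stringsAsFactors = FALSE)
    list(elements = do.call(rbind, rows), truth = truth)
  })

  structure(list(elements = out$elements, design = design,
                 truth = out$truth),
            class = "ArrayExperiment")
}

#' @export
print.ArrayExperiment <- function(x, ...) {
  cat(sprintf("ArrayExperiment: %d elements x %d arrays (%d print-tip groups)\n",
              length(unique(x$elements$element_id)), nrow(x$design),
              length(unique(x$elements$printtip))))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$design$genotype_group)),
                            table(x$design$genotype_group)), collapse = ", ")))
  invisible(x)
}

#' Construct a severity distribution for an ordinal phenotype assay
#'
#' @param counts non-negative integer counts per ordinal severity class
#'   (class 1 = least severe first).
#' @param genotype genotype label.
#' @param sex "female" or "male".
#' @return object of class \code{SeverityDistribution}.
#' @export
severity_distribution <- function(counts, genotype = "", sex = "female") {
  if (!is.numeric(counts) || length(counts) < 2 || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be non-negative integers over >= 2 classes",
         call. = FALSE)
  }
  sex <- match.arg(sex, c("female", "male"))
  structure(list(counts = as.integer(counts), genotype = genotype, sex = sex),
            class = "SeverityDistribution")
}

#' Simulate a wing-notching modifier cross
#'
#' Draws fly counts over ordinal severity classes from a multinomial whose
#' probabilities are the control class probabilities exponentially tilted
#' by class index: \eqn{p_c \propto p^{ctrl}_c \exp(shift \cdot c)}.
#' \code{shift > 0} moves mass toward severe classes (an enhancer),
#' \code{shift < 0} toward mild classes (a suppressor), \code{shift = 0}
#' reproduces the control distribution in expectation.
#'
#' @param control_probs probability vector over classes (sums to 1).
#' @param shift tilt per severity class on the log scale.
#' @param n_flies number of flies scored.
#' @param seed integer seed.
#' @param genotype,sex labels carried to the result.
#' @return a \code{\link{severity_distribution}}.
#' @export
simulate_wing_cross <- function(control_probs, shift, n_flies, seed = 1L,
                                genotype = "test", sex = "female") {
  if (!is.numeric(control_probs) || length(control_probs) < 2 ||
      any(control_probs < 0) || abs(sum(control_probs) - 1) > 1e-9) {
    stop("control_probs must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  assert_scalar_number(shift, "shift", allow_inf = TRUE)
  n_flies <- assert_count(n_flies, "n_flies")
  k <- seq_along(control_probs)
  if (is.infinite(shift)) {
    sup <- which(control_probs > 0)
    probs <- numeric(length(control_probs))
    probs[if (shift > 0) max(sup) else min(sup)] <- 1
  } else {
    w <- control_probs * exp(shift * k)
    probs <- w / sum(w)
  }
  counts <- with_local_seed(seed, as.integer(rmultinom(1, n_flies, probs)))
  severity_distribution(counts, genotype = genotype, sex = sex)
}

#' Construct a bristle-duplication cross record
#'
#' @param n total flies counted.
#' @param d flies displaying the duplicated scutellar bristle phenotype.
#' @param genotype genotype label.
#' @param role "control" or "test".
#' @return object of class \code{BristleCross}.
#' @export
bristle_cross <- function(n, d, genotype = "", role = c("control", "test")) {
  n <- assert_count(n, "n")
  d <- assert_count(d, "d", min = 0L)
  if (d > n) stop("d must not exceed n", call. = FALSE)
  role <- match.arg(role)
  structure(list(genotype = genotype, n = n, d = d, role = role),
            class = "BristleCross")
}

#' Simulate a scutellar-bristle duplication cross
#'
#' @param p_dup per-fly probability of the duplicated-bristle phenotype.
#' @param n_flies total flies.
#' @param seed integer seed.
#' @param genotype,role labels carried to the result.
#' @return a \code{\link{bristle_cross}}.
#' @export
simulate_bristle_cross <- function(p_dup, n_flies, seed = 1L,
                                   genotype = "test", role = "test") {
  assert_probability(p_dup, "p_dup")
  n_flies <- assert_count(n_flies, "n_flies")
  d <- with_local_seed(seed, rbinom(1, n_flies, p_dup))
  bristle_cross(n_flies, d, genotype = genotype, role = role)
}

#' Generate a library of random informative motif matrices
#'
#' Columns are drawn from a symmetric Dirichlet (via gamma variates) with
#' concentration \code{alpha}; small \code{alpha} gives sharp, informative
#' columns resembling curated binding-site matrices. Used as a null motif
#' library in calibration and power studies.
#'
#' @param n_motifs number of matrices.
#' @param width motif width (single value or vector recycled to
#'   \code{n_motifs}).
#' @param seed integer seed.
#' @param alpha Dirichlet concentration (default 0.3).
#' @return list of \code{\link{motif_matrix}} objects.
#' @export
random_motif_library <- function(n_motifs, width = 8L, seed = 1L,
                                 alpha = 0.3) {
  n_motifs <- assert_count(n_motifs, "n_motifs")
  widths <- rep_len(as.integer(width), n_motifs)
  assert_scalar_number(alpha, "alpha", lower = 1e-6)
  with_local_seed(seed, {
    lapply(seq_len(n_motifs), function(i) {
      W <- widths[i]
      g <- matrix(rgamma(4L * W, shape = alpha), nrow = 4L)
      mat <- sweep(g, 2L, colSums(g), "/")
      rownames(mat) <- DNA_BASES4
      motif_matrix(sprintf("rand%03d", i), mat, source = "constructed")
    })
  })
}

# I/O -------------------------------------------------------------------

#' Write promoters as FASTA
#' @param promoters a \code{DNAStringSet} or named character vector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- as_promoter_chr(promoters)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read promoters from FASTA
#' @param path FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
read_promoters_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write / read an ArrayExperiment as tab-delimited tables
#'
#' The element table has columns element_id, gene_id, array_id, printtip,
#' channel1, channel2, genotype_group; the design (and truth, if present)
#' are written alongside.
#'
#' @param exp an \code{ArrayExperiment}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_array_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "ArrayExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- exp$elements
  el$genotype_group <-
    exp$design$genotype_group[match(el$array_id, exp$design$array_id)]
  names(el)[names(el) == "ch1"] <- "channel1"
  names(el)[names(el) == "ch2"] <- "channel2"
  write_tsv(el, file.path(dir, "elements.tsv"))
  write_tsv(exp$design, file.path(dir, "design.tsv"))
  if (!is.null(exp$truth)) write_tsv(exp$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_array_experiment
#' @param elements_path,design_path paths to the element and design tables.
#' @export
read_array_experiment <- function(elements_path, design_path) {
  el <- read_tsv(elements_path)
  names(el)[names(el) == "channel1"] <- "ch1"
  names(el)[names(el) == "channel2"] <- "ch2"
  el$genotype_group <- NULL
  design <- read_tsv(design_path)
  array_experiment(el, design)
}
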