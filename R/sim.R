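#' Simulation configuration
#'
#' Parameters of the fragment simulator.  A pair of everywhere-heterozygous
#' haplotypes of length `n` is drawn; a genotype-calling step miscalls each
#' base independently with probability `g_e`; sequence copies at total
#' per-site coverage `c` are sourced half from the true pair and half from
#' the erroneous pair; copies are cut into non-overlapping fragments of
#' length 3-7; half of the reads are made paired-end by merging a
#' first-half fragment with a same-copy second-half fragment; finally every
#' observed base is flipped with probability `seq_flip`.
#'
#' The default `seq_flip = 0.05 - g_e/2` calibrates the presets so that the
#' total error rate of matrix entries (genotype-sourced plus sequencing) is
#' about 0.05 regardless of `g_e`: 0.03 for `g_e = 0.04` and 0.01 for
#' `g_e = 0.08`.  (The exact expectation is
#' `seq_flip + (g_e/2) * (1 - 4*seq_flip/3)`, marginally below 0.05 because
#' a sequencing flip can strike an already-miscalled base.)
#'
#' @param n Number of heterozygous SNP sites (>= 2).
#' @param c Total per-site coverage; must be even (half true-sourced, half
#'   error-sourced copies).
#' @param g_e Genotype-calling error probability per base.
#' @param seq_flip Per-base sequencing flip probability; default calibrated
#'   as above.
#' @param frag_len_range Inclusive fragment-length range, default `c(3, 7)`.
#' @param paired_fraction Target fraction of reads that are paired-end,
#'   default 1/2.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n, c, g_e, seq_flip = NULL,
                       frag_len_range = c(3L, 7L),
                       paired_fraction = 0.5, seed = NULL) {
  if (is.null(seq_flip)) seq_flip <- max(0, 0.05 - g_e / 2)
  stopifnot(n >= 2L, c >= 0L, c %% 2 == 0,
            g_e >= 0, g_e < 1, seq_flip >= 0, seq_flip < 1,
            length(frag_len_range) == 2L,
            frag_len_range[1] >= 1L, frag_len_range[2] >= frag_len_range[1],
            paired_fraction >= 0, paired_fraction <= 0.5)
  structure(list(n = as.integer(n), c = as.integer(c), g_e = g_e,
                 seq_flip = seq_flip,
                 frag_len_range = as.integer(frag_len_range),
                 paired_fraction = paired_fraction, seed = seed),
            class = "SimConfig")
}

#' Draw true and miscalled haplotype pairs
#'
#' Each site's true genotype is an unordered pair of distinct bases, uniform
#' over the 6 such pairs, in random phase.  The erroneous pair copies the
#' true pair and flips every base independently with probability `g_e`,
#' uniformly to one of the other three nucleotides; a flip may make the
#' miscalled genotype homozygous, which is exactly the kind of
#' genotype-calling error the assembler is meant to repair.  `error_sites`
#' are the sites whose miscalled unordered genotype differs from the true
#' one (two complementary flips can cancel).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `SimTruth`: list with `h1`, `h2`, `err_h1`,
#'   `err_h2`, `error_sites`, `config`.
#' @export
simulate_truth <- function(config) {
  n <- config$n
  h1 <- sample(BASES, n, replace = TRUE)
  h2 <- vapply(h1, function(a) sample(setdiff(BASES, a), 1L), "")
  names(h2) <- NULL
  err_h1 <- flip_bases(h1, config$g_e)
  err_h2 <- flip_bases(h2, config$g_e)
  gt <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  error_sites <- which(gt(h1, h2) != gt(err_h1, err_h2))
  structure(list(h1 = h1, h2 = h2, err_h1 = err_h1, err_h2 = err_h2,
                 error_sites = error_sites, config = config),
            class = "SimTruth")
}

# flip each base with probability p, uniformly to one of the other three
flip_bases <- function(seq, p) {
  if (p <= 0) return(seq)
  hit <- which(stats::runif(length(seq)) < p)
  if (length(hit)) {
    seq[hit] <- vapply(seq[hit], function(a) sample(setdiff(BASES, a), 1L), "")
  }
  seq
}

#' Full-length sequence copies at target coverage
#'
#' Emits `c` full-length single-haplotype copies so that every site has
#' total coverage `c`: the first `c/2` copies are sourced from the true
#' pair and the rest from the erroneous pair, alternating between
#' haplotype 1 and 2 so both are covered equally.
#'
#' @param truth A [simulate_truth()] result.
#' @param config A [sim_config()] object.
#' @return A list of copies, each `list(seq, lane, source)` with `lane` in
#'   `1:2` and `source` in `c("true", "err")`.
#' @export
make_copies <- function(truth, config) {
  cc <- config$c
  if (cc == 0L) return(list())
  lapply(seq_len(cc), function(k) {
    lane <- ((k - 1L) %% 2L) + 1L
    source <- if (k <= cc %/% 2L) "true" else "err"
    seq <- if (source == "true") {
      if (lane == 1L) truth$h1 else truth$h2
    } else {
      if (lane == 1L) truth$err_h1 else truth$err_h2
    }
    list(seq = seq, lane = lane, source = source)
  })
}

#' Cut copies into non-overlapping fragments
#'
#' Each copy is partitioned left to right into fragments whose lengths are
#' drawn uniformly from `frag_len_range`; the final remainder fragment may
#' be shorter (minimum 1 site) and is kept so tail coverage is unbiased.
#'
#' @param copies Output of [make_copies()].
#' @param config A [sim_config()] object.
#' @return A list of fragments `list(copy, lane, source, start, alleles)`.
#' @export
fragmentize <- function(copies, config) {
  lo <- config$frag_len_range[1]; hi <- config$frag_len_range[2]
  frags <- list()
  for (ci in seq_along(copies)) {
    cp <- copies[[ci]]
    n <- length(cp$seq)
    start <- 1L
    while (start <= n) {
      len <- min(sample(seq.int(lo, hi), 1L), n - start + 1L)
      frags[[length(frags) + 1L]] <- list(
        copy = ci, lane = cp$lane, source = cp$source,
        start = start, alleles = cp$seq[start:(start + len - 1L)])
      start <- start + len
    }
  }
  frags
}

#' Merge fragments into paired-end reads
#'
#' Fragments lying entirely in the first half of the sites are randomly
#' matched with same-copy fragments lying entirely in the second half and
#' merged into single read records (with the insert gap between the mates),
#' until the paired fraction of reads reaches `paired_fraction` or no
#' candidates remain.
#'
#' @param frags Output of [fragmentize()].
#' @param config A [sim_config()] object.
#' @return A list of reads, each `list(copy, lane, source, segs)` where
#'   `segs` is a list of `(start, alleles)` segments.
#' @export
pair_fragments <- function(frags, config) {
  n <- config$n
  half <- n %/% 2L
  ends <- vapply(frags, function(f) f$start + length(f$alleles) - 1L, 1L)
  starts <- vapply(frags, `[[`, 1L, "start")
  copies <- vapply(frags, `[[`, 1L, "copy")
  first_half <- which(ends <= half)
  second_half <- which(starts > half)
  # same-copy random matching: shuffle within copy, zip
  cand <- list()
  for (cp in unique(copies)) {
    a <- first_half[copies[first_half] == cp]
    b <- second_half[copies[second_half] == cp]
    if (!length(a) || !length(b)) next
    a <- a[sample.int(length(a))]
    b <- b[sample.int(length(b))]
    k <- min(length(a), length(b))
    for (i in seq_len(k)) cand[[length(cand) + 1L]] <- c(a[i], b[i])
  }
  if (length(cand) > 1L) cand <- cand[sample.int(length(cand))]
  F <- length(frags)
  target <- config$paired_fraction
  merged <- list()
  used <- logical(F)
  p <- 0L
  for (pr in cand) {
    # after p merges there are F - p reads, p of them paired
    if (p >= target * (F - p)) break
    merged[[length(merged) + 1L]] <- pr
    used[pr] <- TRUE
    p <- p + 1L
  }
  reads <- list()
  for (pr in merged) {
    f1 <- frags[[pr[1]]]; f2 <- frags[[pr[2]]]
    reads[[length(reads) + 1L]] <- list(
      copy = f1$copy, lane = f1$lane, source = f1$source,
      segs = list(list(start = f1$start, alleles = f1$alleles),
                  list(start = f2$start, alleles = f2$alleles)))
  }
  for (i in which(!used)) {
    f <- frags[[i]]
    reads[[length(reads) + 1L]] <- list(
      copy = f$copy, lane = f$lane, source = f$source,
      segs = list(list(start = f$start, alleles = f$alleles)))
  }
  reads
}

#' Apply per-base sequencing errors
#'
#' Every non-gap matrix entry is independently flipped with probability
#' `seq_flip`, uniformly to one of the other three nucleotides.
#'
#' @param x A `ReadMatrix`.
#' @param config A [sim_config()] object.
#' @return The perturbed `ReadMatrix`.
#' @export
add_sequencing_errors <- function(x, config) {
  p <- config$seq_flip
  if (p <= 0) return(x)
  m <- unclass(x)
  idx <- which(m != GAP & stats::runif(length(m)) < p)
  if (length(idx)) {
    m[idx] <- vapply(m[idx], function(a) sample(setdiff(BASES, a), 1L), "")
  }
  read_matrix(m, sites = site_index(x))
}

#' Generate a complete simulated dataset
#'
#' Orchestrates [simulate_truth()], [make_copies()], [fragmentize()],
#' [pair_fragments()] and [add_sequencing_errors()].  Fully reproducible
#' when `config$seed` is set.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `hap_sim`: list with `matrix` (the
#'   `ReadMatrix`), `truth` (`SimTruth`), and per-read `lane` and `source`
#'   vectors (used for error-rate calibration).
#' @examples
#' sim <- generate_dataset(sim_config(n = 30, c = 4, g_e = 0.04, seed = 1))
#' sim$matrix
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- simulate_truth(config)
  copies <- make_copies(truth, config)
  frags <- fragmentize(copies, config)
  reads <- pair_fragments(frags, config)
  mat <- matrix(GAP, nrow = length(reads), ncol = config$n)
  for (i in seq_along(reads)) {
    for (seg in reads[[i]]$segs) {
      mat[i, seg$start:(seg$start + length(seg$alleles) - 1L)] <- seg$alleles
    }
  }
  rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  x <- add_sequencing_errors(read_matrix(mat), config)
  structure(list(matrix = x, truth = truth,
                 lane = vapply(reads, `[[`, 1L, "lane"),
                 source = vapply(reads, `[[`, "", "source")),
            class = "hap_sim")
}

#' Empirical matrix error rate of a simulated dataset
#'
#' Fraction of non-gap matrix entries that differ from the true haplotype
#' allele of the read's source haplotype; combines genotype-sourced and
#' sequencing errors, and should be near 0.05 under the calibrated presets.
#'
#' @param sim A [generate_dataset()] result.
#' @return Proportion of erroneous entries.
#' @export
matrix_error_rate <- function(sim) {
  stopifnot(inherits(sim, "hap_sim"))
  m <- unclass(sim$matrix)
  truth_mat <- rbind(sim$truth$h1, sim$truth$h2)[sim$lane, , drop = FALSE]
  covered <- m != GAP
  sum(m[covered] != truth_mat[covered]) / sum(covered)
}

#' Write/read a simulation truth sidecar
#'
#' Plain TSV with one row per site: `site`, true `h1`/`h2`, miscalled
#' `err_h1`/`err_h2` and an `is_error` flag.
#'
#' @param truth A `SimTruth`.
#' @param path File path.
#' @return `path` invisibly, or the reconstructed `SimTruth`.
#' @export
write_sim_truth <- function(truth, path) {
  df <- data.frame(site = seq_along(truth$h1), h1 = truth$h1, h2 = truth$h2,
                   err_h1 = truth$err_h1, err_h2 = truth$err_h2,
                   is_error = as.integer(seq_along(truth$h1) %in% truth$error_sites))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "character",
                                         "character", "character", "integer"))
  if (!nrow(df)) stop("empty truth file: ", path)
  structure(list(h1 = df$h1, h2 = df$h2, err_h1 = df$err_h1,
                 err_h2 = df$err_h2, error_sites = which(df$is_error == 1L),
                 config = NULL),
            class = "SimTruth")
}
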