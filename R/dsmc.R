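#' Model parameters for the assembler
#'
#' The measurement model is a single global per-base sequencing error rate
#' `e`: an observed base equals the underlying haplotype allele with
#' probability `1 - e` and each of the other three nucleotides with
#' probability `e/3`.  The state-transition prior over the next allele pair
#' is the product of per-base composition probabilities (no linkage
#' information is used).  `K` is the particle budget; when `NULL` it is set
#' per block from the block length via [choose_K()].
#'
#' @param e Per-base sequencing error probability, `0 < e < 1`.  The default
#'   0.01 matches typical base-space platform accuracy.
#' @param composition Named numeric vector of nucleotide composition
#'   probabilities for `A`, `C`, `G`, `T`; must sum to 1.  Uniform by
#'   default.
#' @param K Fixed particle count, or `NULL` for the length-adaptive
#'   schedule.
#' @return An object of class `ModelParams`.
#' @export
model_params <- function(e = 0.01,
                         composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         K = NULL) {
  stopifnot(is.numeric(e), length(e) == 1L, e > 0, e < 1)
  composition <- composition[BASES]
  stopifnot(!anyNA(composition), all(composition >= 0),
            abs(sum(composition) - 1) < 1e-8)
  if (!is.null(K)) stopifnot(K >= 1L)
  structure(list(e = e, composition = composition, K = K),
            class = "ModelParams")
}

#' Particle budget schedule
#'
#' Longer blocks need more particles to protect the maximum-weight path from
#' being pruned.  The default schedule is 12 particles for blocks of up to
#' 12 sites, `floor(n/2)` for 12 < n < 100, and 50 for n >= 100.
#'
#' @param n Block length (number of heterozygous sites).
#' @return Integer particle count.
#' @examples
#' choose_K(12); choose_K(50); choose_K(100)
#' @export
choose_K <- function(n) {
  stopifnot(n >= 1L)
  if (n <= 12L) 12L else if (n < 100L) as.integer(n %/% 2L) else 50L
}

#' Per-base emission probability
#'
#' `Pr(observed = x | allele = s)`: `1 - e` on a match, `e/3` on each
#' mismatch.  Vectorized over `x` and `s`.
#'
#' @param x,s Observed base and underlying allele (characters in
#'   `A`,`C`,`G`,`T`).
#' @param e Sequencing error rate.
#' @return Numeric probability.
#' @export
emission_prob <- function(x, s, e) {
  stopifnot(all(x %in% BASES), all(s %in% BASES))
  ifelse(x == s, 1 - e, e / 3)
}

#' Candidate heterozygous extensions of a column
#'
#' All ordered pairs of distinct alleles drawn from the bases observed in
#' the column (after masking), in lexicographic order for reproducibility.
#' With `a` distinct alleles there are `a * (a - 1)` candidates (at most 12).
#' Only heterozygous pairs are enumerated: a site whose maximum-likelihood
#' heterozygous genotype disagrees with an upstream genotype call is thereby
#' re-called.
#'
#' @param column Character vector: one matrix column (may contain `-`).
#' @param first_site If `TRUE`, mirror pairs are collapsed by keeping only
#'   pairs with `s1 < s2`: the global haplotype labeling is arbitrary, so
#'   the two mirror paths always carry identical weights and doubling the
#'   bookkeeping at initialization is wasted budget.
#' @return Two-column character matrix of `(s1, s2)` pairs.
#' @export
enumerate_candidates <- function(column, first_site = FALSE) {
  alleles <- sort(intersect(BASES, column))
  if (length(alleles) < 2L) {
    stop("column has fewer than two observed alleles; ",
         "should have been filtered as homozygous")
  }
  grid <- expand.grid(s2 = alleles, s1 = alleles,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$s1 != grid$s2, c("s1", "s2")]
  if (first_site) grid <- grid[grid$s1 < grid$s2, , drop = FALSE]
  as.matrix(grid[order(grid$s1, grid$s2), , drop = FALSE])
}

#' Nearest-informative-position bookkeeping
#'
#' For each read, `pos[i]` is the nearest non-gap column at or left of the
#' current column; 0 means the read has no informative entry yet.  This is
#' what lets phase information flow across the insert gap of a paired-end
#' read: the measurement branch for a read at column `t` conditions on the
#' read's base at `pos[i]`, not at `t - 1`.
#'
#' @param pos_prev Integer vector (per read) after column `t - 1`; use
#'   `rep(0L, m)` before the first column.
#' @param column Character vector: column `t` of the matrix.
#' @param t Column index.
#' @return Updated integer vector.
#' @export
update_pos <- function(pos_prev, column, t) {
  stopifnot(length(pos_prev) == length(column))
  ifelse(column != GAP, as.integer(t), as.integer(pos_prev))
}

#' Gap-aware per-read measurement branch
#'
#' The likelihood of observing `x_it` under a candidate allele pair
#' `(s1, s2)`, given the read's base at its nearest informative position and
#' the particle's phased alleles there.  If that base matches the particle's
#' hap-1 allele the read is chained to haplotype 1 (emission against `s1`);
#' if it matches hap-2, against `s2`; otherwise (no informative position
#' yet, or the anchoring base matches neither allele, e.g. it was an
#' erroneous or masked call) the read's origin is unresolved and the two
#' emissions are averaged with the uniform 1/2 origin prior.
#'
#' @param x_it Observed base at the current column (non-gap).
#' @param s_pair Candidate allele pair, length-2 character `(s1, s2)`.
#' @param x_prev Read's base at its nearest informative position, or `NA`
#'   if there is none (`pos = 0`).
#' @param s_prev_pair Particle's phased alleles at that position, or `NA`.
#' @param e Sequencing error rate.
#' @return Numeric probability.
#' @export
read_branch_likelihood <- function(x_it, s_pair, x_prev, s_prev_pair, e) {
  stopifnot(x_it %in% BASES, length(s_pair) == 2L, s_pair[1] != s_pair[2])
  if (!is.na(x_prev) && !anyNA(s_prev_pair) && x_prev == s_prev_pair[1]) {
    emission_prob(x_it, s_pair[1], e)
  } else if (!is.na(x_prev) && !anyNA(s_prev_pair) && x_prev == s_prev_pair[2]) {
    emission_prob(x_it, s_pair[2], e)
  } else {
    (emission_prob(x_it, s_pair[1], e) + emission_prob(x_it, s_pair[2], e)) / 2
  }
}

#' Column likelihood of a candidate extension
#'
#' Product over all reads with a non-gap entry at column `t` of the per-read
#' measurement branch ([read_branch_likelihood()]); the empty product is 1.
#'
#' @param t Column index.
#' @param s_pair Candidate allele pair.
#' @param path Particle path so far: 2 x (t-1) character matrix of phased
#'   alleles (may have 0 columns at `t = 1`).
#' @param mat `ReadMatrix` block.
#' @param pos_prev Per-read nearest-informative-position vector after column
#'   `t - 1`.
#' @param e Sequencing error rate.
#' @return Numeric probability.
#' @export
column_likelihood <- function(t, s_pair, path, mat, pos_prev, e) {
  lik <- 1
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, t]
    if (x == GAP) next
    p <- pos_prev[i]
    if (p > 0L) {
      lik <- lik * read_branch_likelihood(x, s_pair, mat[i, p], path[, p], e)
    } else {
      lik <- lik * read_branch_likelihood(x, s_pair, NA_character_, NA, e)
    }
  }
  lik
}

#' State-transition prior of an allele pair
#'
#' Product of the composition probabilities of the two alleles; with uniform
#' composition this is 1/16 for every pair and cancels under weight
#' normalization.
#'
#' @param s_pair Candidate allele pair.
#' @param params A [model_params()] object.
#' @return Numeric probability.
#' @export
transition_prob <- function(s_pair, params) {
  unname(params$composition[s_pair[1]] * params$composition[s_pair[2]])
}

#' Log-weight of one particle extension
#'
#' The weight recursion: the extension's log-weight is the parent's
#' log-weight plus the log column likelihood plus the log transition prior.
#' Computed in log space to avoid underflow on long blocks.
#'
#' @inheritParams column_likelihood
#' @param log_w_prev Parent particle's log-weight.
#' @param params A [model_params()] object.
#' @return Log-weight of the extended particle.
#' @export
extension_weight <- function(log_w_prev, t, s_pair, path, mat, pos_prev, params) {
  log_w_prev + log(column_likelihood(t, s_pair, path, mat, pos_prev, params$e)) +
    log(transition_prob(s_pair, params))
}

#' Top-K particle selection
#'
#' Keeps the `K` highest-weight extensions; ties are broken by extension
#' index (parent-major, candidate-minor order) so the sweep is fully
#' deterministic.  Zero-weight (`-Inf`) extensions are dropped first, and
#' the surviving log-weights are normalized to sum to one.
#'
#' @param log_w Numeric vector of extension log-weights, in parent-major /
#'   candidate-minor order.
#' @param K Particle budget.
#' @return List with `keep` (indices into `log_w`, best first) and `log_w`
#'   (their normalized log-weights).
#' @export
select_top_K <- function(log_w, K) {
  alive <- which(is.finite(log_w))
  if (!length(alive)) stop("all candidate extensions have zero weight")
  o <- alive[order(-log_w[alive], alive)]
  keep <- o[seq_len(min(K, length(o)))]
  w <- log_w[keep]
  list(keep = keep, log_w = w - logsumexp(w))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Assemble one block by deterministic sequential Monte Carlo
#'
#' Sweeps the block left to right (or right to left), maintaining at most
#' `K` weighted partial haplotype-pair particles.  At each column every
#' particle is extended by every candidate heterozygous allele pair
#' ([enumerate_candidates()]); extension weights follow
#' [extension_weight()]; the top `K` survive ([select_top_K()]).  At the
#' last column the maximum-weight particle's path is returned.
#'
#' @param block A `ReadMatrix` with >= 2 heterozygous, connected sites.
#' @param params A [model_params()] object.
#' @param direction `"forward"` or `"backward"`.  The backward sweep runs on
#'   the column-reversed matrix and un-reverses its result; reconciling the
#'   two directions removes start-position artifacts (see [reconcile()]).
#' @return A `HaplotypePair`: list with `h1`, `h2` (character allele
#'   vectors), `sites` (original site indices), `log_likelihood` (the
#'   winning particle's final normalized log-weight) and `direction`.
#' @export
run_block <- function(block, params = model_params(),
                      direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(block, "ReadMatrix"), ncol(block) >= 2L)
  codes <- encode_matrix(block)
  if (direction == "backward") codes <- codes[, rev(seq_len(ncol(codes))), drop = FALSE]
  K <- if (is.null(params$K)) choose_K(ncol(block)) else as.integer(params$K)
  res <- dsmc_sweep_cpp(codes, K, params$e, log(unname(params$composition)))
  h1 <- decode_bases(res$h1)
  h2 <- decode_bases(res$h2)
  if (direction == "backward") { h1 <- rev(h1); h2 <- rev(h2) }
  structure(list(h1 = h1, h2 = h2, sites = site_index(block),
                 log_likelihood = res$log_weight, direction = direction),
            class = "HaplotypePair")
}

#' @export
print.HaplotypePair <- function(x, ...) {
  cat(sprintf("HaplotypePair: %d sites, log-likelihood %.4f (%s)\n",
              length(x$h1), x$log_likelihood, x$direction))
  if (length(x$h1) <= 60L) {
    cat(" h1:", paste(x$h1, collapse = ""), "\n")
    cat(" h2:", paste(x$h2, collapse = ""), "\n")
  }
  invisible(x)
}

#' Per-site genotype calls of an assembled pair
#'
#' @param pair A `HaplotypePair`.
#' @return Character vector of unordered genotypes, e.g. `"A/C"`, one per
#'   assembled site.
#' @export
genotype_calls <- function(pair) {
  paste(pmin(pair$h1, pair$h2), pmax(pair$h1, pair$h2), sep = "/")
}

# Pure-R reference sweep mirroring the C++ core step by step; used to
# cross-validate the compiled path on small instances.  With trace = TRUE
# the per-generation sums of normalized particle weights are attached as
# attribute "weight_sums".
dsmc_sweep_r <- function(block, params, trace = FALSE) {
  mat <- unclass(block)
  m <- nrow(mat); n <- ncol(mat)
  cand1 <- enumerate_candidates(mat[, 1L], first_site = TRUE)
  paths <- lapply(seq_len(nrow(cand1)), function(l) {
    matrix(cand1[l, ], nrow = 2L, ncol = 1L)
  })
  log_w <- vapply(seq_len(nrow(cand1)), function(l) {
    log(column_likelihood(1L, cand1[l, ], matrix(character(), 2, 0),
                          mat, rep(0L, m), params$e))
  }, 0)
  sel <- select_top_K(log_w, if (is.null(params$K)) choose_K(n) else params$K)
  paths <- paths[sel$keep]; log_w <- sel$log_w
  sums <- sum(exp(log_w))
  pos <- update_pos(rep(0L, m), mat[, 1L], 1L)
  for (t in seq_len(n)[-1L]) {
    cand <- enumerate_candidates(mat[, t])
    ext_w <- numeric(0); ext_paths <- list()
    for (k in seq_along(paths)) {
      for (l in seq_len(nrow(cand))) {
        ext_w <- c(ext_w, extension_weight(log_w[k], t, cand[l, ],
                                           paths[[k]], mat, pos, params))
        ext_paths[[length(ext_paths) + 1L]] <- cbind(paths[[k]], cand[l, ])
      }
    }
    sel <- select_top_K(ext_w, if (is.null(params$K)) choose_K(n) else params$K)
    paths <- ext_paths[sel$keep]; log_w <- sel$log_w
    sums <- c(sums, sum(exp(log_w)))
    pos <- update_pos(pos, mat[, t], t)
  }
  best <- paths[[1L]]
  out <- structure(list(h1 = best[1L, ], h2 = best[2L, ],
                        sites = site_index(block),
                        log_likelihood = log_w[[1L]], direction = "forward"),
                   class = "HaplotypePair")
  if (trace) attr(out, "weight_sums") <- sums
  out
}
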