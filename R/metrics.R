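#' Minimum error correction (MEC) score
#'
#' The smallest number of matrix entries that must be changed for every
#' read to be consistent with the given haplotype pair: each read is
#' assigned to whichever haplotype it mismatches least (gaps excluded) and
#' the per-read minima are summed.
#'
#' @param x A `ReadMatrix` whose columns align with the pair's sites.
#' @param pair A `HaplotypePair` or any list with character vectors `h1`,
#'   `h2` of length `ncol(x)`.
#' @return Integer MEC score.
#' @export
mec_score <- function(x, pair) {
  stopifnot(inherits(x, "ReadMatrix"), length(pair$h1) == ncol(x),
            length(pair$h2) == ncol(x))
  m <- unclass(x)
  covered <- m != GAP
  mis1 <- rowSums(covered & m != matrix(pair$h1, nrow(m), ncol(m), byrow = TRUE))
  mis2 <- rowSums(covered & m != matrix(pair$h2, nrow(m), ncol(m), byrow = TRUE))
  as.integer(sum(pmin(mis1, mis2)))
}

#' Haplotype reconstruction rate
#'
#' `R = 1 - min(D(h1,e1) + D(h2,e2), D(h1,e2) + D(h2,e1)) / (2l)`, where
#' `D` is the generalized Hamming distance (per-site symbol mismatch count)
#' and `l` the number of sites scored.  The minimum over the two label
#' pairings makes `R` invariant to the arbitrary global haplotype labeling.
#'
#' @param true_pair,est_pair Lists with character vectors `h1`, `h2`,
#'   site-aligned and of equal length.
#' @return Proportion in `[0, 1]`.
#' @export
reconstruction_rate <- function(true_pair, est_pair) {
  l <- length(true_pair$h1)
  stopifnot(l == length(true_pair$h2), l == length(est_pair$h1),
            l == length(est_pair$h2))
  if (l == 0L) return(NA_real_)
  1 - pair_distance(true_pair, est_pair) / (2 * l)
}

# min over label pairings of summed Hamming distances
pair_distance <- function(true_pair, est_pair) {
  d_keep <- sum(true_pair$h1 != est_pair$h1) + sum(true_pair$h2 != est_pair$h2)
  d_swap <- sum(true_pair$h1 != est_pair$h2) + sum(true_pair$h2 != est_pair$h1)
  min(d_keep, d_swap)
}

#' Switch error rate
#'
#' A switch error is an adjacent pair of phased sites whose relative phase
#' is inverted between truth and estimate.  Only sites where the estimated
#' genotype equals the true (heterozygous) genotype are comparable: at each
#' such site the estimate's hap-1 allele identifies which true haplotype it
#' tracks, and a switch is counted whenever that orientation flips between
#' consecutive comparable sites.  Invariant under global relabeling of
#' either pair.
#'
#' @inheritParams reconstruction_rate
#' @return Proportion of comparable adjacent pairs that switch, or `NA` if
#'   fewer than two sites are comparable.
#' @export
switch_error_rate <- function(true_pair, est_pair) {
  counts <- switch_error_counts(true_pair, est_pair)
  if (counts[["pairs"]] == 0L) return(NA_real_)
  counts[["switches"]] / counts[["pairs"]]
}

switch_error_counts <- function(true_pair, est_pair) {
  l <- length(true_pair$h1)
  stopifnot(l == length(est_pair$h1))
  het <- true_pair$h1 != true_pair$h2
  conc <- het &
    pmin(true_pair$h1, true_pair$h2) == pmin(est_pair$h1, est_pair$h2) &
    pmax(true_pair$h1, true_pair$h2) == pmax(est_pair$h1, est_pair$h2)
  ori <- ifelse(est_pair$h1[conc] == true_pair$h1[conc], 1L, 2L)
  if (length(ori) < 2L) return(c(switches = 0L, pairs = 0L))
  c(switches = sum(diff(ori) != 0L), pairs = length(ori) - 1L)
}

#' Genotype-repair rate at induced-error sites
#'
#' Among the sites where the simulator injected a genotype-calling error
#' (and which fall inside phased blocks), the fraction whose estimated
#' unordered genotype equals the true genotype, i.e. the rate at which
#' joint assembly repairs miscalled genotypes.
#'
#' @param truth A `SimTruth` from [simulate_truth()] /
#'   [generate_dataset()].
#' @param asm A `hap_assembly` over the same sites.
#' @return Proportion, or `NA` if no induced-error site was phased.
#' @export
genotype_improvement_rate <- function(truth, asm) {
  stopifnot(inherits(asm, "hap_assembly"))
  err <- truth$error_sites
  if (!length(err)) return(NA_real_)
  hits <- 0L; total <- 0L
  true_gt <- paste(pmin(truth$h1, truth$h2), pmax(truth$h1, truth$h2), sep = "/")
  for (b in asm$blocks) {
    at <- which(b$sites %in% err)
    if (!length(at)) next
    total <- total + length(at)
    hits <- hits + sum(b$genotypes[at] == true_gt[b$sites[at]])
  }
  if (total == 0L) return(NA_real_)
  hits / total
}

#' Evaluate an assembly against simulated truth
#'
#' Per-block and aggregate evaluation: number of phased sites, total MEC,
#' reconstruction rate (distances summed over blocks, each block scored
#' under its own best label pairing, normalized by 2 x sites scored),
#' switch error rate (adjacent comparable pairs pooled over blocks) and the
#' genotype-repair rate.
#'
#' @param asm A `hap_assembly`.
#' @param truth A `SimTruth` with `h1`, `h2` over the original sites.
#' @return A one-row `data.frame` with columns `n_phased`, `n_blocks`,
#'   `mec`, `recon_rate`, `switch_error`, `imp_ge_ac`.
#' @export
evaluate_assembly <- function(asm, truth) {
  stopifnot(inherits(asm, "hap_assembly"))
  dist <- 0; scored <- 0L; sw <- 0L; swp <- 0L
  for (b in asm$blocks) {
    tp <- list(h1 = truth$h1[b$sites], h2 = truth$h2[b$sites])
    dist <- dist + pair_distance(tp, b)
    scored <- scored + length(b$sites)
    counts <- switch_error_counts(tp, b)
    sw <- sw + counts[["switches"]]
    swp <- swp + counts[["pairs"]]
  }
  data.frame(
    n_phased = scored,
    n_blocks = length(asm$blocks),
    mec = sum(vapply(asm$blocks, function(b) b$mec, 1L)),
    recon_rate = if (scored) 1 - dist / (2 * scored) else NA_real_,
    switch_error = if (swp) sw / swp else NA_real_,
    imp_ge_ac = genotype_improvement_rate(truth, asm)
  )
}
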