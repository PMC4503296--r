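#' Bidirectional assembly of a block
#'
#' The sweep's greedy pruning makes its output sensitive to the starting
#' position: information right of an ambiguous site cannot rescue a path
#' pruned before that information is reached.  Running the recursion in both
#' directions and reconciling disagreements recovers most such losses.  The
#' backward result is relabeled (haplotypes swapped or not) to minimize
#' disagreement with the forward result, so site-wise comparison is
#' meaningful despite the arbitrary global labeling.
#'
#' @param block A `ReadMatrix` block with >= 2 sites.
#' @param params A [model_params()] object.
#' @return List with elements `forward` and `backward` (both
#'   `HaplotypePair`, aligned to a common labeling).
#' @export
run_bidirectional <- function(block, params = model_params()) {
  fwd <- run_block(block, params, "forward")
  bwd <- run_block(block, params, "backward")
  d_keep <- sum(bwd$h1 != fwd$h1) + sum(bwd$h2 != fwd$h2)
  d_swap <- sum(bwd$h2 != fwd$h1) + sum(bwd$h1 != fwd$h2)
  if (d_swap < d_keep) {
    tmp <- bwd$h1; bwd$h1 <- bwd$h2; bwd$h2 <- tmp
  }
  list(forward = fwd, backward = bwd)
}

#' Reconcile forward and backward assemblies
#'
#' Sites where the two directions disagree are grouped into maximal runs of
#' consecutive disagreeing sites.  An isolated disagreeing site adopts the
#' allele pair of the direction with the larger final log-likelihood.  For a
#' run of two or more consecutive sites, the two spliced candidates (the
#' forward segment vs. the backward segment, embedded in the consensus that
#' the directions agree on elsewhere) are compared by their MEC score on the
#' reads covering the run, and the smaller-MEC splice is kept; ties go to
#' the forward segment.
#'
#' @param forward,backward Label-aligned `HaplotypePair`s from
#'   [run_bidirectional()].
#' @param block The `ReadMatrix` block they were assembled from.
#' @param params A [model_params()] object (unused by the MEC rule but kept
#'   for interface stability).
#' @return The reconciled `HaplotypePair`; its `log_likelihood` is the
#'   larger of the two directions'.
#' @export
reconcile <- function(forward, backward, block, params = model_params()) {
  stopifnot(length(forward$h1) == length(backward$h1))
  h1 <- forward$h1
  h2 <- forward$h2
  disc <- which(forward$h1 != backward$h1 | forward$h2 != backward$h2)
  if (length(disc)) {
    runs <- split(disc, cumsum(c(1L, diff(disc) != 1L)))
    codes <- encode_matrix(block)
    for (run in runs) {
      if (length(run) == 1L) {
        if (backward$log_likelihood > forward$log_likelihood) {
          h1[run] <- backward$h1[run]
          h2[run] <- backward$h2[run]
        }
      } else {
        cand_f <- list(h1 = h1, h2 = h2)
        cand_b <- list(h1 = h1, h2 = h2)
        cand_b$h1[run] <- backward$h1[run]
        cand_b$h2[run] <- backward$h2[run]
        rows <- which(rowSums(codes[, run, drop = FALSE] > 0L) > 0L)
        sub <- read_matrix(unclass(block)[rows, , drop = FALSE])
        if (mec_score(sub, cand_b) < mec_score(sub, cand_f)) {
          h1[run] <- backward$h1[run]
          h2[run] <- backward$h2[run]
        }
      }
    }
  }
  structure(list(h1 = h1, h2 = h2, sites = forward$sites,
                 log_likelihood = max(forward$log_likelihood,
                                      backward$log_likelihood),
                 direction = "reconciled"),
            class = "HaplotypePair")
}

#' Assemble haplotypes from a fragment matrix
#'
#' Full pipeline: rare-allele masking, heterozygous-site detection,
#' splitting into connected blocks, per-block (bidirectional) deterministic
#' SMC assembly and reconciliation.  Singleton blocks and sites declared
#' homozygous are reported as unphased.
#'
#' @param x A [read_matrix()] object.
#' @param params A [model_params()] object.
#' @param postprocess If `TRUE` (default), run both directions and
#'   [reconcile()]; otherwise a single forward sweep per block.
#' @return An object of class `hap_assembly`: list with `blocks` (a list of
#'   `HaplotypePair`, each with an `mec` score and `genotypes` attached),
#'   `unphased_sites`, `n_sites` and `params`.
#' @examples
#' m <- read_matrix(rbind(c("A","C","-"), c("A","C","G"), c("C","A","T"),
#'                        c("-","A","T")))
#' asm <- assemble_haplotypes(m)
#' asm$blocks[[1]]
#' @export
assemble_haplotypes <- function(x, params = model_params(), postprocess = TRUE) {
  stopifnot(inherits(x, "ReadMatrix"))
  masked <- mask_rare_alleles(x)
  het <- detect_heterozygous_sites(masked)
  blocks <- split_connected_blocks(het)
  phaseable <- vapply(blocks, ncol, 1L) >= 2L
  unphased <- sort(c(setdiff(site_index(x), site_index(het)),
                     unlist(lapply(blocks[!phaseable], site_index))))
  out <- vector("list", sum(phaseable))
  bi <- 0L
  for (blk in blocks[phaseable]) {
    bi <- bi + 1L
    if (postprocess) {
      runs <- run_bidirectional(blk, params)
      pair <- reconcile(runs$forward, runs$backward, blk, params)
    } else {
      pair <- run_block(blk, params, "forward")
    }
    pair$block_id <- bi
    pair$mec <- mec_score(blk, pair)
    pair$genotypes <- genotype_calls(pair)
    out[[bi]] <- pair
  }
  structure(list(blocks = out, unphased_sites = unphased,
                 n_sites = ncol(x), params = params),
            class = "hap_assembly")
}

#' @export
print.hap_assembly <- function(x, ...) {
  np <- sum(vapply(x$blocks, function(b) length(b$h1), 1L))
  cat(sprintf("hap_assembly: %d block(s), %d of %d sites phased, total MEC %d\n",
              length(x$blocks), np, x$n_sites,
              sum(vapply(x$blocks, function(b) b$mec, 1L))))
  invisible(x)
}

#' Sites phased by an assembly
#'
#' @param asm A `hap_assembly`.
#' @return Integer vector of phased (original) site indices, in order.
#' @export
phased_sites <- function(asm) {
  sort(unlist(lapply(asm$blocks, function(b) b$sites)))
}

#' Write phased haplotype blocks
#'
#' One header line per block, `BLOCK <id> nPhased <k> logL <v> MEC <s>`,
#' followed by one line per site: `<site> <hap1_allele> <hap2_allele>
#' <genotype>` (1-based original site coordinates).
#'
#' @param asm A `hap_assembly` from [assemble_haplotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_blocks <- function(asm, path) {
  stopifnot(inherits(asm, "hap_assembly"))
  con <- file(path, "w")
  on.exit(close(con))
  for (b in asm$blocks) {
    writeLines(sprintf("BLOCK %d nPhased %d logL %.6g MEC %d",
                       b$block_id, length(b$h1), b$log_likelihood, b$mec), con)
    writeLines(sprintf("%d %s %s %s", b$sites, b$h1, b$h2, b$genotypes), con)
  }
  invisible(path)
}

#' Read phased haplotype blocks
#'
#' Parses the format written by [write_phased_blocks()].
#'
#' @param path File path.
#' @return A list of `HaplotypePair` objects (with `block_id`, `mec`,
#'   `genotypes`).
#' @export
read_phased_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur)) return(blocks)
    c(blocks, list(structure(cur, class = "HaplotypePair")))
  }
  for (line in lines) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[[1]] == "BLOCK") {
      blocks <- flush(cur, blocks)
      cur <- list(block_id = as.integer(tok[[2]]), h1 = character(0),
                  h2 = character(0), sites = integer(0),
                  log_likelihood = as.numeric(tok[[6]]),
                  mec = as.integer(tok[[8]]), genotypes = character(0),
                  direction = "reconciled")
    } else {
      if (is.null(cur)) stop("site line before any BLOCK header")
      cur$sites <- c(cur$sites, as.integer(tok[[1]]))
      cur$h1 <- c(cur$h1, tok[[2]])
      cur$h2 <- c(cur$h2, tok[[3]])
      cur$genotypes <- c(cur$genotypes, tok[[4]])
    }
  }
  flush(cur, blocks)
}
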