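#' Mask rarely observed alleles
#'
#' At every site, only the two most frequently observed nucleotides (three
#' when the second and third counts tie) are plausible alleles; the rest are
#' almost surely sequencing errors and are replaced by the gap symbol.  This
#' both de-noises the data and bounds the number of candidate heterozygous
#' pairs the assembler must score per site.  All alleles tied with the
#' second-most-frequent count are kept (conservative tie rule).
#'
#' @param x A [read_matrix()] object.
#' @return A `ReadMatrix` with rare alleles replaced by `-`.
#' @export
mask_rare_alleles <- function(x) {
  stopifnot(inherits(x, "ReadMatrix"))
  codes <- encode_matrix(x)
  out <- unclass(x)
  for (j in seq_len(ncol(x))) {
    cj <- codes[, j]
    counts <- tabulate(cj, nbins = 4L)
    observed <- which(counts > 0L)
    if (length(observed) <= 2L) next
    c2 <- sort(counts[observed], decreasing = TRUE)[2L]
    drop <- which(counts > 0L & counts < c2)
    if (length(drop)) out[cj %in% drop, j] <- GAP
  }
  read_matrix(out, sites = site_index(x))
}

#' Detect heterozygous sites and project onto them
#'
#' Sites where (after allele masking) fewer than two distinct alleles are
#' observed carry no phase information: they are declared homozygous (or
#' uninformative, if uncovered) and removed before assembly.
#'
#' @param x A `ReadMatrix` (normally the output of [mask_rare_alleles()]).
#' @return A `ReadMatrix` restricted to the heterozygous sites; the original
#'   coordinates of the retained columns are available via [site_index()].
#' @export
detect_heterozygous_sites <- function(x) {
  stopifnot(inherits(x, "ReadMatrix"))
  codes <- encode_matrix(x)
  het <- vapply(seq_len(ncol(x)), function(j) {
    cj <- codes[, j]
    sum(tabulate(cj, nbins = 4L) > 0L) >= 2L
  }, logical(1))
  keep <- which(het)
  read_matrix(unclass(x)[, keep, drop = FALSE], sites = site_index(x)[keep])
}

#' Split a fragment matrix into connected blocks
#'
#' Two sites can be phased relative to each other only if some chain of
#' reads connects them.  Build the graph whose vertices are sites and whose
#' edges join sites co-covered by at least one read (a paired-end read links
#' sites across its insert gap); each connected component becomes an
#' independently assemblable block.  Sites covered by no read, or connected
#' to no other site, form singleton blocks that cannot be phased.
#'
#' @param x A `ReadMatrix` of heterozygous sites.
#' @return A list of `ReadMatrix` blocks (each with >= 1 site and the reads
#'   covering it; original coordinates via [site_index()]), ordered by their
#'   first site.  Singleton blocks are included; callers report them as
#'   unphased.
#' @export
split_connected_blocks <- function(x) {
  stopifnot(inherits(x, "ReadMatrix"))
  n <- ncol(x)
  if (n == 0L) return(list())
  codes <- encode_matrix(x)
  # edges: consecutive covered sites within each read chain the whole read
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(nrow(x))) {
    cov <- which(codes[i, ] > 0L)
    if (length(cov) >= 2L) {
      ei <- c(ei, cov[-length(cov)])
      ej <- c(ej, cov[-1L])
    }
  }
  g <- igraph::make_graph(rbind(ei, ej), n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  blocks <- unname(split(seq_len(n), comp))
  blocks <- blocks[order(vapply(blocks, min, 1L))]
  lapply(blocks, function(sites) {
    sub <- codes[, sites, drop = FALSE]
    rows <- which(rowSums(sub > 0L) > 0L)
    read_matrix(unclass(x)[rows, sites, drop = FALSE],
                sites = site_index(x)[sites])
  })
}
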