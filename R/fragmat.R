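#' @useDynLib smchap, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Nucleotide alphabet used throughout; '-' marks a site not covered by a read
# (or an ambiguous base call).
BASES <- c("A", "C", "G", "T")
GAP <- "-"

#' Construct a fragment matrix
#'
#' A `ReadMatrix` is the standard input of single-individual haplotyping: an
#' m x n character matrix whose rows are sequencing reads (a paired-end read
#' and its mate form a single row) and whose columns are heterozygous SNP
#' sites, with entries in `A`, `C`, `G`, `T` or `-` for sites a read does not
#' cover.  Site coordinates are 1-based and closed.
#'
#' @param mat Character matrix with entries in `c("A","C","G","T","-")`.
#'   Ambiguous calls (`N`) are mapped to `-`.  Row names, if present, are kept
#'   as read identifiers; otherwise `r1..rm` are assigned.
#' @param sites Optional integer vector of original site indices (used when a
#'   matrix is a projection/block of a larger one); defaults to `1:ncol(mat)`.
#' @return An object of class `ReadMatrix`.
#' @examples
#' m <- read_matrix(rbind(r1 = c("A", "C", "-"), r2 = c("-", "C", "G")))
#' n_sites(m)
#' @export
read_matrix <- function(mat, sites = NULL) {
  mat <- as.matrix(mat)
  mode(mat) <- "character"
  mat[mat %in% c("N", "n", ".")] <- GAP
  bad <- !(mat %in% c(BASES, GAP))
  if (any(bad)) {
    stop("invalid allele character(s): ",
         paste(unique(mat[bad]), collapse = ", "))
  }
  if (is.null(rownames(mat)) && nrow(mat) > 0L) {
    rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  }
  if (is.null(sites)) sites <- seq_len(ncol(mat))
  stopifnot(length(sites) == ncol(mat))
  structure(mat, sites = as.integer(sites), class = c("ReadMatrix", "matrix"))
}

#' @export
print.ReadMatrix <- function(x, ...) {
  cat(sprintf("ReadMatrix: %d reads x %d sites\n", nrow(x), ncol(x)))
  if (nrow(x) <= 20L && ncol(x) <= 60L) {
    print(unclass(x))
  } else {
    cat("(use unclass() to see entries)\n")
  }
  invisible(x)
}

#' @rdname read_matrix
#' @param x A `ReadMatrix`.
#' @export
n_reads <- function(x) nrow(x)

#' @rdname read_matrix
#' @export
n_sites <- function(x) ncol(x)

#' @rdname read_matrix
#' @export
site_index <- function(x) attr(x, "sites")

# integer coding of the matrix for the C++ core: 0 = gap, 1..4 = A,C,G,T
encode_matrix <- function(x) {
  codes <- match(x, BASES, nomatch = 0L)
  dim(codes) <- dim(x)
  codes
}

decode_bases <- function(codes) BASES[codes]

# split a dense row into (start, allele-string) segments; inverse of
# materialization.  Returns a list of list(start=, alleles=).
row_segments <- function(row) {
  covered <- row != GAP
  if (!any(covered)) return(list())
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) {
    list(start = starts[i],
         alleles = paste(row[starts[i]:ends[i]], collapse = ""))
  })
}

#' Read a fragment file
#'
#' Parses the whitespace-delimited fragment format
#' `\code{<n_segments> <read_id> {<start> <alleles>}...}` with one read per
#' line: each segment is a 1-based start site followed by a string of
#' contiguous base calls.  An optional final token that is not part of a
#' segment (e.g. a per-base quality string emitted by fragment extractors) is
#' accepted and ignored: the model uses a single global error rate.  Lines
#' starting with `#` are comments; a header comment `# n=<sites>` overrides
#' the number of sites (otherwise the maximum segment end is used).
#'
#' @param path Path to the fragment file.
#' @return A [read_matrix()] object.
#' @examples
#' frags <- system.file("extdata", "example.frags", package = "smchap")
#' parse_fragment_file(frags)
#' @export
parse_fragment_file <- function(path) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  lines <- readLines(path)
  n_override <- NA_integer_
  reads <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      hm <- regmatches(line, regexec("n\\s*=\\s*([0-9]+)", line))[[1]]
      if (length(hm) == 2L) n_override <- as.integer(hm[[2]])
      next
    }
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("line %d: expected '<n_segments> <read_id> <start> <alleles> ...'", ln))
    }
    nseg <- suppressWarnings(as.integer(tok[[1]]))
    if (is.na(nseg) || nseg < 1L) {
      stop(sprintf("line %d: invalid segment count '%s'", ln, tok[[1]]))
    }
    need <- 2L + 2L * nseg
    if (length(tok) < need || length(tok) > need + 1L) {
      stop(sprintf("line %d: %d segments declared but %d tokens found",
                   ln, nseg, length(tok)))
    }
    segs <- vector("list", nseg)
    for (s in seq_len(nseg)) {
      start <- suppressWarnings(as.integer(tok[[2L * s + 1L]]))
      alleles <- toupper(tok[[2L * s + 2L]])
      if (is.na(start) || start < 1L) {
        stop(sprintf("line %d: invalid segment start '%s'", ln, tok[[2L * s + 1L]]))
      }
      alleles <- gsub("N", GAP, alleles, fixed = TRUE)
      if (grepl(sprintf("[^%s-]", paste(BASES, collapse = "")), alleles)) {
        stop(sprintf("line %d: non-ACGT allele in segment '%s'", ln, alleles))
      }
      segs[[s]] <- list(start = start, alleles = alleles)
    }
    starts <- vapply(segs, `[[`, 1L, "start")
    ends <- starts + nchar(vapply(segs, `[[`, "", "alleles")) - 1L
    o <- order(starts)
    segs <- segs[o]; starts <- starts[o]; ends <- ends[o]
    if (nseg > 1L && any(starts[-1L] <= ends[-nseg])) {
      stop(sprintf("line %d: overlapping segments in read '%s'", ln, tok[[2]]))
    }
    reads[[length(reads) + 1L]] <- list(id = tok[[2]], segs = segs,
                                        end = max(ends))
  }
  n <- if (!is.na(n_override)) n_override else
    if (length(reads)) max(vapply(reads, `[[`, 1L, "end")) else 0L
  mat <- matrix(GAP, nrow = length(reads), ncol = n)
  for (i in seq_along(reads)) {
    for (seg in reads[[i]]$segs) {
      a <- strsplit(seg$alleles, "")[[1]]
      mat[i, seg$start:(seg$start + length(a) - 1L)] <- a
    }
  }
  rownames(mat) <- vapply(reads, `[[`, "", "id")
  read_matrix(mat)
}

#' Write a fragment file
#'
#' Inverse of [parse_fragment_file()]: each read is emitted as one line of
#' `<n_segments> <read_id> {<start> <alleles>}...`, reads in matrix order.
#' Reads with no covered site are skipped.  Writes a `# n=` header so the
#' site count round-trips even when trailing sites are uncovered.
#'
#' @param x A `ReadMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_file <- function(x, path) {
  stopifnot(inherits(x, "ReadMatrix"))
  out <- character(0)
  out <- c(out, sprintf("# n=%d", ncol(x)))
  for (i in seq_len(nrow(x))) {
    segs <- row_segments(x[i, ])
    if (!length(segs)) next
    toks <- unlist(lapply(segs, function(s) c(s$start, s$alleles)))
    out <- c(out, paste(c(length(segs), rownames(x)[i], toks), collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read/write a dense TSV allele matrix
#'
#' Plain-text fixture format: one row per read, first column the read id,
#' then one single-character column per site (`-` for gaps).
#'
#' @param path File path.
#' @return [parse_matrix_tsv()] returns a `ReadMatrix`;
#'   [write_matrix_tsv()] returns `path` invisibly.
#' @export
parse_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) stop("ragged rows in ", path)
  mat <- do.call(rbind, lapply(fields, function(f) toupper(f[-1L])))
  rownames(mat) <- vapply(fields, `[[`, "", 1L)
  read_matrix(mat)
}

#' @rdname parse_matrix_tsv
#' @param x A `ReadMatrix`.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "ReadMatrix"))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], x[i, ]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
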