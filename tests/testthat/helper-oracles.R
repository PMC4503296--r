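# Independent brute-force oracles used to validate the implementation.

BASES4 <- c("A", "C", "G", "T")

# MEC by exhaustive enumeration of read-to-haplotype assignments.
brute_mec <- function(x, pair) {
  m <- unclass(x)
  nr <- nrow(m)
  best <- Inf
  for (mask in 0:(2^nr - 1)) {
    f <- bitwAnd(bitwShiftR(mask, seq_len(nr) - 1L), 1L) + 1L
    total <- 0L
    for (i in seq_len(nr)) {
      h <- if (f[i] == 1L) pair$h1 else pair$h2
      total <- total + sum(m[i, ] != "-" & m[i, ] != h)
    }
    best <- min(best, total)
  }
  best
}

# Connected components of the site graph via union-find.
uf_components <- function(x) {
  m <- unclass(x)
  n <- ncol(m)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(nrow(m))) {
    cov <- which(m[i, ] != "-")
    if (length(cov) >= 2L) {
      for (k in seq_along(cov)[-1L]) {
        ra <- find(cov[1L]); rb <- find(cov[k])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), match(roots, unique(roots)))
}

# Log-weight of a complete haplotype-pair path under the gap-aware
# recursion, recomputed directly from the exported step operations.
path_log_weight <- function(h1, h2, mat, params) {
  m <- nrow(mat)
  pos <- rep(0L, m)
  lw <- log(column_likelihood(1L, c(h1[1], h2[1]),
                              matrix(character(), 2, 0), mat, pos, params$e))
  pos <- update_pos(pos, mat[, 1L], 1L)
  for (t in seq_len(ncol(mat))[-1L]) {
    path <- rbind(h1[seq_len(t - 1L)], h2[seq_len(t - 1L)])
    lw <- extension_weight(lw, t, c(h1[t], h2[t]), path, mat, pos, params)
    pos <- update_pos(pos, mat[, t], t)
  }
  unname(lw)
}

# All candidate paths of a block (mirror pairs collapsed at site 1).
enumerate_all_paths <- function(mat) {
  cands <- lapply(seq_len(ncol(mat)), function(t) {
    enumerate_candidates(mat[, t], first_site = (t == 1L))
  })
  idx <- do.call(expand.grid, lapply(cands, function(cc) seq_len(nrow(cc))))
  lapply(seq_len(nrow(idx)), function(r) {
    picks <- vapply(seq_along(cands), function(t) {
      cands[[t]][idx[r, t], , drop = TRUE]
    }, character(2))
    list(h1 = picks[1, ], h2 = picks[2, ])
  })
}

# Random small fragment matrix suitable for exhaustive-oracle tests:
# returns a preprocessed single block with n_sites in [2, max_n] and a
# bounded number of candidate paths.
random_block <- function(max_n = 6L, max_m = 12L, err = 0.1, max_paths = 2000L) {
  repeat {
    n <- sample(3:max_n, 1L)
    m <- sample(4:max_m, 1L)
    h1 <- sample(BASES4, n, replace = TRUE)
    h2 <- vapply(h1, function(a) sample(setdiff(BASES4, a), 1L), "")
    mat <- matrix("-", m, n)
    for (i in seq_len(m)) {
      len <- sample(2:n, 1L)
      start <- sample(seq_len(n - len + 1L), 1L)
      src <- if (stats::runif(1) < 0.5) h1 else h2
      seg <- src[start:(start + len - 1L)]
      hit <- stats::runif(len) < err
      seg[hit] <- vapply(seg[hit], function(a) sample(setdiff(BASES4, a), 1L), "")
      mat[i, start:(start + len - 1L)] <- seg
    }
    x <- detect_heterozygous_sites(mask_rare_alleles(read_matrix(mat)))
    if (ncol(x) < 2L) next
    blocks <- split_connected_blocks(x)
    blk <- blocks[[which.max(vapply(blocks, ncol, 1L))]]
    if (ncol(blk) < 2L) next
    L <- vapply(seq_len(ncol(blk)), function(t) {
      a <- length(intersect(BASES4, blk[, t]))
      if (t == 1L) a * (a - 1L) / 2L else a * (a - 1L)
    }, 0)
    if (prod(L) > max_paths) next
    return(list(block = blk, truth = list(h1 = h1, h2 = h2), K = prod(L)))
  }
}

# Independent re-statement of the reconciliation rule, used to check the
# implementation against a second code path.
reconcile_oracle <- function(fwd, bwd, block) {
  h1 <- fwd$h1; h2 <- fwd$h2
  disc <- which(fwd$h1 != bwd$h1 | fwd$h2 != bwd$h2)
  if (length(disc)) {
    runs <- unname(split(disc, cumsum(c(1L, diff(disc) != 1L))))
    for (run in runs) {
      take_bwd <- if (length(run) == 1L) {
        bwd$log_likelihood > fwd$log_likelihood
      } else {
        cf <- list(h1 = h1, h2 = h2)
        cb <- list(h1 = replace(h1, run, bwd$h1[run]),
                   h2 = replace(h2, run, bwd$h2[run]))
        cov <- which(apply(unclass(block)[, run, drop = FALSE] != "-", 1, any))
        sub <- read_matrix(unclass(block)[cov, , drop = FALSE])
        brute_mec(sub, cb) < brute_mec(sub, cf)
      }
      if (take_bwd) {
        h1[run] <- bwd$h1[run]
        h2[run] <- bwd$h2[run]
      }
    }
  }
  list(h1 = h1, h2 = h2)
}
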