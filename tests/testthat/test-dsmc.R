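test_that("particle budget schedule follows the block length", {
  expect_equal(choose_K(5), 12L)
  expect_equal(choose_K(12), 12L)
  expect_equal(choose_K(13), 6L)
  expect_equal(choose_K(50), 25L)
  expect_equal(choose_K(99), 49L)
  expect_equal(choose_K(100), 50L)
  expect_equal(choose_K(1000), 50L)
})

test_that("emission probabilities match the error model and normalize", {
  expect_equal(emission_prob("A", "A", 0.01), 0.99)
  expect_equal(emission_prob("A", "C", 0.01), 0.01 / 3)
  for (s in c("A", "C", "G", "T")) {
    expect_equal(sum(emission_prob(c("A", "C", "G", "T"), s, 0.13)), 1)
  }
})

test_that("candidate enumeration covers all ordered heterozygous pairs", {
  cc <- enumerate_candidates(c("C", "G", "-", "C"))
  expect_equal(cc, rbind(c("C", "G"), c("G", "C")), ignore_attr = TRUE)
  expect_equal(nrow(enumerate_candidates(c("A", "C", "G"))), 6L)
  expect_equal(nrow(enumerate_candidates(c("A", "C", "G", "T"))), 12L)
  # mirror collapse at the first site
  cc1 <- enumerate_candidates(c("A", "C", "G", "T"), first_site = TRUE)
  expect_equal(nrow(cc1), 6L)
  expect_true(all(cc1[, 1] < cc1[, 2]))
  expect_error(enumerate_candidates(c("A", "A", "-")), "fewer than two")
})

test_that("nearest informative positions track gaps and are monotone", {
  row <- c("A", "-", "-", "C")
  pos <- 0L
  got <- integer(4)
  for (t in 1:4) {
    pos <- update_pos(pos, row[t], t)
    got[t] <- pos
  }
  expect_equal(got, c(1L, 1L, 1L, 4L))
  expect_equal(update_pos(0L, "-", 5L), 0L)  # all-gap prefix stays 0
  set.seed(3)
  for (rep in 1:10) {
    row <- sample(c("A", "-"), 12, replace = TRUE)
    pos <- 0L
    trail <- vapply(seq_along(row), function(t) pos <<- update_pos(pos, row[t], t), 1L)
    expect_true(all(diff(trail) >= 0))
  }
})

test_that("measurement branches chain reads through their anchoring base", {
  e <- 0.01
  # anchor matches hap-1 allele -> emission against s1
  expect_equal(read_branch_likelihood("A", c("A", "C"), "G", c("G", "T"), e),
               1 - e)
  # anchor matches hap-2 allele -> emission against s2
  expect_equal(read_branch_likelihood("A", c("A", "C"), "T", c("G", "T"), e),
               e / 3)
  # no informative position yet -> averaged emissions
  expect_equal(read_branch_likelihood("A", c("A", "C"), NA, NA, e),
               ((1 - e) + e / 3) / 2)
  # anchor matches neither phased allele (erroneous/masked base) -> averaged
  expect_equal(read_branch_likelihood("C", c("A", "C"), "T", c("A", "G"), e),
               (e / 3 + (1 - e)) / 2)
})

test_that("column likelihood is the product of per-read branches", {
  e <- 0.02
  mat <- rbind(c("A", "A"), c("C", "C"), c("-", "G"))
  # no read covers a column -> empty product
  empty <- read_matrix(rbind(c("A", "-"), c("C", "-")))
  expect_equal(column_likelihood(2, c("A", "C"), rbind("A", "C"),
                                 unclass(empty), c(1L, 1L), e), 1)
  # single error-free read chained to hap-1
  one <- rbind(c("A", "A"))
  expect_equal(column_likelihood(2, c("A", "C"), rbind("A", "C"),
                                 one, c(1L), e), 1 - e)
  # random columns against a direct re-computation
  set.seed(9)
  for (rep in 1:10) {
    m <- sample(2:6, 1L)
    mat <- matrix(sample(c("A", "C", "-"), m * 2, replace = TRUE), m, 2)
    path <- rbind("A", "C")
    pos <- ifelse(mat[, 1] != "-", 1L, 0L)
    want <- 1
    for (i in seq_len(m)) {
      if (mat[i, 2] == "-") next
      want <- want * read_branch_likelihood(
        mat[i, 2], c("C", "A"),
        if (pos[i] > 0) mat[i, 1] else NA,
        if (pos[i] > 0) path[, 1] else NA, e)
    }
    expect_equal(column_likelihood(2, c("C", "A"), path, mat, pos, e), want)
  }
})

test_that("transition prior multiplies composition probabilities", {
  p <- model_params()
  expect_equal(transition_prob(c("A", "C"), p), 1 / 16)
  q <- model_params(composition = c(A = 0.4, C = 0.2, G = 0.2, T = 0.2))
  expect_equal(transition_prob(c("A", "C"), q), 0.08)
  pairs <- expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  expect_equal(sum(apply(pairs, 1, transition_prob, params = q)), 1)
})

test_that("extension weights agree with the linear-space product", {
  set.seed(15)
  p <- model_params(e = 0.05)
  for (rep in 1:10) {
    inst <- random_block(max_n = 4)
    mat <- unclass(inst$block)
    cand <- enumerate_candidates(mat[, 2])
    path <- enumerate_candidates(mat[, 1], first_site = TRUE)[1, , drop = FALSE]
    pos <- ifelse(mat[, 1] != "-", 1L, 0L)
    lw <- extension_weight(log(0.37), 2L, cand[1, ], t(path), mat, pos, p)
    lin <- 0.37 * column_likelihood(2L, cand[1, ], t(path), mat, pos, p$e) *
      transition_prob(cand[1, ], p)
    expect_equal(lw, log(lin))
  }
})

test_that("top-K selection equals sort-and-truncate with deterministic ties", {
  set.seed(21)
  for (rep in 1:10) {
    w <- log(stats::runif(30))
    w[sample(30, 3)] <- -Inf
    K <- sample(3:12, 1L)
    sel <- select_top_K(w, K)
    alive <- which(is.finite(w))
    want <- alive[order(-w[alive], alive)][seq_len(min(K, length(alive)))]
    expect_equal(sel$keep, want)
    expect_equal(sum(exp(sel$log_w)), 1)
  }
  # all kept when fewer extensions than budget
  sel <- select_top_K(log(c(0.2, 0.5)), 10L)
  expect_equal(sel$keep, c(2L, 1L))
  expect_error(select_top_K(rep(-Inf, 3), 2L), "zero weight")
})

test_that("noiseless full-coverage matrices are reconstructed exactly", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:12, 1L)
    h1 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    h2 <- vapply(h1, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1L), "")
    x <- read_matrix(rbind(h1, h2, h1, h2))
    pair <- run_block(x, model_params())
    expect_equal(reconstruction_rate(list(h1 = h1, h2 = h2), pair), 1)
    expect_equal(mec_score(x, pair), 0L)
  }
})

test_that("with a full particle budget the sweep maximizes the path weight", {
  set.seed(37)
  p <- model_params(e = 0.05)
  for (rep in 1:30) {
    inst <- random_block()
    got <- run_block(inst$block, model_params(e = 0.05, K = inst$K))
    got_w <- path_log_weight(got$h1, got$h2, unclass(inst$block), p)
    best <- max(vapply(enumerate_all_paths(unclass(inst$block)), function(pp) {
      path_log_weight(pp$h1, pp$h2, unclass(inst$block), p)
    }, 0))
    expect_equal(got_w, best, tolerance = 1e-9)
  }
})

test_that("compiled sweep matches the pure-R reference sweep", {
  set.seed(41)
  for (rep in 1:15) {
    inst <- random_block(max_n = 5)
    K <- sample(2:6, 1L)
    p <- model_params(e = 0.03, K = K)
    a <- run_block(inst$block, p)
    b <- smchap:::dsmc_sweep_r(inst$block, p)
    expect_equal(a$log_likelihood, b$log_likelihood, tolerance = 1e-9)
    wa <- path_log_weight(a$h1, a$h2, unclass(inst$block), p)
    wb <- path_log_weight(b$h1, b$h2, unclass(inst$block), p)
    expect_equal(wa, wb, tolerance = 1e-9)
  }
})

test_that("the path weight is invariant under a global haplotype swap", {
  set.seed(43)
  p <- model_params(e = 0.05)
  for (rep in 1:10) {
    inst <- random_block()
    pair <- run_block(inst$block, model_params(e = 0.05, K = 20))
    expect_equal(path_log_weight(pair$h1, pair$h2, unclass(inst$block), p),
                 path_log_weight(pair$h2, pair$h1, unclass(inst$block), p))
  }
})

test_that("a consistent error-free read never hurts the true path", {
  # relative posterior weight of the truth vs any competitor is monotone in
  # consistent evidence
  set.seed(47)
  p <- model_params(e = 0.05)
  for (rep in 1:10) {
    inst <- random_block(max_n = 4, err = 0)
    mat0 <- unclass(inst$block)
    truth <- list(h1 = inst$truth$h1[site_index(inst$block)],
                  h2 = inst$truth$h2[site_index(inst$block)])
    extra <- matrix(truth$h1, nrow = 1)
    mat1 <- rbind(mat0, extra)
    paths <- enumerate_all_paths(mat0)
    w0 <- vapply(paths, function(pp) path_log_weight(pp$h1, pp$h2, mat0, p), 0)
    w1 <- vapply(paths, function(pp) path_log_weight(pp$h1, pp$h2, mat1, p), 0)
    truth_at <- which(vapply(paths, function(pp) {
      (all(pp$h1 == truth$h1) && all(pp$h2 == truth$h2)) ||
        (all(pp$h1 == truth$h2) && all(pp$h2 == truth$h1))
    }, logical(1)))
    if (!length(truth_at)) next
    ti <- truth_at[1]
    expect_true(all((w1[ti] - w1) >= (w0[ti] - w0) - 1e-9))
  }
})

test_that("runtime grows about linearly with block length", {
  p <- model_params(K = 30)
  mk_x <- function(n) {
    h1 <- rep(c("A", "C"), length.out = n)
    h2 <- rep(c("C", "A"), length.out = n)
    read_matrix(do.call(rbind, replicate(8, rbind(h1, h2), simplify = FALSE)))
  }
  t1 <- system.time(for (i in 1:5) run_block(mk_x(100), p))[["elapsed"]]
  t4 <- system.time(for (i in 1:5) run_block(mk_x(400), p))[["elapsed"]]
  # generous bound: 4x the sites should cost well under 16x (quadratic) time
  expect_lt(t4, max(16 * t1, 0.5))
})
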