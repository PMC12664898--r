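# Independent oracles and shared fixtures for the test suite.

# Brute-force flood fill (BFS in plain R), independent of the package's
# labelling kernel.
brute_flood_fill <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(off))
  off <- off[s > 0 & (connectivity == 26 | (connectivity == 18 & s <= 2) |
                      (connectivity == 6 & s <= 1)), , drop = FALSE]
  lab <- array(0L, dm)
  nxt <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(start, dm)[1, ])
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(off))) {
        q <- p + off[r, ]
        if (any(q < 1) || any(q > dm)) next
        if (mask[q[1], q[2], q[3]] != 0 && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Exhaustive maximum-cardinality matching under a strict distance threshold
# (recursive search; fine for <= 12 points per side).
brute_max_matching <- function(A, B, threshold) {
  nA <- nrow(A); nB <- nrow(B)
  d <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
  ok <- d < threshold
  best <- 0L
  recurse <- function(a, usedB, count) {
    if (a > nA) { best <<- max(best, count); return(invisible()) }
    if (count + (nA - a + 1L) <= best) return(invisible())  # bound
    recurse(a + 1L, usedB, count)  # skip a
    for (b in which(ok[a, ] & !usedB)) {
      usedB[b] <- TRUE
      recurse(a + 1L, usedB, count + 1L)
      usedB[b] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nB), 0L)
  best
}

# Hand-built two-slab atlas: region A (id 10) fills the left half of axis 1,
# region B (id 20) the right half; one top level under a root.
make_slab_atlas <- function(n = 10L, spacing = 10) {
  lab <- array(0L, c(n, n, n))
  lab[1:(n / 2), , ] <- 10L
  lab[(n / 2 + 1):n, , ] <- 20L
  onto <- data.frame(id = c(997, 10, 20),
                     acronym = c("root", "A", "B"),
                     name = c("root", "region A", "region B"),
                     parent_structure_id = c(NA, 997, 997))
  LabelAtlas(lab, spacing = spacing, ontology = onto)
}

toy_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildToyAtlas(10, c(30, 30, 30), 6, seed = 101)
    cache
  }
})

# The fixed-seed validation benchmark is expensive; run it once per session.
benchmark_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- runBenchmark(seed = 1L)
    cache
  }
})

expect_equal_sorted <- function(a, b, ...) {
  testthat::expect_equal(sort(as.numeric(a)), sort(as.numeric(b)), ...)
}
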