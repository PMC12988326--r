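# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Ends-free Needleman-Wunsch with affine gaps (BLOSUM62, open 11,
# extend 1) on tiny strings, returning the optimal score and the identity
# (over aligned columns; terminal gaps are free and excluded) of one
# optimal alignment. Identity can differ between co-optimal alignments;
# the score is unique. Plain O(n*m) dynamic program with explicit
# three-state recursion.
nw_identity_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in b (a aligned to gap)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  # free leading gaps
  for (i in 2:(n + 1)) Ix[i, 1] <- 0
  for (j in 2:(m + 1)) Iy[1, j] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    }
  }
  # free trailing gaps: the optimum ends on the last row or last column
  best <- -Inf
  bi <- bj <- bstate <- NA
  for (i in seq_len(n + 1)) {
    for (j in seq_len(m + 1)) {
      if (i == n + 1 || j == m + 1) {
        vals <- c(M[i, j], Ix[i, j], Iy[i, j])
        if (max(vals) > best) {
          best <- max(vals)
          bi <- i
          bj <- j
          bstate <- which.max(vals)
        }
      }
    }
  }
  # traceback over the aligned region only
  i <- bi
  j <- bj
  state <- bstate
  pa <- character()
  pb <- character()
  repeat {
    if (state == 1 && i == 1 && j == 1) break
    if (state == 2 && j == 1) break # leading free gap
    if (state == 3 && i == 1) break
    if (state == 1) {
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state_next <- which.max(prev)
      pa <- c(av[i - 1], pa)
      pb <- c(bv[j - 1], pb)
      i <- i - 1
      j <- j - 1
      state <- state_next
    } else if (state == 2) {
      from_m <- M[i - 1, j] - gap_open - gap_ext
      state_next <- if (isTRUE(all.equal(Ix[i, j], from_m))) 1 else 2
      if (j > 1) { # inside the aligned region, record the gap column
        pa <- c(av[i - 1], pa)
        pb <- c("-", pb)
      }
      i <- i - 1
      state <- state_next
    } else {
      from_m <- M[i, j - 1] - gap_open - gap_ext
      state_next <- if (isTRUE(all.equal(Iy[i, j], from_m))) 1 else 3
      if (i > 1) {
        pa <- c("-", pa)
        pb <- c(bv[j - 1], pb)
      }
      j <- j - 1
      state <- state_next
    }
  }
  # trailing free-gap columns never entered pa/pb (traceback started at the
  # boundary cell), and leading ones are cut by the break conditions; but a
  # trailing gap run reached through state 2/3 from the boundary is still
  # recorded, so trim gap-only columns at both ends
  if (length(pa) > 0 && any(pa != "-") && any(pb != "-")) {
    core <- seq(
      max(min(which(pa != "-")), min(which(pb != "-"))),
      min(max(which(pa != "-")), max(which(pb != "-")))
    )
    pa <- pa[core]
    pb <- pb[core]
  }
  list(
    identity = sum(pa == pb & pa != "-") / length(pa),
    score = best
  )
}

# Brute-force Benjamini-Hochberg step-up adjustment from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  # adjusted p of the i-th smallest = min over j >= i of m * p_(j) / j
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  adj
}

# Closed-form Wilson interval evaluated independently.
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  c(
    (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  )
}

# Penalized log-likelihood of a logistic model (for grid/numeric Firth
# oracle): l(beta) + 0.5 log det X'WX.
firth_pll_oracle <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * eta - log1p(exp(pmin(eta, 700))))
  info <- crossprod(X, X * (mu * (1 - mu)))
  ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
}

# A tiny two-system reference db + single-genome fixture shared by tests.
tiny_refdb <- function(seed = 11) generate_reference_db(1, mean_len = 80, seed = seed)

tiny_genome <- function(rm_types = c("I", "II"), identity = 0.9, seed = 3,
                        refdb = tiny_refdb(), ...) {
  plan <- plan_genome(
    "gT",
    systems = tibble::tibble(
      system_name = paste0("RM_type_", rm_types), rm_type = rm_types
    ),
    identity = identity, ...
  )
  generate_genome(plan, refdb, seed = seed)
}

# Assignments straight from ground truth (bypasses alignment) for
# rule-engine tests.
truth_assignments <- function(genome) {
  tr <- genome$truth
  purrr::list_rbind(purrr::pmap(tr, function(gene_ids, roles, rm_type, ...) {
    if (is.na(rm_type)) {
      return(NULL)
    }
    tibble::tibble(
      query_id = unlist(gene_ids),
      ref_id = paste0(rm_type, "-", unlist(roles), "-01"),
      rm_type = rm_type, role = unlist(roles),
      identity = 1, coverage = 1
    )
  }))
}
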